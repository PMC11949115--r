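# Assembly of per-sample phase assignments into buffer x pH phase diagrams,
# transition-pH extraction and d_NN-vs-pH tables.

#' Assemble a phase diagram from analyzed profiles
#'
#' Stacks `phase_assignment` rows (from [analyze_profile()] over a series)
#' into a phase-diagram table sorted by buffer and descending pH, with
#' coexisting phases listed jointly per cell.
#'
#' @param assignments Tibble of assignment rows with at least `buffer`, `ph`,
#'   `group_id`, `d_nn` columns; typically one [analyze_profile()] result per
#'   (buffer, pH) sample, row-bound.
#' @param merge Allow several profiles for the same (buffer, pH) cell
#'   (default `FALSE`: duplicates beyond phase coexistence within one profile
#'   raise an error).
#' @return A tibble of class `phase_diagram`.
#' @export
assemble_phase_diagram <- function(assignments, merge = FALSE) {
  if (nrow(assignments) == 0L) {
    out <- assignments
    class(out) <- c("phase_diagram", class(out))
    return(out)
  }
  check_columns(assignments, c("buffer", "ph", "group_id", "d_nn"),
                "assignments")
  if (!merge && "label" %in% names(assignments)) {
    dup <- assignments |>
      distinct(.data$buffer, .data$ph, .data$label) |>
      dplyr::count(.data$buffer, .data$ph) |>
      filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        "Several distinct profiles map to the same (buffer, pH) cell; ",
        "pass merge = TRUE to combine them."
      ))
    }
  }
  out <- arrange(assignments, .data$buffer, desc(.data$ph))
  class(out) <- c("phase_diagram", class(out))
  out
}

#' Extract the transition pH per buffer
#'
#' The transition pH for a target phase is the highest sampled pH at which
#' that phase appears (alone or coexisting). The bracketing interval is also
#' reported: the lowest sampled pH above the transition that lacks the
#' target, down to the transition itself. Invariant to row order and to
#' adding higher-pH samples without the target phase.
#'
#' @param diagram A [assemble_phase_diagram()] result.
#' @param target_phase Space group id to track (default `"H_II_p6mm"`, the
#'   inverse hexagonal phase).
#' @return Tibble per buffer: `transition_ph` (NA if the phase never
#'   appears), `bracket_high` (lowest sampled pH without the target above the
#'   transition, NA if the target is present at every sampled pH),
#'   `bracket_low` (= `transition_ph`).
#' @export
extract_transition_ph <- function(diagram, target_phase = "H_II_p6mm") {
  check_columns(diagram, c("buffer", "ph", "group_id"), "diagram")
  if (nrow(diagram) == 0L) {
    abort("`diagram` is empty.")
  }
  diagram |>
    as_tibble() |>
    group_by(.data$buffer) |>
    dplyr::group_modify(function(rows, key) {
      with_target <- unique(rows$ph[rows$group_id == target_phase])
      all_ph <- unique(rows$ph)
      if (length(with_target) == 0L) {
        return(tibble(transition_ph = NA_real_, bracket_high = NA_real_,
                      bracket_low = NA_real_))
      }
      t_ph <- max(with_target)
      above <- all_ph[all_ph > t_ph &
                        !all_ph %in% with_target]
      tibble(
        transition_ph = t_ph,
        bracket_high = if (length(above) > 0) min(above) else NA_real_,
        bracket_low = t_ph
      )
    }) |>
    ungroup()
}

#' Long-format nearest-neighbor distance table
#'
#' One row per phase assignment: `(buffer, ph, group_id, lattice_a, d_nn)`,
#' suitable for plotting d_NN against pH per buffer and phase.
#'
#' @param diagram A [assemble_phase_diagram()] result (or any assignment
#'   table).
#' @return A tibble.
#' @export
dnn_vs_ph <- function(diagram) {
  check_columns(diagram, c("buffer", "ph", "group_id", "d_nn"), "diagram")
  diagram |>
    as_tibble() |>
    select(dplyr::any_of(c("buffer", "ph", "group_id", "lattice_a",
                           "lattice_c", "d_nn"))) |>
    arrange(.data$buffer, desc(.data$ph), .data$group_id)
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates the stages over a single configuration: buffer speciation
#' and ionic-strength tables, SAXS series analysis (from a file manifest or a
#' simulated series), phase-diagram assembly with transition extraction, and
#' expression-kinetics summaries. Stages are run only if their config section
#' is present.
#'
#' Config sections (R list or YAML file):
#' \describe{
#'   \item{buffers}{`names` (preset names), `ph` (grid), `c_total_mM`,
#'     optional `nacl_mM`.}
#'   \item{saxs}{either `manifest` (CSV with columns `file`, `buffer`, `ph`)
#'     plus optional `q_units`, or `simulate = TRUE` to use
#'     [phase_series_presets()]; optional `tolerance`.}
#'   \item{kinetics}{`csv` path (columns `cell_id`, `condition`, `time_h`,
#'     `fluorescence`) and optional `reference` condition.}
#' }
#'
#' @param config R list or path to a YAML file.
#' @param seed Integer seed used for any simulated inputs.
#' @param out_dir Optional output directory; stage tables are written as CSV
#'   plus a JSON run record and a plain-text log of effective parameters.
#' @return A named list of result tibbles (invisible if `out_dir` given).
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a YAML file path.")
  }
  results <- list()
  log_lines <- c(
    sprintf("mesobuffer run, seed = %d", seed),
    sprintf("stages: %s", paste(names(config), collapse = ", "))
  )

  if (!is.null(config$buffers)) {
    cfg <- config$buffers
    ph <- cfg$ph %||% seq(3.5, 7.5, by = 0.5)
    c_tot <- cfg$c_total_mM %||% 50
    bg <- if (!is.null(cfg$nacl_mM)) nacl_background(cfg$nacl_mM)
    specs <- map(cfg$names %||% c("citrate", "phosphate", "acetate"),
                 function(b) speciate(b, ph, c_tot))
    results$speciation <- list_rbind(specs)
    results$ionic_strength <- list_rbind(
      map(specs, ionic_strength, background = bg)
    )
  }

  if (!is.null(config$saxs)) {
    cfg <- config$saxs
    tol <- cfg$tolerance %||% 0.005
    profiles <- if (isTRUE(cfg$simulate)) {
      simulate_phase_series(phase_series_presets(), seed = seed)$profile
    } else if (!is.null(cfg$manifest)) {
      man <- readr::read_csv(cfg$manifest, show_col_types = FALSE)
      check_columns(man, c("file", "buffer", "ph"), "manifest")
      base <- dirname(cfg$manifest)
      pmap(man, function(file, buffer, ph, ...) {
        path <- if (file.exists(file)) file else file.path(base, file)
        read_saxs_profile(path, q_units = cfg$q_units %||% "nm",
                          buffer = buffer, ph = ph)
      })
    } else {
      abort("saxs stage needs either `manifest` or `simulate: true`.")
    }
    assignments <- list_rbind(map(profiles, analyze_profile,
                                  tolerance = tol))
    results$assignments <- assignments
    results$phase_diagram <- assemble_phase_diagram(assignments)
    results$transitions <- extract_transition_ph(results$phase_diagram)
    results$dnn <- dnn_vs_ph(results$phase_diagram)
  }

  if (!is.null(config$kinetics)) {
    cfg <- config$kinetics
    traj <- read_trajectories(cfg$csv)
    summaries <- summarize_condition(traj)
    if (!is.null(cfg$reference) &&
        cfg$reference %in% summaries$condition) {
      summaries <- relative_efficiency(summaries, cfg$reference)
    }
    results$kinetics <- summaries
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results)) {
      tab <- results[[nm]]
      drop <- vapply(tab, is.list, logical(1))
      readr::write_csv(tab[, !drop, drop = FALSE],
                       file.path(out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(
      list(seed = seed, stages = names(results)),
      file.path(out_dir, "run.json"),
      auto_unbox = TRUE
    )
    writeLines(log_lines, file.path(out_dir, "run.log"))
    return(invisible(results))
  }
  results
}
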