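#' Define a polyprotic buffer
#'
#' A buffer is described by the acid dissociation constants of its (possibly
#' polyprotic) weak acid, written as pKa values in strictly ascending order,
#' and the charge of the counterion used to prepare the salt (sodium, +1, for
#' all buffers considered here).
#'
#' @param name Buffer name, e.g. `"citrate"`.
#' @param pKa Numeric vector of acid dissociation constants, strictly
#'   ascending. Its length is the number of acidic protons.
#' @param counterion_charge Integer charge of the counterion (default `1`,
#'   sodium). Must be non-zero.
#' @param counterion Label for the counterion (default `"Na+"`).
#'
#' @return An object of class `buffer_definition`.
#' @seealso [buffer_presets()] for the citrate/phosphate/acetate defaults.
#' @export
#' @examples
#' buffer_definition("acetate", 4.76)
#' buffer_definition("citrate", c(3.13, 4.76, 6.40))
buffer_definition <- function(name, pKa, counterion_charge = 1L,
                              counterion = "Na+") {
  if (!is.character(name) || length(name) != 1L) {
    abort("`name` must be a single string.")
  }
  if (!is.numeric(pKa) || length(pKa) < 1L || anyNA(pKa)) {
    abort("`pKa` must be a non-empty numeric vector.")
  }
  if (length(pKa) > 1L && any(diff(pKa) <= 0)) {
    abort("`pKa` values must be strictly ascending.")
  }
  if (counterion_charge == 0) {
    abort("`counterion_charge` must be non-zero.")
  }
  structure(
    list(
      name = name,
      pKa = as.numeric(pKa),
      max_deprotonation = length(pKa),
      counterion_charge = as.integer(counterion_charge),
      counterion = counterion
    ),
    class = "buffer_definition"
  )
}

#' @export
print.buffer_definition <- function(x, ...) {
  cat(sprintf(
    "<buffer_definition> %s: pKa = %s; counterion %s (%+d)\n",
    x$name, paste(format(x$pKa), collapse = ", "),
    x$counterion, x$counterion_charge
  ))
  invisible(x)
}

#' Default buffer definitions
#'
#' Full polyprotic pKa sets for the three buffers used throughout:
#' citric acid 3.13 / 4.76 / 6.40, phosphoric acid 2.15 / 7.20 / 12.35,
#' acetic acid 4.76. The full sets (rather than the single pKa closest to the
#' working pH) are required to reproduce the ionic strengths of the 50 mM
#' buffers at pH 5.5 (151 / 52 / 42 mM for citrate / phosphate / acetate).
#' All are sodium salts.
#'
#' @param name Optional buffer name; if given, the single matching
#'   [buffer_definition()] is returned instead of the full list.
#' @return A named list of `buffer_definition` objects, or a single one.
#' @export
#' @examples
#' buffer_presets("citrate")
buffer_presets <- function(name = NULL) {
  presets <- list(
    citrate   = buffer_definition("citrate", c(3.13, 4.76, 6.40)),
    phosphate = buffer_definition("phosphate", c(2.15, 7.20, 12.35)),
    acetate   = buffer_definition("acetate", 4.76)
  )
  if (is.null(name)) {
    return(presets)
  }
  if (!name %in% names(presets)) {
    abort(sprintf(
      "Unknown buffer preset '%s' (available: %s).",
      name, paste(names(presets), collapse = ", ")
    ))
  }
  presets[[name]]
}

#' Read buffer definitions from a YAML config
#'
#' The file holds a list of buffers, each with `name`, `pKa` (list) and
#' optionally `counterion_charge`.
#'
#' @param path Path to a YAML file.
#' @return Named list of [buffer_definition()] objects.
#' @export
read_buffer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$buffers)) cfg$buffers else cfg
  defs <- lapply(entries, function(b) {
    buffer_definition(
      name = b$name,
      pKa = unlist(b$pKa),
      counterion_charge = b$counterion_charge %||% 1L
    )
  })
  setNames(defs, vapply(defs, function(d) d$name, character(1)))
}

as_buffer <- function(buffer) {
  if (inherits(buffer, "buffer_definition")) {
    return(buffer)
  }
  if (is.character(buffer) && length(buffer) == 1L) {
    return(buffer_presets(buffer))
  }
  abort("`buffer` must be a buffer_definition or a preset name.")
}

# Degree-of-deprotonation fractions alpha_j (j = 0..n) of an n-protic acid,
# computed in log10 space for numerical stability at extreme pH.
alpha_fractions <- function(pKa, ph) {
  log_t <- c(0, cumsum(ph - pKa)) # log10 of [H]^{-j} prod Ka_i, up to a constant
  t <- 10^(log_t - max(log_t))
  t / sum(t)
}

species_labels <- function(n, j) {
  # j protons removed out of n: H_{n-j}A^{j-}
  h <- n - j
  h_part <- ifelse(h == 0L, "", ifelse(h == 1L, "H", paste0("H", h)))
  charge <- ifelse(j == 0L, "", ifelse(j == 1L, "-", paste0(j, "-")))
  paste0(h_part, "A", charge)
}

#' Speciate a polyprotic buffer at given pH
#'
#' Closed-form Henderson-Hasselbalch speciation: the fraction of the buffer in
#' deprotonation state `j` (charge `-j`) follows the standard polyprotic
#' alpha-fraction expressions. The counterion (sodium) concentration is
#' assigned by electroneutrality, including the hydronium/hydroxide
#' contribution unless disabled. Should charge balance require a negative
#' counterion concentration (strong-acid regime), the balancing ion is
#' reported as a monovalent co-ion (`Cl-`) instead.
#'
#' @param buffer A [buffer_definition()] or preset name (`"citrate"`,
#'   `"phosphate"`, `"acetate"`).
#' @param ph pH value(s), in `[0, 14]`. Vectorized.
#' @param c_total Total buffer concentration in mM (single positive number,
#'   or zero).
#' @param include_water_ions Include H+ and OH- rows and their contribution to
#'   the charge balance (default `TRUE`; negligible between pH 3.5 and 7.5).
#'
#' @return A tibble of class `speciation` with one row per ionic species and
#'   pH: columns `buffer`, `ph`, `c_total_mM`, `role` (`"buffer"`,
#'   `"counterion"` or `"water"`), `species`, `level` (protons removed),
#'   `charge` and `conc_mM`.
#' @export
#' @examples
#' speciate("acetate", ph = 4.76, c_total = 50)
#' speciate("citrate", ph = 5.5, c_total = 50)
speciate <- function(buffer, ph, c_total, include_water_ions = TRUE) {
  buffer <- as_buffer(buffer)
  if (!is.numeric(ph) || anyNA(ph) || any(ph < 0 | ph > 14)) {
    abort("`ph` must be numeric in [0, 14].")
  }
  if (!is.numeric(c_total) || length(c_total) != 1L || c_total < 0) {
    abort("`c_total` must be a single non-negative number (mM).")
  }
  n <- buffer$max_deprotonation
  rows <- map(ph, function(p) {
    a <- alpha_fractions(buffer$pKa, p)
    j <- 0:n
    conc <- c_total * a
    h_mM <- 10^(-p) * 1000
    oh_mM <- 10^(-(14 - p)) * 1000
    net_negative <- sum(j * conc) +
      if (include_water_ions) oh_mM - h_mM else 0
    z_c <- buffer$counterion_charge
    c_counter <- net_negative / z_c
    if (c_counter >= 0) {
      counter <- tibble(
        role = "counterion", species = buffer$counterion,
        level = NA_integer_, charge = as.numeric(z_c), conc_mM = c_counter
      )
    } else {
      counter <- tibble(
        role = "counterion", species = "Cl-",
        level = NA_integer_, charge = -1, conc_mM = -net_negative
      )
    }
    out <- bind_rows(
      tibble(
        role = "buffer", species = species_labels(n, j),
        level = as.integer(j), charge = -as.numeric(j), conc_mM = conc
      ),
      counter,
      if (include_water_ions) {
        tibble(
          role = "water", species = c("H+", "OH-"),
          level = NA_integer_, charge = c(1, -1), conc_mM = c(h_mM, oh_mM)
        )
      }
    )
    mutate(out, buffer = buffer$name, ph = p, c_total_mM = c_total,
           .before = 1)
  })
  out <- list_rbind(rows)
  class(out) <- c("speciation", class(out))
  out
}

#' Mean valency (average charge magnitude) of a buffer versus pH
#'
#' The average number of charges per buffer molecule,
#' `sum_j j * alpha_j(pH)`. For an acid this is non-decreasing in pH, running
#' from 0 (fully protonated) to the number of acidic protons.
#'
#' @inheritParams speciate
#' @param ph Numeric vector of pH values (the grid).
#' @return A tibble with columns `buffer`, `ph`, `valency`.
#' @export
#' @examples
#' mean_valency("citrate", ph = seq(3, 8, by = 0.5))
mean_valency <- function(buffer, ph) {
  buffer <- as_buffer(buffer)
  if (length(ph) < 1L) {
    abort("`ph` grid must be non-empty.")
  }
  val <- map_dbl(ph, function(p) {
    a <- alpha_fractions(buffer$pKa, p)
    sum((0:buffer$max_deprotonation) * a)
  })
  tibble(buffer = buffer$name, ph = as.numeric(ph), valency = val)
}

#' Background electrolyte helper
#'
#' Convenience constructor for the background-salt table consumed by
#' [ionic_strength()]: a fully dissociated 1:1 sodium chloride solution.
#'
#' @param nacl_mM NaCl concentration in mM.
#' @return Tibble with columns `species`, `charge`, `conc_mM`.
#' @export
#' @examples
#' nacl_background(150)
nacl_background <- function(nacl_mM) {
  tibble(
    species = c("Na+", "Cl-"),
    charge = c(1, -1),
    conc_mM = as.numeric(nacl_mM)
  )
}

#' Ionic strength of a speciated buffer
#'
#' Computes `I = 1/2 * sum(c_i * z_i^2)` over every ionic species of a
#' [speciate()] result plus any background electrolyte. Neutral buffer species
#' (charge 0) contribute nothing.
#'
#' @param spec A `speciation` tibble from [speciate()] (may hold several pH
#'   values), or `NULL` for background-only calculations.
#' @param background Optional tibble with columns `charge` and `conc_mM`
#'   (see [nacl_background()]).
#' @return A tibble with one row per (buffer, ph, c_total) group: columns
#'   `buffer`, `ph`, `c_total_mM`, `I_mM`, `background_included`, and a
#'   `contributions` list-column of per-ion `c*z^2/2` terms.
#' @export
#' @examples
#' ionic_strength(speciate("citrate", 5.5, 50))
#' ionic_strength(speciate("acetate", 5.5, 50), background = nacl_background(150))
ionic_strength <- function(spec, background = NULL) {
  if (!is.null(background)) {
    check_columns(background, c("charge", "conc_mM"), "background")
  }
  bg <- if (is.null(background)) {
    tibble(species = character(), charge = numeric(), conc_mM = numeric())
  } else {
    as_tibble(background)
  }
  if (is.null(spec)) {
    contrib <- mutate(bg, term_mM = 0.5 * .data$conc_mM * .data$charge^2)
    return(tibble(
      buffer = NA_character_, ph = NA_real_, c_total_mM = 0,
      I_mM = sum(contrib$term_mM),
      background_included = !is.null(background),
      contributions = list(contrib)
    ))
  }
  check_columns(spec, c("buffer", "ph", "c_total_mM", "species", "charge",
                        "conc_mM"), "spec")
  spec |>
    group_by(.data$buffer, .data$ph, .data$c_total_mM) |>
    dplyr::group_modify(function(rows, key) {
      contrib <- bind_rows(
        select(rows, "species", "charge", "conc_mM"),
        bg
      ) |>
        mutate(term_mM = 0.5 * .data$conc_mM * .data$charge^2)
      tibble(
        I_mM = sum(contrib$term_mM),
        background_included = !is.null(background),
        contributions = list(contrib)
      )
    }) |>
    ungroup()
}

#' Buffer concentration needed to reach a target ionic strength
#'
#' At fixed pH the buffer's contribution to the ionic strength is exactly
#' linear in the total buffer concentration, so a two-point evaluation gives
#' the answer directly; the only departure from linearity is the kink where
#' the counterion demanded by electroneutrality changes sign (relevant only
#' at extreme pH), which is handled by a bisection refinement. Used to design
#' series at matched ionic strength on top of a background salt (e.g. NaCl
#' 150 mM, targets 160 / 200 / 300 mM).
#'
#' @inheritParams speciate
#' @param I_target Target ionic strength in mM. Must be at least the ionic
#'   strength of the background (plus water ions) alone.
#' @param background Optional background electrolyte tibble
#'   (see [nacl_background()]).
#' @return One-row tibble: `buffer`, `ph`, `I_target_mM`, `c_total_mM`,
#'   `I_achieved_mM`.
#' @export
#' @examples
#' concentration_for_ionic_strength("acetate", 5.5, 160,
#'   background = nacl_background(150))
concentration_for_ionic_strength <- function(buffer, ph, I_target,
                                             background = NULL,
                                             include_water_ions = TRUE) {
  buffer <- as_buffer(buffer)
  I_at <- function(c_tot) {
    ionic_strength(
      speciate(buffer, ph, c_tot, include_water_ions = include_water_ions),
      background = background
    )$I_mM
  }
  I0 <- I_at(0)
  if (I_target < I0 - 1e-9) {
    abort(sprintf(
      "I_target (%.3f mM) is below the background contribution (%.3f mM).",
      I_target, I0
    ))
  }
  if (abs(I_target - I0) <= 1e-9 * max(I_target, 1)) {
    # background alone already meets the target
    return(tibble(
      buffer = buffer$name, ph = as.numeric(ph),
      I_target_mM = as.numeric(I_target), c_total_mM = 0,
      I_achieved_mM = I0
    ))
  }
  # linear solve away from c = 0 (exact on the branch), then refine across
  # the counterion sign-change kink if necessary
  slope <- I_at(2) - I_at(1)
  c_total <- max(0, 1 + (I_target - I_at(1)) / slope)
  if (abs(I_at(c_total) - I_target) > 1e-9 * max(I_target, 1)) {
    upper <- max(c_total * 2, 1)
    while (I_at(upper) < I_target) upper <- upper * 2
    c_total <- stats::uniroot(function(c) I_at(c) - I_target,
                              c(0, upper), tol = 1e-12)$root
  }
  tibble(
    buffer = buffer$name, ph = as.numeric(ph),
    I_target_mM = as.numeric(I_target),
    c_total_mM = c_total,
    I_achieved_mM = I_at(c_total)
  )
}
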