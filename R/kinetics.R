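# Single-cell GFP expression summaries: onset time, area under the curve,
# two-exponential model fits, per-condition aggregation and relative
# transfection efficiency.

traj_cols <- c("cell_id", "time_h", "fluorescence")

check_trajectories <- function(data) {
  check_columns(data, traj_cols, "data")
  invisible(data)
}

#' Read single-cell trajectories from CSV
#'
#' Expects columns `cell_id`, `condition`, `time_h`, `fluorescence`.
#'
#' @param path CSV file path.
#' @return A tibble of trajectories.
#' @export
read_trajectories <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  check_trajectories(data)
  data
}

per_cell_baseline <- function(time_h, fluorescence, baseline_window) {
  idx <- time_h >= baseline_window[1] & time_h <= baseline_window[2]
  if (!any(idx)) idx <- seq_along(time_h) == 1L
  c(mean(fluorescence[idx]), stats::sd(fluorescence[idx]))
}

#' Area under the expression curve per cell
#'
#' Trapezoidal integral of the baseline-subtracted fluorescence over an
#' integration window; the per-cell baseline is the mean fluorescence over
#' `baseline_window`, and negative excursions are clipped at zero before
#' integration.
#'
#' @param data Trajectory tibble with columns `cell_id`, `time_h`,
#'   `fluorescence` (and optionally `condition`).
#' @param window Integration window `(t_start, t_end)` in hours (default
#'   `c(0, 30)`); clipped to the observation span with a warning if it
#'   extends beyond it.
#' @param baseline_window Window used for the per-cell baseline (default the
#'   first hour). Use `NULL` to skip baseline subtraction.
#' @return Tibble: `cell_id` (and `condition` if present), `auc`
#'   (a.u. * hours), `peak_fluorescence`.
#' @export
#' @examples
#' pop <- simulate_trajectories(population_params(n_cells = 2), seed = 1)
#' compute_auc(pop$trajectories)
compute_auc <- function(data, window = c(0, 30), baseline_window = c(0, 1)) {
  check_trajectories(data)
  grouping <- intersect(c("condition", "cell_id"), names(data))
  data |>
    group_by(across(all_of(grouping))) |>
    dplyr::group_modify(function(rows, key) {
      t <- rows$time_h
      f <- rows$fluorescence
      if (is.unsorted(t, strictly = TRUE)) {
        ord <- order(t)
        t <- t[ord]
        f <- f[ord]
      }
      if (length(t) < 2L) {
        abort("Each trajectory needs at least 2 samples.")
      }
      if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9) {
        warn("Integration window extends beyond the observation span; clipping.")
      }
      lo <- max(window[1], t[1])
      hi <- min(window[2], t[length(t)])
      if (hi <= lo) {
        abort("Integration window does not overlap the trajectory.")
      }
      base <- if (is.null(baseline_window)) {
        0
      } else {
        per_cell_baseline(t, f, baseline_window)[1]
      }
      g <- pmax(f - base, 0)
      # restrict to window, interpolating the end points onto the grid
      tt <- sort(unique(c(lo, t[t > lo & t < hi], hi)))
      gg <- approx(t, g, xout = tt)$y
      auc <- sum(diff(tt) * (utils::head(gg, -1) + utils::tail(gg, -1)) / 2)
      tibble(auc = auc, peak_fluorescence = max(f))
    }) |>
    ungroup()
}

#' Expression onset time per cell
#'
#' The onset is the first time the fluorescence exceeds
#' `baseline mean + k * baseline sd` for `persistence` consecutive samples,
#' linearly interpolated to the threshold crossing. Cells that never show a
#' sustained crossing get `NA` (a valid result: no detectable expression).
#'
#' @inheritParams compute_auc
#' @param k Threshold multiplier on the baseline standard deviation
#'   (default 3).
#' @param persistence Number of consecutive super-threshold samples required
#'   (default 3).
#' @return Tibble: `cell_id` (and `condition`), `onset_h` (hours or `NA`).
#' @export
estimate_onset <- function(data, baseline_window = c(0, 1), k = 3,
                           persistence = 3) {
  check_trajectories(data)
  grouping <- intersect(c("condition", "cell_id"), names(data))
  data |>
    group_by(across(all_of(grouping))) |>
    dplyr::group_modify(function(rows, key) {
      t <- rows$time_h
      f <- rows$fluorescence
      bs <- per_cell_baseline(t, f, baseline_window)
      thr <- bs[1] + k * (if (is.na(bs[2])) 0 else bs[2])
      above <- f > thr
      run <- 0L
      onset <- NA_real_
      for (i in seq_along(above)) {
        run <- if (above[i]) run + 1L else 0L
        if (run >= persistence) {
          j <- i - persistence + 1L # first sample of the sustained run
          if (j == 1L) {
            onset <- t[1]
          } else {
            # linear interpolation between the last sub-threshold sample and
            # the first super-threshold one
            f0 <- f[j - 1L]
            f1 <- f[j]
            frac <- if (f1 > f0) (thr - f0) / (f1 - f0) else 0
            frac <- min(1, max(0, frac))
            onset <- t[j - 1L] + frac * (t[j] - t[j - 1L])
          }
          break
        }
      }
      tibble(onset_h = onset)
    }) |>
    ungroup()
}

#' Fit the two-exponential expression model per cell
#'
#' Least-squares fit of
#' `G(t) = A * (exp(-gamma*(t-t0)) - exp(-delta*(t-t0)))` for `t >= t0`
#' (0 before) by Levenberg-Marquardt, with the rate ordering `delta > gamma`
#' enforced by parameterising `delta = gamma + exp(log_rate_gap)` (the curve
#' is symmetric under swapping the rates, so the ordering fixes the labels).
#' Start values come from the threshold onset, the peak height and the peak
#' time. Non-convergence is reported per cell via `converged = FALSE`.
#'
#' @inheritParams estimate_onset
#' @return Tibble per cell: `amplitude`, `t0`, `gamma`, `delta`, `rss`,
#'   `converged`.
#' @export
fit_expression_model <- function(data, baseline_window = c(0, 1)) {
  check_trajectories(data)
  grouping <- intersect(c("condition", "cell_id"), names(data))
  onsets <- estimate_onset(data, baseline_window = baseline_window)
  data |>
    group_by(across(all_of(grouping))) |>
    dplyr::group_modify(function(rows, key) {
      t <- rows$time_h
      f <- rows$fluorescence
      onset0 <- onsets$onset_h[match(key$cell_id, onsets$cell_id)]
      fail <- tibble(amplitude = NA_real_, t0 = NA_real_,
                     gamma = NA_real_, delta = NA_real_,
                     rss = NA_real_, converged = FALSE)
      if (is.na(onset0)) {
        return(fail)
      }
      i_peak <- which.max(f)
      t_peak <- max(t[i_peak] - onset0, 0.5)
      delta0 <- 2 / t_peak
      gamma0 <- delta0 / 5
      A0 <- max(f) / 0.7
      fit <- tryCatch(
        minpack.lm::nlsLM(
          fluor ~ expression_curve(tt, A, t0, gamma, gamma + exp(lgap)),
          data = list(fluor = f, tt = t),
          start = list(A = A0, t0 = onset0, gamma = gamma0,
                       lgap = log(delta0 - gamma0)),
          lower = c(0, 0, 1e-4, -10),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL,
        warning = function(w) NULL
      )
      if (is.null(fit)) {
        return(fail)
      }
      p <- coef(fit)
      tibble(
        amplitude = unname(p["A"]), t0 = unname(p["t0"]),
        gamma = unname(p["gamma"]),
        delta = unname(p["gamma"] + exp(p["lgap"])),
        rss = sum(stats::resid(fit)^2), converged = TRUE
      )
    }) |>
    ungroup()
}

#' Summarise expression per condition
#'
#' Aggregates per-cell AUC and onset by condition: cells without a detected
#' onset are excluded from the onset mean but still counted in `n_cells` and
#' contribute their (possibly near-zero) AUC to the efficiency means, so the
#' condition mean reflects the whole observed population. `sem = sd/sqrt(n)`.
#'
#' @inheritParams estimate_onset
#' @param window,baseline_window Passed to [compute_auc()] /
#'   [estimate_onset()].
#' @param k,persistence Onset detector settings.
#' @return Tibble per condition: `n_cells`, `mean_auc`, `sem_auc`,
#'   `n_onset`, `mean_onset`, `sem_onset`.
#' @export
#' @examples
#' pop <- simulate_trajectories(population_params(n_cells = 10), seed = 1)
#' summarize_condition(pop$trajectories)
summarize_condition <- function(data, window = c(0, 30),
                                baseline_window = c(0, 1), k = 3,
                                persistence = 3) {
  check_trajectories(data)
  if (!"condition" %in% names(data)) {
    data$condition <- "all"
  }
  aucs <- compute_auc(data, window = window,
                      baseline_window = baseline_window)
  onsets <- estimate_onset(data, baseline_window = baseline_window, k = k,
                           persistence = persistence)
  cells <- left_join(aucs, onsets, by = c("condition", "cell_id"))
  cells |>
    group_by(.data$condition) |>
    summarise(
      n_cells = n(),
      mean_auc = mean(.data$auc),
      sem_auc = stats::sd(.data$auc) / sqrt(n()),
      n_onset = sum(!is.na(.data$onset_h)),
      mean_onset = mean(.data$onset_h, na.rm = TRUE),
      sem_onset = stats::sd(.data$onset_h, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$onset_h))),
      .groups = "drop"
    )
}

#' Relative transfection efficiency across conditions
#'
#' Adds `relative_efficiency = mean_auc / mean_auc(reference)`; the reference
#' condition is exactly 1.
#'
#' @param summaries Output of [summarize_condition()] (rows for several
#'   conditions).
#' @param reference Reference condition name (default `"citrate"`).
#' @return `summaries` with a `relative_efficiency` column.
#' @export
relative_efficiency <- function(summaries, reference = "citrate") {
  check_columns(summaries, c("condition", "mean_auc"), "summaries")
  if (!reference %in% summaries$condition) {
    abort(sprintf("Reference condition '%s' not present.", reference))
  }
  ref <- summaries$mean_auc[summaries$condition == reference][1]
  if (!is.finite(ref) || ref == 0) {
    abort("Reference condition has zero mean AUC.")
  }
  mutate(summaries, relative_efficiency = .data$mean_auc / ref)
}
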