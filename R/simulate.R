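# Seeded generators for every input the analysis consumes: powder-like 1D
# SAXS profiles with known phase ground truth, pH series emulating the
# buffer-specific phase diagrams, and single-cell GFP expression trajectories.
# All generators are pure functions of (parameters, seed).

#' Ground truth for one synthetic SAXS profile
#'
#' @param group_id Space group id from [space_group_registry()], or
#'   `"L_II_disordered"` for a single broad correlation peak.
#' @param lattice_a Lattice constant in nm (for L_II: the correlation
#'   distance `2*pi/q` of the broad peak).
#' @param lattice_c P63/mmc only; default ideal `a * sqrt(8/3)`.
#' @param peak_width Relative FWHM of Bragg peaks (default 0.008; L_II uses
#'   `max(peak_width, 0.15)`).
#' @param decay_exponent Peak-height envelope exponent: heights scale as
#'   `(q1/q)^decay_exponent` (default 2; no measured form factors are
#'   emulated).
#' @param background_level Smooth background amplitude relative to the first
#'   peak height (default 0.05).
#' @param noise_sd_fraction Gaussian noise standard deviation as a fraction of
#'   the local (signal + background) intensity (default 0.02).
#' @param n_reflections Number of reflections to generate (default 6).
#' @param eta Lorentzian fraction of the pseudo-Voigt peak shape
#'   (default 0.5).
#' @return A `phase_truth` list.
#' @export
phase_truth <- function(group_id, lattice_a, lattice_c = NULL,
                        peak_width = 0.008, decay_exponent = 2,
                        background_level = 0.05, noise_sd_fraction = 0.02,
                        n_reflections = 6, eta = 0.5) {
  stopifnot(lattice_a > 0, peak_width > 0, background_level >= 0,
            noise_sd_fraction >= 0, eta >= 0, eta <= 1)
  structure(
    list(
      group_id = group_id, lattice_a = lattice_a,
      lattice_c = lattice_c %||%
        if (group_id == "P63mmc") lattice_a * sqrt(8 / 3) else NA_real_,
      peak_width = peak_width, decay_exponent = decay_exponent,
      background_level = background_level,
      noise_sd_fraction = noise_sd_fraction,
      n_reflections = n_reflections, eta = eta
    ),
    class = "phase_truth"
  )
}

pseudo_voigt <- function(q, q0, fwhm, eta) {
  hw <- fwhm / 2
  lor <- 1 / (1 + ((q - q0) / hw)^2)
  gau <- exp(-log(2) * ((q - q0) / hw)^2)
  eta * lor + (1 - eta) * gau
}

truth_positions <- function(truth) {
  if (truth$group_id == "L_II_disordered") {
    return(2 * pi / truth$lattice_a)
  }
  predicted_positions(truth$group_id, truth$lattice_a, truth$lattice_c,
                      n_reflections = truth$n_reflections)$q
}

signal_on_grid <- function(truth, q) {
  q0 <- truth_positions(truth)
  if (truth$group_id == "L_II_disordered") {
    width <- max(truth$peak_width, 0.15)
    return(pseudo_voigt(q, q0, width * q0, truth$eta))
  }
  heights <- (q0[1] / q0)^truth$decay_exponent
  sig <- rep(0, length(q))
  for (j in seq_along(q0)) {
    sig <- sig + heights[j] *
      pseudo_voigt(q, q0[j], truth$peak_width * q0[j], truth$eta)
  }
  sig
}

default_q_grid <- function(truths, n = 1500) {
  pos <- unlist(lapply(truths, truth_positions))
  if (length(pos) == 1L) {
    # single broad correlation peak: leave room for its wide tails
    return(seq(0.4 * pos, 1.8 * pos, length.out = n))
  }
  seq(0.55 * min(pos), 1.15 * max(pos), length.out = n)
}

#' Generate a synthetic 1D SAXS profile
#'
#' Pseudo-Voigt Bragg peaks at the phase's predicted positions with a
#' `q^-decay` height envelope, a smooth power-law background, and seeded
#' Gaussian noise proportional to the local intensity. Deterministic for a
#' fixed seed.
#'
#' @param truth A [phase_truth()], or a list of them for a coexisting-phase
#'   profile (their patterns are summed).
#' @param q_grid Scattering vector grid (nm^-1); default covers
#'   `0.55 * q_first` to `1.15 * q_last` of all reflections with 1500 points.
#' @param seed Integer seed.
#' @param buffer,ph,label Metadata stamped on the profile.
#' @return A `saxs_profile` tibble; the ground truth is attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' prof <- simulate_saxs_profile(phase_truth("H_II_p6mm", 6), seed = 7)
simulate_saxs_profile <- function(truth, q_grid = NULL, seed = 1,
                                  buffer = NA_character_, ph = NA_real_,
                                  label = NA_character_) {
  truths <- if (inherits(truth, "phase_truth")) list(truth) else truth
  stopifnot(all(vapply(truths, inherits, logical(1), "phase_truth")))
  q <- q_grid %||% default_q_grid(truths)
  pos <- unlist(lapply(truths, truth_positions))
  covered <- vapply(truths, function(tr) {
    p <- truth_positions(tr)
    need <- p[seq_len(min(3, length(p)))]
    min(q) <= min(need) && max(q) >= max(need)
  }, logical(1))
  if (!all(covered)) {
    abort("`q_grid` must cover at least the first three reflections of every phase.")
  }
  sig <- Reduce(`+`, lapply(truths, signal_on_grid, q = q))
  bg <- truths[[1]]$background_level * (min(pos) / q)
  clean <- sig + bg
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  noise <- rnorm(length(q), sd = truths[[1]]$noise_sd_fraction * clean)
  out <- saxs_profile(q, clean + noise, buffer = buffer, ph = ph,
                      label = label)
  attr(out, "truth") <- truths
  attr(out, "seed") <- seed
  out
}

#' Buffer-specific pH series ground truth
#'
#' The per-pH phase sequences observed for MC3/cholesterol mesophases in the
#' three buffers (pH 7.5 to 3.5 in 0.5 steps): in citrate, P63/mmc at pH 7.0
#' and Fd3m at pH 6.5 give way to the inverse hexagonal phase from pH 6.0
#' downward; in acetate the same sequence is shifted down by half a unit with
#' H_II from pH 5.0; phosphate stays disordered micellar from pH 7.5 to 6.0,
#' shows a mixed P63/mmc + Fd3m cell at pH 5.5 and H_II from pH 5.0.
#' Representative lattice constants are used (H_II a ~ 6 nm growing gently as
#' pH decreases, Fd3m a = 15 nm, P63/mmc a = 7 nm at the ideal axial ratio,
#' L_II correlation distance 5.5 nm).
#'
#' @param buffers Which buffers to include.
#' @return Tibble with columns `buffer`, `ph` and a `truths` list-column
#'   (each element a list of [phase_truth()] objects; more than one means
#'   coexistence).
#' @export
phase_series_presets <- function(buffers = c("citrate", "acetate",
                                             "phosphate")) {
  buffers <- match.arg(buffers, several.ok = TRUE)
  ph_grid <- seq(7.5, 3.5, by = -0.5)
  hii <- function(ph) {
    list(phase_truth("H_II_p6mm", 6.0 + 0.12 * (6.0 - ph)))
  }
  l2 <- list(phase_truth("L_II_disordered", 5.5))
  p63 <- list(phase_truth("P63mmc", 7.0))
  fd3m <- list(phase_truth("Fd3m", 15.0))
  truth_for <- function(buffer, ph) {
    if (buffer == "citrate") {
      if (ph >= 7.5) l2
      else if (ph == 7.0) p63
      else if (ph == 6.5) fd3m
      else hii(ph)
    } else if (buffer == "acetate") {
      if (ph >= 7.0) l2
      else if (ph == 6.5) p63
      else if (ph %in% c(6.0, 5.5)) fd3m
      else hii(ph)
    } else {
      if (ph >= 6.0) l2
      else if (ph == 5.5) c(p63, fd3m)
      else hii(ph)
    }
  }
  grid <- tidyr::expand_grid(buffer = buffers, ph = ph_grid)
  grid$truths <- pmap(grid, function(buffer, ph) truth_for(buffer, ph))
  grid
}

#' Generate a synthetic SAXS series over a (buffer, pH) grid
#'
#' One profile per row of the series specification; entries with several
#' phase truths produce summed (coexisting) patterns. Per-profile sub-seeds
#' are derived from `seed` by row offset, so the whole series is reproducible
#' from `(spec, seed)`.
#'
#' @param series Tibble with columns `buffer`, `ph`, `truths` (list-column of
#'   lists of [phase_truth()]), e.g. from [phase_series_presets()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory: profiles are written as two-column text
#'   plus a `manifest.csv` mapping file to (buffer, ph, group ids, seed).
#' @return The series tibble with list-column `profile` added (and `file` if
#'   written).
#' @export
simulate_phase_series <- function(series, seed = 1, out_dir = NULL) {
  check_columns(series, c("buffer", "ph", "truths"), "series")
  if (nrow(series) == 0L) {
    abort("`series` must be non-empty.")
  }
  series$profile <- pmap(
    list(series$buffer, series$ph, series$truths, seq_len(nrow(series))),
    function(buffer, ph, truths, i) {
      simulate_saxs_profile(
        truths, seed = seed + i,
        buffer = buffer, ph = ph,
        label = sprintf("%s_pH%.1f", buffer, ph)
      )
    }
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    series$file <- map_chr2(series$profile, function(p) {
      f <- file.path(out_dir, paste0(attr(p, "label"), ".dat"))
      write_saxs_profile(p, f)
      f
    })
    manifest <- tibble(
      file = series$file, buffer = series$buffer, ph = series$ph,
      truth_groups = map_chr2(series$truths, function(tr) {
        paste(vapply(tr, function(x) x$group_id, character(1)),
              collapse = "+")
      }),
      seed = seed + seq_len(nrow(series))
    )
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  series
}

map_chr2 <- function(x, f) vapply(x, f, character(1))

#' Population parameters for synthetic expression trajectories
#'
#' Single-cell GFP expression is modelled as
#' `G(t) = A * (exp(-gamma*(t - t0)) - exp(-delta*(t - t0)))` for `t >= t0`
#' (0 before onset): a translation/maturation rise at rate `delta` and a
#' slower decay at rate `gamma`, with cell-to-cell variability in amplitude
#' (lognormal `A`) and onset time (normal truncated at 0). Defaults emulate a
#' 30 h live-cell experiment sampled every 10 min.
#'
#' @param n_cells Number of cells.
#' @param amplitude_meanlog,amplitude_sdlog Lognormal amplitude parameters
#'   (a.u.).
#' @param onset_mean,onset_sd Onset-time distribution in hours (truncated at
#'   0).
#' @param gamma Decay rate (1/h), `0 < gamma < delta`.
#' @param delta Rise rate (1/h).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param dt Sampling interval in hours (default 1/6 h = 10 min).
#' @param duration Observation span in hours (default 30).
#' @return A `population_params` list.
#' @export
population_params <- function(n_cells = 200,
                              amplitude_meanlog = log(500),
                              amplitude_sdlog = 0.5,
                              onset_mean = 4, onset_sd = 2,
                              gamma = 0.05, delta = 0.3,
                              noise_sd = 5, dt = 1 / 6, duration = 30) {
  stopifnot(n_cells >= 1, delta > gamma, gamma > 0, duration > onset_mean,
            dt > 0, noise_sd >= 0, onset_sd >= 0)
  structure(
    list(
      n_cells = as.integer(n_cells),
      amplitude_meanlog = amplitude_meanlog,
      amplitude_sdlog = amplitude_sdlog,
      onset_mean = onset_mean, onset_sd = onset_sd,
      gamma = gamma, delta = delta, noise_sd = noise_sd,
      dt = dt, duration = duration
    ),
    class = "population_params"
  )
}

#' Two-exponential expression curve
#'
#' `A * (exp(-gamma*(t-t0)) - exp(-delta*(t-t0)))` for `t >= t0`, zero
#' before; the degenerate `delta == gamma` limit
#' `A * gamma * (t-t0) * exp(-gamma*(t-t0))` is used when the rates are
#' within relative 1e-8.
#'
#' @param t Times (h).
#' @param A Amplitude (a.u.).
#' @param t0 Onset (h).
#' @param gamma,delta Decay and rise rates (1/h).
#' @return Fluorescence values.
#' @export
expression_curve <- function(t, A, t0, gamma, delta) {
  tau <- pmax(0, t - t0)
  if (abs(delta - gamma) <= 1e-8 * max(gamma, delta)) {
    out <- A * gamma * tau * exp(-gamma * tau)
  } else {
    out <- A * (exp(-gamma * tau) - exp(-delta * tau))
  }
  out[t < t0] <- 0
  out
}

# Exact integral of expression_curve from t0 to t_end (>= t0)
expression_curve_integral <- function(A, t0, gamma, delta, t_end) {
  tau <- pmax(0, t_end - t0)
  if (abs(delta - gamma) <= 1e-8 * max(gamma, delta)) {
    g <- gamma
    return(A * (1 / g - (tau + 1 / g) * exp(-g * tau)))
  }
  A * ((1 - exp(-gamma * tau)) / gamma - (1 - exp(-delta * tau)) / delta)
}

#' Generate a synthetic single-cell trajectory population
#'
#' @param params A [population_params()].
#' @param seed Integer seed (per-cell sub-seeds derived by offset).
#' @param condition Condition label stamped on every cell.
#' @return A list with `trajectories` (long tibble: `cell_id`, `condition`,
#'   `time_h`, `fluorescence`) and `truth` (per-cell tibble: `cell_id`,
#'   `amplitude`, `onset_h`, `gamma`, `delta`, `auc_exact` — the closed-form
#'   integral of the noise-free curve over the observation window).
#' @export
#' @examples
#' pop <- simulate_trajectories(population_params(n_cells = 3), seed = 1)
#' head(pop$trajectories)
simulate_trajectories <- function(params, seed = 1, condition = "synthetic") {
  stopifnot(inherits(params, "population_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n <- params$n_cells
  A <- rlnorm(n, params$amplitude_meanlog, params$amplitude_sdlog)
  t0 <- pmax(0, rnorm(n, params$onset_mean, params$onset_sd))
  times <- seq(0, params$duration, by = params$dt)
  ids <- sprintf("cell_%03d", seq_len(n))
  traj <- map(seq_len(n), function(i) {
    g <- expression_curve(times, A[i], t0[i], params$gamma, params$delta)
    if (params$noise_sd > 0) {
      g <- g + rnorm(length(times), sd = params$noise_sd)
    }
    tibble(cell_id = ids[i], condition = condition, time_h = times,
           fluorescence = g)
  })
  truth <- tibble(
    cell_id = ids, condition = condition, amplitude = A, onset_h = t0,
    gamma = params$gamma, delta = params$delta,
    auc_exact = vapply(seq_len(n), function(i) {
      expression_curve_integral(A[i], t0[i], params$gamma, params$delta,
                                params$duration)
    }, numeric(1))
  )
  list(trajectories = list_rbind(traj), truth = truth, seed = seed)
}
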