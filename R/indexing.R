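# Phase identification from relative Bragg peak positions.
#
# For one-parameter groups the least-squares lattice constant has a closed
# form: with predicted q_i = s_i / a, minimizing sum (q_obs,i - s_i/a)^2
# gives 1/a = sum(s_i q_i) / sum(s_i^2). For P63/mmc, q^2 is linear in
# (1/a^2, 1/c^2) and the two parameters come from an exact normal-equation
# solve.

match_greedy <- function(q_obs, q_pred, tolerance) {
  # one observed peak per predicted reflection, nearest-first, within
  # relative tolerance |q_obs - q_pred| / q_pred <= tolerance
  assignment <- rep(NA_integer_, length(q_pred))
  used <- rep(FALSE, length(q_obs))
  ord <- order(q_pred)
  for (j in ord) {
    rel <- abs(q_obs - q_pred[j]) / q_pred[j]
    rel[used] <- Inf
    i <- which.min(rel)
    if (length(i) == 1L && is.finite(rel[i]) && rel[i] <= tolerance) {
      assignment[j] <- i
      used[i] <- TRUE
    }
  }
  assignment
}

#' Least-squares lattice fit for an indexed peak set
#'
#' @param peaks A `peak_list` (or tibble with a `q` column).
#' @param group_id Space group id from [space_group_registry()].
#' @param reflection_idx Integer vector: for each peak (row of `peaks`), the
#'   row of the group's reflection table it is indexed as.
#' @param registry Registry tibble.
#' @return A list with `lattice_a`, `lattice_c` (NA unless P63/mmc),
#'   `rms_relative_residual`, and the matched predicted positions `q_pred`.
#' @export
#' @examples
#' pk <- tibble::tibble(q = predicted_positions("H_II_p6mm", 6)$q[1:3])
#' fit_lattice(pk, "H_II_p6mm", 1:3)
fit_lattice <- function(peaks, group_id, reflection_idx,
                        registry = space_group_registry()) {
  check_columns(peaks, "q", "peaks")
  row <- match(group_id, registry$group_id)
  if (is.na(row)) {
    abort(sprintf("Unknown space group '%s'.", group_id))
  }
  refl <- registry$reflections[[row]]
  n_par <- registry$n_params[row]
  q_obs <- peaks$q
  if (length(reflection_idx) != length(q_obs)) {
    abort("`reflection_idx` must assign one reflection per peak.")
  }
  if (length(q_obs) < n_par || length(q_obs) < 1L) {
    abort("Too few peaks to determine the lattice parameters.")
  }
  if (group_id == "P63mmc") {
    m <- refl$m[reflection_idx]
    l <- refl$l[reflection_idx]
    X <- cbind(4 * pi^2 * (4 / 3) * m, 4 * pi^2 * l^2)
    yy <- q_obs^2
    if (length(q_obs) >= 3L && qr(X)$rank == 2L) {
      beta <- solve(crossprod(X), crossprod(X, yy))
    } else {
      # underdetermined for two parameters: pin the axial ratio at the ideal
      # hcp value c/a = sqrt(8/3)
      s <- 2 * pi * sqrt((4 / 3) * m + (3 / 8) * l^2)
      a <- sum(s^2) / sum(s * q_obs)
      beta <- c(1 / a^2, 1 / ((8 / 3) * a^2))
    }
    if (any(beta <= 0)) {
      abort("P63/mmc fit produced non-positive lattice parameters.")
    }
    lattice_a <- 1 / sqrt(beta[1])
    lattice_c <- 1 / sqrt(beta[2])
    q_pred <- sqrt(X %*% beta)[, 1]
  } else {
    s <- refl$s[reflection_idx]
    lattice_a <- sum(s^2) / sum(s * q_obs)
    lattice_c <- NA_real_
    q_pred <- s / lattice_a
  }
  list(
    lattice_a = as.numeric(lattice_a),
    lattice_c = as.numeric(lattice_c),
    rms_relative_residual =
      sqrt(mean(((q_obs - q_pred) / q_obs)^2)),
    q_pred = q_pred
  )
}

assignment_tibble <- function(group_id, fit, matched_idx, d_nn, meta = NULL) {
  tibble(
    buffer = meta$buffer %||% NA_character_,
    ph = meta$ph %||% NA_real_,
    label = meta$label %||% NA_character_,
    group_id = group_id,
    lattice_a = fit$lattice_a,
    lattice_c = fit$lattice_c,
    d_nn = d_nn,
    n_matched = length(matched_idx),
    rms_relative_residual = fit$rms_relative_residual,
    matched_peaks = list(as.integer(matched_idx))
  )
}

index_one_candidate <- function(peaks, group_id, registry, tolerance,
                                max_first = 3L) {
  row <- match(group_id, registry$group_id)
  refl <- registry$reflections[[row]]
  min_peaks <- registry$min_peaks[row]
  if (nrow(peaks) < min_peaks || nrow(refl) == 0L) {
    return(NULL)
  }
  q_obs <- peaks$q
  # spacing coefficients at the ideal axial ratio (exact for 1-parameter
  # groups) give the trial lattice constant for each hypothesis about which
  # allowed reflection the first observed peak is
  s_all <- refl$s
  best <- NULL
  for (first in seq_len(min(max_first, nrow(refl)))) {
    a0 <- s_all[first] / q_obs[1]
    fit <- NULL
    for (iter in 1:2) {
      q_pred <- if (group_id == "P63mmc" && !is.null(fit)) {
        2 * pi * sqrt((4 / 3) * refl$m / fit$lattice_a^2 +
                        refl$l^2 / fit$lattice_c^2)
      } else {
        s_all / a0
      }
      assignment <- match_greedy(q_obs, q_pred, tolerance)
      matched_refl <- which(!is.na(assignment))
      matched_obs <- assignment[matched_refl]
      if (length(matched_obs) < min_peaks) {
        fit <- NULL
        break
      }
      fit <- fit_lattice(peaks[matched_obs, , drop = FALSE], group_id,
                         matched_refl, registry = registry)
      a0 <- fit$lattice_a
    }
    if (is.null(fit)) next
    # demand the leading allowed reflection of the fit is actually observed:
    # indexing that skips the strongest low-order reflection is spurious
    if (!1 %in% matched_refl) next
    # an hcp fit must constrain both lattice parameters: at least one basal
    # (l = 0) and one non-basal reflection among the matches, else the
    # pattern is indistinguishable from a plain 2D hexagonal lattice
    if (group_id == "P63mmc" &&
        (all(refl$l[matched_refl] == 0) ||
           all(refl$m[matched_refl] == 0))) {
      next
    }
    cand <- list(fit = fit, matched_obs = matched_obs,
                 matched_refl = matched_refl)
    if (is.null(best) ||
        length(cand$matched_obs) > length(best$matched_obs) ||
        (length(cand$matched_obs) == length(best$matched_obs) &&
           cand$fit$rms_relative_residual < best$fit$rms_relative_residual)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  meta <- attr(peaks, "profile_meta")
  assignment_tibble(
    group_id, best$fit, best$matched_obs,
    d_nn = d_nn(group_id, best$fit$lattice_a, best$fit$lattice_c,
                registry = registry),
    meta = meta
  )
}

#' Nearest-neighbor distance between water cores
#'
#' `d_nn = a` for the inverse hexagonal phase, `factor * a` for the cubic
#' groups (Fd3m default `sqrt(2)/4`), `min(a, sqrt(a^2/3 + c^2/4))` for
#' P63/mmc, and `2*pi/q` of the correlation peak for disordered L_II (pass
#' the peak position as `lattice_a = 2*pi/q` upstream; see
#' [analyze_profile()]).
#'
#' @param group_id Space group id.
#' @param lattice_a Lattice constant (nm); for `L_II_disordered` interpret as
#'   the correlation length `2*pi/q`.
#' @param lattice_c P63/mmc only.
#' @param registry Registry tibble (carries the Fd3m convention factor).
#' @return Nearest-neighbor distance in nm.
#' @export
#' @examples
#' d_nn("H_II_p6mm", 6)
#' d_nn("Fd3m", 15)
d_nn <- function(group_id, lattice_a, lattice_c = NULL,
                 registry = space_group_registry()) {
  row <- match(group_id, registry$group_id)
  if (is.na(row)) {
    abort(sprintf("Unknown space group '%s'.", group_id))
  }
  if (group_id == "P63mmc") {
    lattice_c <- lattice_c %||% (lattice_a * sqrt(8 / 3))
    return(min(lattice_a, sqrt(lattice_a^2 / 3 + lattice_c^2 / 4)))
  }
  if (group_id == "L_II_disordered") {
    return(lattice_a)
  }
  registry$dnn_factor[row] * lattice_a
}

l2_fallback <- function(peaks) {
  meta <- attr(peaks, "profile_meta")
  q_star <- peaks$q[which.max(peaks$height %||% peaks$q * 0 + 1)]
  tibble(
    buffer = meta$buffer %||% NA_character_,
    ph = meta$ph %||% NA_real_,
    label = meta$label %||% NA_character_,
    group_id = "L_II_disordered",
    lattice_a = NA_real_, lattice_c = NA_real_,
    d_nn = 2 * pi / q_star,
    n_matched = 1L,
    rms_relative_residual = 0,
    matched_peaks = list(which.max(peaks$height %||% rep(1, nrow(peaks))))
  )
}

#' Rank candidate phases against an observed peak list
#'
#' Each candidate group is indexed by hypothesising the identity of the first
#' observed peak among its leading allowed reflections, greedily matching all
#' remaining peaks within a relative tolerance, and refining the lattice by
#' least squares. Candidates are ranked by number of matched peaks
#' (descending), then rms relative residual (ascending), then fewer free
#' lattice parameters, then alphabetical id. A peak list with a single
#' (broad) peak yields the disordered-micellar fallback with
#' `d_nn = 2*pi/q`.
#'
#' @param peaks A `peak_list` from [detect_peaks()].
#' @param candidates Character vector of group ids (default
#'   [default_candidates()]).
#' @param tolerance Relative tolerance on peak positions (default 0.005).
#' @param registry Registry tibble.
#' @return A tibble of ranked `phase_assignment` rows (possibly empty):
#'   columns `buffer`, `ph`, `label`, `group_id`, `lattice_a`, `lattice_c`,
#'   `d_nn`, `n_matched`, `rms_relative_residual`, `matched_peaks`
#'   (list-column of observed-peak indices).
#' @export
index_phase <- function(peaks, candidates = default_candidates(),
                        tolerance = 0.005,
                        registry = space_group_registry()) {
  check_columns(peaks, "q", "peaks")
  if (length(candidates) == 0L) {
    abort("`candidates` must be non-empty.")
  }
  if (nrow(peaks) == 0L) {
    return(empty_assignment())
  }
  if (nrow(peaks) == 1L) {
    if ("L_II_disordered" %in% candidates) {
      return(as_phase_set(l2_fallback(peaks)))
    }
    return(empty_assignment())
  }
  ordered <- setdiff(candidates, "L_II_disordered")
  results <- map(ordered, function(g) {
    index_one_candidate(peaks, g, registry, tolerance)
  })
  results <- list_rbind(keep(results, ~ !is.null(.x)))
  if (nrow(results) == 0L) {
    return(empty_assignment())
  }
  n_par <- registry$n_params[match(results$group_id, registry$group_id)]
  results$n_params <- n_par
  results <- results[order(-results$n_matched, results$rms_relative_residual,
                           results$n_params, results$group_id), ]
  results$n_params <- NULL
  as_phase_set(results)
}

empty_assignment <- function() {
  as_phase_set(tibble(
    buffer = character(), ph = numeric(), label = character(),
    group_id = character(), lattice_a = numeric(), lattice_c = numeric(),
    d_nn = numeric(), n_matched = integer(),
    rms_relative_residual = numeric(), matched_peaks = list()
  ))
}

as_phase_set <- function(x) {
  if (!inherits(x, "phase_set")) {
    class(x) <- c("phase_set", class(x))
  }
  x
}

#' Decompose a peak list into coexisting phases
#'
#' Iterative peeling: index, keep the top-ranked phase, remove its matched
#' peaks, and re-index the residual peaks until too few remain or nothing
#' matches. A pure-phase peak list returns exactly the top-ranked single
#' assignment.
#'
#' @inheritParams index_phase
#' @return Tibble of one or more `phase_assignment` rows (peak indices in
#'   `matched_peaks` refer to the original peak list).
#' @export
decompose_mixture <- function(peaks, candidates = default_candidates(),
                              tolerance = 0.005,
                              registry = space_group_registry()) {
  check_columns(peaks, "q", "peaks")
  remaining <- seq_len(nrow(peaks))
  out <- list()
  repeat {
    sub <- peaks[remaining, , drop = FALSE]
    attr(sub, "profile_meta") <- attr(peaks, "profile_meta")
    ranked <- index_phase(sub, candidates, tolerance, registry)
    if (nrow(ranked) == 0L) break
    top <- ranked[1, ]
    # only accept the L_II fallback when the full pattern was one broad peak
    if (top$group_id == "L_II_disordered" &&
        length(remaining) < nrow(peaks)) {
      break
    }
    matched_local <- top$matched_peaks[[1]]
    top$matched_peaks <- list(remaining[matched_local])
    out[[length(out) + 1]] <- top
    remaining <- setdiff(remaining, remaining[matched_local])
    if (length(remaining) == 0L) break
  }
  if (length(out) == 0L) {
    return(empty_assignment())
  }
  as_phase_set(list_rbind(out))
}

#' Analyze a profile end to end
#'
#' [detect_peaks()] then [decompose_mixture()]; nearest-neighbor distances
#' and sample metadata are carried on each assignment row.
#'
#' @inheritParams detect_peaks
#' @inheritParams index_phase
#' @return Tibble of `phase_assignment` rows (zero rows if nothing was
#'   assigned).
#' @export
#' @examples
#' prof <- simulate_saxs_profile(phase_truth("Fd3m", 15), seed = 2)
#' analyze_profile(prof)
analyze_profile <- function(profile, candidates = default_candidates(),
                            tolerance = 0.005,
                            prominence_frac = 0.05, snr = 5,
                            registry = space_group_registry()) {
  peaks <- detect_peaks(profile, prominence_frac = prominence_frac,
                        snr = snr)
  decompose_mixture(peaks, candidates, tolerance, registry)
}
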