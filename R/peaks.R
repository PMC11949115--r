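#' Construct a 1D scattering profile
#'
#' @param q Scattering vector magnitudes (nm^-1 by default), strictly
#'   increasing and positive.
#' @param intensity Intensities (arbitrary units), same length as `q`.
#' @param sigma Optional uncertainties, same length.
#' @param buffer,ph,label Optional sample metadata carried through the
#'   analysis.
#' @return A tibble of class `saxs_profile` with columns `q`, `intensity`
#'   (and `sigma` if given); metadata stored as attributes.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL,
                         buffer = NA_character_, ph = NA_real_,
                         label = NA_character_) {
  if (length(q) != length(intensity)) {
    abort("`q` and `intensity` must have the same length.")
  }
  if (any(q <= 0) || any(diff(q) <= 0)) {
    abort("`q` must be strictly increasing and positive.")
  }
  out <- tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) {
      abort("`sigma` must match the length of `q`.")
    }
    out$sigma <- as.numeric(sigma)
  }
  attr(out, "buffer") <- buffer
  attr(out, "ph") <- ph
  attr(out, "label") <- label
  class(out) <- c("saxs_profile", class(out))
  out
}

profile_meta <- function(profile) {
  list(
    buffer = attr(profile, "buffer") %||% NA_character_,
    ph = attr(profile, "ph") %||% NA_real_,
    label = attr(profile, "label") %||% NA_character_
  )
}

#' Read a two- or three-column SAXS profile from text
#'
#' Whitespace- or comma-delimited columns `q`, `intensity` and optionally
#' `sigma`; lines starting with `#` are skipped.
#'
#' @param path File path.
#' @param q_units `"nm"` (default, q in nm^-1) or `"angstrom"` (q multiplied
#'   by 10 on read).
#' @inheritParams saxs_profile
#' @return A `saxs_profile` tibble.
#' @export
read_saxs_profile <- function(path, q_units = c("nm", "angstrom"),
                              buffer = NA_character_, ph = NA_real_,
                              label = NULL) {
  q_units <- match.arg(q_units)
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", fill = TRUE)
  if (ncol(raw) == 1L) {
    raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                             sep = ",", fill = TRUE)
  }
  if (ncol(raw) < 2L) {
    abort("Profile files need at least two columns (q, intensity).")
  }
  q <- raw[[1]]
  if (q_units == "angstrom") q <- q * 10
  saxs_profile(
    q, raw[[2]],
    sigma = if (ncol(raw) >= 3L && !all(is.na(raw[[3]]))) raw[[3]],
    buffer = buffer, ph = ph, label = label %||% basename(path)
  )
}

#' Write a profile as two/three-column text
#'
#' @param profile A `saxs_profile`.
#' @param path Output path.
#' @export
write_saxs_profile <- function(profile, path) {
  check_columns(profile, c("q", "intensity"), "profile")
  utils::write.table(
    as.data.frame(profile), path,
    row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

rolling_stat <- function(x, window, fun) {
  n <- length(x)
  half <- max(1L, window %/% 2L)
  vapply(seq_len(n), function(i) {
    fun(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Estimate a smooth scattering background
#'
#' Iterated rolling-minimum followed by a rolling mean, applied in
#' log-intensity, which tracks the smooth small-angle background underneath
#' sharp Bragg peaks without cutting into them.
#'
#' @param profile A `saxs_profile`.
#' @param window Rolling window in grid points (default: 1/8 of the profile,
#'   at least 11).
#' @param iterations Number of rolling-minimum passes (default 2).
#' @return Numeric vector of background intensities on the profile grid.
#' @export
estimate_background <- function(profile, window = NULL, iterations = 2) {
  check_columns(profile, c("q", "intensity"), "profile")
  n <- nrow(profile)
  window <- window %||% max(11L, n %/% 8L)
  pos <- profile$intensity[profile$intensity > 0]
  eps <- if (length(pos) > 0) min(pos) else 1e-12
  y <- log(pmax(profile$intensity, eps * 1e-3))
  b <- y
  for (i in seq_len(iterations)) {
    b <- rolling_stat(b, window, min)
  }
  b <- rolling_stat(b, window, mean)
  exp(b)
}

#' Detect Bragg peaks in a 1D profile
#'
#' Local maxima of the background-subtracted intensity, filtered by
#' prominence, with sub-grid refinement of each position by a three-point
#' parabolic fit through the apex.
#'
#' @param profile A `saxs_profile` (at least 3 points).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   largest background-corrected intensity (default 0.05).
#' @param snr Minimum prominence in units of the robust noise level
#'   (`mad` of the corrected signal; default 5).
#' @param subtract_background Subtract [estimate_background()] first
#'   (default `TRUE`).
#' @param smooth_window Running-mean window (grid points, odd) applied before
#'   the maxima search; suppresses noise ripples while leaving Bragg peaks,
#'   which are much wider than the grid step, intact (default 7; 1 disables).
#' @param window Background window, passed to [estimate_background()].
#' @return A tibble of class `peak_list`: columns `q` (refined position),
#'   `height`, `prominence`, `width` (FWHM estimate in q units), ascending
#'   in `q`.
#' @export
#' @examples
#' prof <- simulate_saxs_profile(phase_truth("H_II_p6mm", 6), seed = 1)
#' detect_peaks(prof)
detect_peaks <- function(profile, prominence_frac = 0.05, snr = 5,
                         subtract_background = TRUE, smooth_window = 7,
                         window = NULL) {
  check_columns(profile, c("q", "intensity"), "profile")
  if (nrow(profile) < 3L) {
    abort("`profile` needs at least 3 samples.")
  }
  q <- profile$q
  y <- profile$intensity
  if (subtract_background) {
    y <- y - estimate_background(profile, window = window)
  }
  # robust point noise level, estimated before smoothing; smoothing over w
  # points shrinks noise ripples by ~sqrt(w) while leaving Bragg peaks
  # (many grid points wide) intact
  sigma_raw <- mad(diff(y)) / sqrt(2)
  if (smooth_window > 1L) {
    y <- rolling_stat(y, as.integer(smooth_window), mean)
  }
  noise_floor <- snr * sigma_raw * 2 / sqrt(max(1, smooth_window))
  n <- length(y)
  empty <- tibble(q = numeric(), height = numeric(),
                  prominence = numeric(), width = numeric())
  class(empty) <- c("peak_list", class(empty))
  attr(empty, "profile_meta") <- profile_meta(profile)

  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  # plateaus: strict local maxima only
  is_max <- is_max[y[is_max] > y[pmax(1L, is_max - 1L)] |
                     y[is_max] > y[pmin(n, is_max + 1L)]]
  if (length(is_max) == 0L) {
    return(empty)
  }
  # prominence: height above the higher of the two key cols, i.e. the minima
  # separating the peak from the nearest taller peak (or record edge) on
  # either side
  prominence <- vapply(is_max, function(i) {
    h <- y[i]
    left <- i; lo_l <- h
    while (left > 1L) {
      left <- left - 1L
      if (y[left] > h) break
      lo_l <- min(lo_l, y[left])
    }
    right <- i; lo_r <- h
    while (right < n) {
      right <- right + 1L
      if (y[right] > h) break
      lo_r <- min(lo_r, y[right])
    }
    h - max(lo_l, lo_r)
  }, numeric(1))

  thr <- max(prominence_frac * max(y), noise_floor)
  keep <- prominence >= thr & y[is_max] > 0
  is_max <- is_max[keep]
  prominence <- prominence[keep]
  if (length(is_max) == 0L) {
    return(empty)
  }

  refine <- function(i) {
    if (i <= 1L || i >= n) {
      return(c(q[i], y[i]))
    }
    y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom >= 0) {
      return(c(q[i], y2))
    }
    delta <- 0.5 * (y1 - y3) / denom
    delta <- max(-0.5, min(0.5, delta))
    dq <- if (delta >= 0) q[min(n, i + 1L)] - q[i] else q[i] - q[max(1L, i - 1L)]
    c(q[i] + delta * dq, y2 - 0.25 * (y1 - y3) * delta)
  }
  refined <- t(vapply(is_max, refine, numeric(2)))

  half_width <- function(i) {
    target <- y[i] / 2
    l <- i
    while (l > 1L && y[l] > target) l <- l - 1L
    r <- i
    while (r < n && y[r] > target) r <- r + 1L
    q[r] - q[l]
  }
  widths <- vapply(is_max, half_width, numeric(1))

  out <- tibble(
    q = refined[, 1], height = refined[, 2],
    prominence = prominence, width = widths
  )
  out <- arrange(out, .data$q)
  class(out) <- c("peak_list", class(out))
  attr(out, "profile_meta") <- profile_meta(profile)
  out
}
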