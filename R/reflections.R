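# Reflection tables for the lyotropic phases encountered in ionizable
# lipid / cholesterol mesophases.
#
# Bragg positions by symmetry:
#   2D hexagonal (H_II, plane group p6mm):
#     q = (4*pi / (sqrt(3) * a)) * sqrt(h^2 + h*k + k^2)
#   cubic (Fd3m, Pn3m, Im3m, Ia3d):
#     q = (2*pi / a) * sqrt(N),  N = h^2 + k^2 + l^2 restricted to the
#     group's allowed reflections
#   hexagonal close packed (P63/mmc, two lattice parameters a, c):
#     q = 2*pi * sqrt((4/3) * (h^2 + h*k + k^2) / a^2 + l^2 / c^2)
#     with reflections (h + 2k = 3n, l odd) extinct
#
# The disordered inverse micellar phase L_II has no lattice; it shows a single
# broad correlation peak and is handled as a fallback with d_nn = 2*pi/q.

# Allowed N = h^2+k^2+l^2 sequences for the cubic groups.
fd3m_N <- c(3, 8, 11, 12, 16, 19, 24, 27, 32, 35, 40, 43, 48, 51)
pn3m_N <- c(2, 3, 4, 6, 8, 9, 10, 12, 14, 16)
im3m_N <- c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20)
ia3d_N <- c(6, 8, 14, 16, 20, 22, 24, 26, 30, 32)

hex2d_m <- c(1, 3, 4, 7, 9, 12, 13, 16, 19, 21) # h^2 + h*k + k^2

# Non-extinct hcp (P63/mmc) reflections as (m = h^2+hk+k^2, l), ordered by
# spacing at the ideal axial ratio c/a = sqrt(8/3).
p63mmc_reflections <- function() {
  grid <- expand.grid(h = 0:3, k = 0:3, l = 0:5)
  grid <- grid[grid$h + grid$k + grid$l > 0, ]
  grid <- grid[grid$h >= grid$k, ] # one representative per (m, l) family
  extinct <- (grid$h + 2 * grid$k) %% 3 == 0 & grid$l %% 2 == 1
  grid <- grid[!extinct, ]
  grid$m <- grid$h^2 + grid$h * grid$k + grid$k^2
  grid <- grid[!duplicated(grid[, c("m", "l")]), ]
  # order by q at ideal c/a: q^2 prop (4/3) m + (3/8) l^2
  s2 <- (4 / 3) * grid$m + (3 / 8) * grid$l^2
  grid <- grid[s2 > 0, ]
  grid <- grid[order(s2[s2 > 0]), ]
  tibble(h = grid$h, k = grid$k, l = grid$l, m = grid$m)
}

cubic_hkl_for_N <- function(N) {
  # representative (h,k,l) with h >= k >= l for each allowed N
  reps <- map(N, function(n) {
    for (h in floor(sqrt(n)):1) {
      for (k in h:0) {
        l2 <- n - h^2 - k^2
        if (l2 < 0) next
        l <- sqrt(l2)
        if (l == floor(l) && l <= k) {
          return(c(h, k, l))
        }
      }
    }
    c(NA_real_, NA_real_, NA_real_)
  })
  do.call(rbind, reps)
}

#' Space-group registry for phase indexing
#'
#' The candidate phases shipped with the package, with their allowed
#' reflections, number of free lattice parameters, minimum peak counts and the
#' geometric factor turning the fitted lattice constant into a nearest
#' neighbor distance `d_nn` between water cores.
#'
#' `d_nn` conventions: `a` itself for the inverse hexagonal phase (cylinder
#' center to center); `sqrt(2)/4 * a` for the Fd3m micellar cubic (configurable
#' via `fd3m_dnn_factor`); `min(a, sqrt(a^2/3 + c^2/4))` for P63/mmc hcp
#' micelles; `2*pi/q` of the broad correlation peak for disordered L_II. The
#' bicontinuous cubic factors are unit-cell conventions (channel-junction
#' spacing) and are exploratory.
#'
#' @param groups Optional character vector restricting the registry to the
#'   named space groups.
#' @param fd3m_dnn_factor Multiplier `d_nn / a` for Fd3m (default `sqrt(2)/4`).
#' @return A tibble with one row per group: `group_id`, `n_params`,
#'   `min_peaks`, `dnn_factor` (NA for P63/mmc, which uses its own formula)
#'   and a `reflections` list-column of `(h, k, l, s)` rows, where `s` is the
#'   spacing coefficient such that `q = s / a` at `c/a = sqrt(8/3)` for hcp.
#' @export
#' @examples
#' space_group_registry()
space_group_registry <- function(groups = NULL,
                                 fd3m_dnn_factor = sqrt(2) / 4) {
  cubic_table <- function(N) {
    hkl <- cubic_hkl_for_N(N)
    tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
           m = NA_real_, s = 2 * pi * sqrt(N))
  }
  hcp <- p63mmc_reflections()
  hcp$s <- 2 * pi * sqrt((4 / 3) * hcp$m + (3 / 8) * hcp$l^2)
  reg <- tibble(
    group_id = c("H_II_p6mm", "Fd3m", "P63mmc", "Pn3m", "Im3m", "Ia3d",
                 "L_II_disordered"),
    n_params = c(1L, 1L, 2L, 1L, 1L, 1L, 0L),
    min_peaks = c(2L, 2L, 3L, 2L, 2L, 2L, 1L),
    dnn_factor = c(1, fd3m_dnn_factor, NA_real_,
                   sqrt(2) / 2, sqrt(3) / 2, sqrt(6) / 4, NA_real_),
    reflections = list(
      {
        hk <- map(hex2d_m, function(m) {
          for (h in 0:5) for (k in 0:h) if (h^2 + h * k + k^2 == m) {
            return(c(h, k))
          }
          c(NA_real_, NA_real_)
        })
        hk <- do.call(rbind, hk)
        tibble(h = hk[, 1], k = hk[, 2], l = 0, m = hex2d_m,
               s = 4 * pi * sqrt(hex2d_m) / sqrt(3))
      },
      cubic_table(fd3m_N),
      hcp,
      cubic_table(pn3m_N),
      cubic_table(im3m_N),
      cubic_table(ia3d_N),
      tibble(h = numeric(), k = numeric(), l = numeric(),
             m = numeric(), s = numeric())
    )
  )
  if (!is.null(groups)) {
    unknown <- setdiff(groups, reg$group_id)
    if (length(unknown) > 0) {
      abort(sprintf("Unknown space group(s): %s.",
                    paste(unknown, collapse = ", ")))
    }
    reg <- reg[match(groups, reg$group_id), ]
  }
  reg
}

#' Default candidate set for indexing
#'
#' The four phases observed in the pH series (inverse hexagonal, Fd3m,
#' P63/mmc, disordered micellar). The bicontinuous cubics (Pn3m, Im3m, Ia3d)
#' are in [space_group_registry()] and can be added explicitly.
#'
#' @return Character vector of group ids.
#' @export
default_candidates <- function() {
  c("H_II_p6mm", "Fd3m", "P63mmc", "L_II_disordered")
}

#' Predicted Bragg peak positions for a phase
#'
#' @param group_id One of the ids in [space_group_registry()].
#' @param lattice_a Lattice constant in nm.
#' @param lattice_c Second lattice constant (nm), P63/mmc only; defaults to
#'   the ideal axial ratio `a * sqrt(8/3)`.
#' @param n_reflections Number of leading reflections to return.
#' @param registry Optional registry tibble (for a modified Fd3m `d_nn`
#'   factor the positions are unchanged).
#' @return Tibble with columns `h`, `k`, `l`, `q` (nm^-1), ascending in `q`.
#' @export
#' @examples
#' predicted_positions("H_II_p6mm", lattice_a = 6)[1:3, ]
#' predicted_positions("Fd3m", lattice_a = 15, n_reflections = 2)
predicted_positions <- function(group_id, lattice_a, lattice_c = NULL,
                                n_reflections = 6,
                                registry = space_group_registry()) {
  if (!group_id %in% registry$group_id) {
    abort(sprintf("Unknown space group '%s'.", group_id))
  }
  if (!is.numeric(lattice_a) || lattice_a <= 0) {
    abort("`lattice_a` must be positive.")
  }
  refl <- registry$reflections[[match(group_id, registry$group_id)]]
  if (nrow(refl) == 0) {
    abort("The disordered phase has no Bragg reflections to predict.")
  }
  if (group_id == "P63mmc") {
    lattice_c <- lattice_c %||% (lattice_a * sqrt(8 / 3))
    q <- 2 * pi * sqrt((4 / 3) * refl$m / lattice_a^2 +
                         refl$l^2 / lattice_c^2)
  } else {
    q <- refl$s / lattice_a
  }
  out <- tibble(h = refl$h, k = refl$k, l = refl$l, q = q)
  out <- arrange(out, .data$q)
  out[seq_len(min(n_reflections, nrow(out))), ]
}
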