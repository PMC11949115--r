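# broom-style tidiers for the package's result objects.

#' Tidy a phase assignment set
#'
#' One row per assigned phase, without the list-column of matched peak
#' indices.
#'
#' @param x A `phase_set` from [index_phase()], [decompose_mixture()] or
#'   [analyze_profile()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy phase_set
#' @export
tidy.phase_set <- function(x, ...) {
  out <- as_tibble(x)
  out$matched_peaks <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of a phase assignment set
#'
#' @inheritParams tidy.phase_set
#' @return Tibble: `n_phases`, `top_group`, `n_matched_total`,
#'   `min_residual`.
#' @method glance phase_set
#' @export
glance.phase_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    return(tibble(n_phases = 0L, top_group = NA_character_,
                  n_matched_total = 0L, min_residual = NA_real_))
  }
  tibble(
    n_phases = nrow(x),
    top_group = x$group_id[1],
    n_matched_total = sum(x$n_matched),
    min_residual = min(x$rms_relative_residual)
  )
}

#' Tidy a speciation table
#'
#' @param x A `speciation` tibble from [speciate()].
#' @param ... Unused.
#' @return A plain tibble of per-species rows.
#' @method tidy speciation
#' @export
tidy.speciation <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row-per-pH summary of a speciation table
#'
#' Reports total buffer charge, counterion concentration and ionic strength
#' (buffer + counterion + water ions, no background salt).
#'
#' @inheritParams tidy.speciation
#' @return Tibble per (buffer, ph): `counterion_mM`, `mean_valency`, `I_mM`.
#' @method glance speciation
#' @export
glance.speciation <- function(x, ...) {
  istr <- ionic_strength(x)
  x |>
    as_tibble() |>
    group_by(.data$buffer, .data$ph, .data$c_total_mM) |>
    summarise(
      counterion_mM = sum(.data$conc_mM[.data$role == "counterion"]),
      mean_valency = if (first(.data$c_total_mM) > 0) {
        sum(.data$level * .data$conc_mM, na.rm = TRUE) /
          first(.data$c_total_mM)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    left_join(select(istr, "buffer", "ph", "c_total_mM", "I_mM"),
              by = c("buffer", "ph", "c_total_mM"))
}
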