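fake_assignment <- function(buffer, ph, group, a = 6, label = NULL) {
  tibble::tibble(
    buffer = buffer, ph = ph,
    label = label %||% sprintf("%s_pH%.1f", buffer, ph),
    group_id = group, lattice_a = a, lattice_c = NA_real_,
    d_nn = a, n_matched = 3L, rms_relative_residual = 0
  )
}

test_that("diagram assembly sorts, preserves coexistence and flags duplicates", {
  rows <- dplyr::bind_rows(
    fake_assignment("citrate", 6.5, "Fd3m", 15),
    fake_assignment("citrate", 6.0, "H_II_p6mm"),
    fake_assignment("acetate", 5.5, "Fd3m", 15),
    fake_assignment("acetate", 5.5, "H_II_p6mm")
  )
  diag <- assemble_phase_diagram(rows)
  expect_s3_class(diag, "phase_diagram")
  expect_equal(diag$buffer, c("acetate", "acetate", "citrate", "citrate"))
  expect_equal(diag$ph[3:4], c(6.5, 6.0))

  # empty in, empty out
  expect_equal(nrow(assemble_phase_diagram(rows[0, ])), 0L)

  dup <- dplyr::bind_rows(
    fake_assignment("citrate", 6.0, "H_II_p6mm", label = "run1"),
    fake_assignment("citrate", 6.0, "H_II_p6mm", label = "run2")
  )
  expect_error(assemble_phase_diagram(dup), "merge")
  expect_equal(nrow(assemble_phase_diagram(dup, merge = TRUE)), 2L)
})

test_that("transition extraction returns the highest pH with the target phase", {
  rows <- dplyr::bind_rows(
    fake_assignment("citrate", 7.0, "P63mmc", 7),
    fake_assignment("citrate", 6.5, "Fd3m", 15),
    fake_assignment("citrate", 6.0, "H_II_p6mm"),
    fake_assignment("citrate", 5.5, "H_II_p6mm"),
    fake_assignment("phosphate", 7.0, "L_II_disordered"),
    fake_assignment("phosphate", 6.5, "L_II_disordered")
  )
  tr <- extract_transition_ph(assemble_phase_diagram(rows))
  cit <- tr[tr$buffer == "citrate", ]
  expect_equal(cit$transition_ph, 6.0)
  expect_equal(cit$bracket_high, 6.5)
  # no inverse hexagonal cell: no transition
  expect_true(is.na(tr$transition_ph[tr$buffer == "phosphate"]))

  # target present at every sampled pH: the highest sampled pH is returned
  all_h <- dplyr::bind_rows(
    fake_assignment("acetate", 6.0, "H_II_p6mm"),
    fake_assignment("acetate", 5.5, "H_II_p6mm")
  )
  tr2 <- extract_transition_ph(assemble_phase_diagram(all_h))
  expect_equal(tr2$transition_ph, 6.0)
  expect_true(is.na(tr2$bracket_high))
})

test_that("transition extraction is invariant to row order and benign additions", {
  rows <- dplyr::bind_rows(
    fake_assignment("citrate", 6.5, "Fd3m", 15),
    fake_assignment("citrate", 6.0, "H_II_p6mm"),
    fake_assignment("citrate", 5.0, "H_II_p6mm")
  )
  base <- extract_transition_ph(assemble_phase_diagram(rows))
  shuffled <- extract_transition_ph(
    assemble_phase_diagram(rows[c(3, 1, 2), ])
  )
  expect_equal(base, shuffled)
  added <- dplyr::bind_rows(rows, fake_assignment("citrate", 7.5,
                                                  "L_II_disordered"))
  expect_equal(
    extract_transition_ph(assemble_phase_diagram(added))$transition_ph,
    base$transition_ph
  )
})

test_that("d_nn tables are long format with one row per assignment", {
  rows <- dplyr::bind_rows(
    fake_assignment("citrate", 6.0, "H_II_p6mm", 6),
    fake_assignment("acetate", 5.5, "Fd3m", 15),
    fake_assignment("acetate", 5.5, "H_II_p6mm", 6.2)
  )
  tab <- dnn_vs_ph(assemble_phase_diagram(rows))
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$buffer == "acetate" & tab$ph == 5.5), 2L)
  expect_true(all(c("buffer", "ph", "group_id", "d_nn") %in% names(tab)))
})

test_that("the pipeline runs stage-wise from a config", {
  # buffers only
  res <- run_pipeline(list(buffers = list(names = "acetate",
                                          ph = c(4.76, 5.5))))
  expect_named(res, c("speciation", "ionic_strength"))
  expect_equal(nrow(res$ionic_strength), 2L)

  # malformed saxs section aborts with a stage-tagged message
  expect_error(run_pipeline(list(saxs = list())), "manifest")
  suppressWarnings(
    expect_error(run_pipeline("no-such-config-file.yaml"), "cannot open")
  )

  # kinetics stage from CSV with relative efficiency
  dir <- withr::local_tempdir()
  traj <- dplyr::bind_rows(
    simulate_trajectories(population_params(n_cells = 4, noise_sd = 1),
                          seed = 1, condition = "citrate")$trajectories,
    simulate_trajectories(population_params(n_cells = 4, noise_sd = 1,
                                            amplitude_meanlog = log(250)),
                          seed = 2, condition = "acetate")$trajectories
  )
  csv <- file.path(dir, "cells.csv")
  readr::write_csv(traj, csv)
  res_k <- run_pipeline(list(kinetics = list(csv = csv,
                                             reference = "citrate")),
                        out_dir = file.path(dir, "out"))
  expect_true(file.exists(file.path(dir, "out", "kinetics.csv")))
  k <- res_k$kinetics
  expect_equal(k$relative_efficiency[k$condition == "citrate"], 1)
})

test_that("a simulated citrate series reproduces its ground-truth labels end to end", {
  series <- simulate_phase_series(phase_series_presets("citrate"),
                                  seed = 29)
  assignments <- purrr::list_rbind(
    purrr::map(series$profile, analyze_profile)
  )
  diag <- assemble_phase_diagram(assignments)
  got <- diag |>
    tibble::as_tibble() |>
    dplyr::group_by(ph) |>
    dplyr::summarise(groups = paste(sort(group_id), collapse = "+"))
  want <- series |>
    dplyr::mutate(groups = purrr::map_chr(truths, function(tr) {
      paste(sort(vapply(tr, function(x) x$group_id, character(1))),
            collapse = "+")
    })) |>
    dplyr::select(ph, groups)
  merged <- dplyr::left_join(want, got, by = "ph",
                             suffix = c("_truth", "_found"))
  expect_equal(merged$groups_found, merged$groups_truth)
})
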