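make_traj <- function(t, f, id = "c1", condition = NULL) {
  out <- tibble::tibble(cell_id = id, time_h = t, fluorescence = f)
  if (!is.null(condition)) out$condition <- condition
  out
}

test_that("AUC of simple signals matches geometry", {
  t <- seq(0, 30, by = 1 / 6)
  # constant F = 5 with no baseline subtraction: a 5 x 30 rectangle
  expect_equal(
    compute_auc(make_traj(t, rep(5, length(t))), baseline_window = NULL)$auc,
    150, tolerance = 1e-12
  )
  # all-zero trajectory
  expect_equal(compute_auc(make_traj(t, rep(0, length(t))))$auc, 0)
  # with the default baseline the constant signal integrates to zero
  expect_equal(compute_auc(make_traj(t, rep(5, length(t))))$auc, 0)
})

test_that("AUC is additive over adjacent windows and stable under grid refinement", {
  t <- seq(0, 30, by = 1 / 6)
  f <- pmax(0, 10 * (t - 3)) # piecewise linear
  full <- compute_auc(make_traj(t, f), window = c(0, 30),
                      baseline_window = NULL)$auc
  a <- compute_auc(make_traj(t, f), window = c(0, 12),
                   baseline_window = NULL)$auc
  b <- compute_auc(make_traj(t, f), window = c(12, 30),
                   baseline_window = NULL)$auc
  expect_equal(a + b, full, tolerance = 1e-9)

  t2 <- seq(0, 30, by = 1 / 60)
  f2 <- pmax(0, 10 * (t2 - 3))
  expect_equal(
    compute_auc(make_traj(t2, f2), baseline_window = NULL)$auc,
    full, tolerance = 1e-9
  )
})

test_that("trapezoidal AUC matches the generator's closed form within 1%", {
  params <- population_params(n_cells = 5, noise_sd = 0)
  pop <- simulate_trajectories(params, seed = 21)
  aucs <- compute_auc(pop$trajectories, baseline_window = NULL)
  merged <- dplyr::left_join(aucs, pop$truth, by = c("cell_id", "condition"))
  expect_true(all(abs(merged$auc - merged$auc_exact) /
                    merged$auc_exact < 0.01))
  # and the closed form itself agrees with numerical quadrature
  tr <- pop$truth[1, ]
  num <- stats::integrate(function(t) {
    expression_curve(t, tr$amplitude, tr$onset_h, tr$gamma, tr$delta)
  }, 0, 30, rel.tol = 1e-10)$value
  expect_equal(tr$auc_exact, num, tolerance = 1e-8)
})

test_that("window clipping warns and an empty overlap errors", {
  t <- seq(0, 10, by = 0.5)
  expect_warning(
    compute_auc(make_traj(t, rep(1, length(t))), window = c(0, 30)),
    "clipping"
  )
  expect_error(
    suppressWarnings(
      compute_auc(make_traj(t, rep(1, length(t))), window = c(20, 30))
    ),
    "overlap"
  )
})

test_that("onset detection finds steps and rejects flat noise", {
  t <- seq(0, 30, by = 1 / 6)
  # flat Gaussian noise: no sustained crossing at k = 3
  set.seed(31)
  flat <- make_traj(t, rnorm(length(t)))
  expect_true(is.na(estimate_onset(flat)$onset_h))
  # noiseless step at t = 6 h
  step <- make_traj(t, ifelse(t >= 6, 10, 0))
  expect_equal(estimate_onset(step)$onset_h, 6, tolerance = 1 / 6)
})

test_that("threshold onset recovers the generator onset at low noise", {
  params <- population_params(n_cells = 30, onset_mean = 4, onset_sd = 1,
                              noise_sd = 0.5)
  pop <- simulate_trajectories(params, seed = 32)
  onsets <- estimate_onset(pop$trajectories)
  merged <- dplyr::left_join(onsets, pop$truth,
                             by = c("cell_id", "condition"))
  expect_true(all(!is.na(merged$onset_h.x)))
  expect_lt(stats::median(abs(merged$onset_h.x - merged$onset_h.y)), 1 / 6)
})

test_that("the expression model fit recovers noiseless parameters", {
  t <- seq(0, 30, by = 1 / 6)
  truth <- list(A = 400, t0 = 4.2, gamma = 0.06, delta = 0.35)
  f <- expression_curve(t, truth$A, truth$t0, truth$gamma, truth$delta)
  fit <- fit_expression_model(make_traj(t, f))
  expect_true(fit$converged)
  expect_equal(fit$amplitude, truth$A, tolerance = 1e-3)
  expect_equal(fit$t0, truth$t0, tolerance = 1e-3)
  expect_equal(fit$gamma, truth$gamma, tolerance = 1e-3)
  expect_equal(fit$delta, truth$delta, tolerance = 1e-3)
  expect_gt(fit$delta, fit$gamma)
})

test_that("the degenerate equal-rate limit is handled", {
  t <- seq(0, 30, by = 1 / 6)
  g <- expression_curve(t, 100, 3, 0.2, 0.2)
  expect_equal(g, 100 * 0.2 * pmax(t - 3, 0) * exp(-0.2 * pmax(t - 3, 0)),
               tolerance = 1e-9)
  # near-degenerate curves are continuous in the rate gap
  g_eps <- expression_curve(t, 100, 3, 0.2, 0.2 + 1e-10)
  expect_equal(g, g_eps, tolerance = 1e-6)
})

test_that("pure noise yields a fit failure, not a spurious fit", {
  t <- seq(0, 30, by = 1 / 6)
  set.seed(41)
  fit <- fit_expression_model(make_traj(t, rnorm(length(t))))
  expect_false(fit$converged)
})

test_that("condition summaries aggregate correctly", {
  t <- seq(0, 30, by = 1 / 6)
  f <- expression_curve(t, 100, 4, 0.05, 0.3)
  trip <- dplyr::bind_rows(
    make_traj(t, f, "a", "x"), make_traj(t, f, "b", "x"),
    make_traj(t, f, "c", "x")
  )
  s <- summarize_condition(trip)
  expect_equal(s$n_cells, 3L)
  expect_equal(s$sem_auc, 0, tolerance = 1e-9)

  # two cells with AUC 100 and 200: mean 150, sd 70.71, sem 50
  t2 <- c(0, 10)
  two <- dplyr::bind_rows(
    make_traj(t2, c(10, 10), "a", "x"),
    make_traj(t2, c(20, 20), "b", "x")
  )
  s2 <- summarize_condition(two, window = c(0, 10), baseline_window = NULL)
  expect_equal(s2$mean_auc, 150)
  expect_equal(s2$sem_auc, 50, tolerance = 1e-12)
})

test_that("relative efficiency normalises to the reference condition", {
  s <- tibble::tibble(condition = c("citrate", "phosphate", "acetate"),
                      mean_auc = c(200, 150, 100))
  r <- relative_efficiency(s, "citrate")
  expect_equal(r$relative_efficiency, c(1, 0.75, 0.5))
  expect_error(relative_efficiency(s, "tris"), "not present")
  s$mean_auc[1] <- 0
  expect_error(relative_efficiency(s, "citrate"), "zero mean AUC")
})

test_that("buffer-ordered populations reproduce the onset/efficiency anticorrelation", {
  # citrate: earlier onset, higher amplitude; acetate: late and weak
  make_pop <- function(cond, meanlog, onset, seed) {
    simulate_trajectories(
      population_params(n_cells = 40, amplitude_meanlog = meanlog,
                        onset_mean = onset, onset_sd = 1, noise_sd = 2),
      seed = seed, condition = cond
    )$trajectories
  }
  traj <- dplyr::bind_rows(
    make_pop("citrate", log(600), 3.5, 51),
    make_pop("phosphate", log(400), 5.0, 52),
    make_pop("acetate", log(250), 6.5, 53)
  )
  s <- relative_efficiency(summarize_condition(traj), "citrate")
  s <- s[order(-s$relative_efficiency), ]
  expect_equal(s$condition, c("citrate", "phosphate", "acetate"))
  expect_equal(s$relative_efficiency[1], 1)
  # onset ordering is inverse to the efficiency ordering
  expect_true(all(diff(s$mean_onset) > 0))
})

test_that("trajectories survive a CSV round trip", {
  pop <- simulate_trajectories(population_params(n_cells = 2), seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(pop$trajectories, path)
  back <- read_trajectories(path)
  expect_equal(back$fluorescence, pop$trajectories$fluorescence,
               tolerance = 1e-12)
})
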