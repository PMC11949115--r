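test_that("speciation reproduces the pH = pKa symmetry and scaling limits", {
  s <- speciate("acetate", ph = 4.76, c_total = 50)
  buf <- dplyr::filter(s, role == "buffer")
  expect_equal(buf$conc_mM, c(25, 25), tolerance = 1e-12)

  s0 <- speciate("acetate", ph = 4.76, c_total = 0,
                 include_water_ions = FALSE)
  expect_true(all(s0$conc_mM == 0))
})

test_that("citrate speciation at pH 5.5 matches the direct alpha-fraction oracle", {
  pKa <- c(3.13, 4.76, 6.40)
  s <- speciate("citrate", ph = 5.5, c_total = 50)
  buf <- dplyr::filter(s, role == "buffer")
  expect_equal(buf$conc_mM, 50 * oracle_alpha(pKa, 5.5), tolerance = 1e-12)
  # frozen values from the oracle
  expect_equal(buf$conc_mM[2:4], c(6.952647, 38.207638, 4.810057),
               tolerance = 2e-6)
  na <- dplyr::filter(s, role == "counterion")
  expect_equal(na$species, "Na+")
  expect_equal(na$conc_mM, 97.794933, tolerance = 2e-6)
})

test_that("speciation obeys the equilibrium relations it encodes", {
  set.seed(101)
  for (rep in 1:20) {
    b <- random_buffer()
    ph <- runif(1, 1, 13)
    c_tot <- runif(1, 1, 200)
    s <- speciate(b, ph, c_tot)
    buf <- dplyr::filter(s, role == "buffer")
    # successive species satisfy c_j / c_{j-1} = Ka_j / [H+]
    H <- 10^(-ph)
    ratio <- buf$conc_mM[-1] / buf$conc_mM[-nrow(buf)]
    finite <- is.finite(ratio) & ratio > 0
    expect_equal(ratio[finite], (10^(-b$pKa) / H)[finite],
                 tolerance = 1e-9)
    # mass conservation
    expect_equal(sum(buf$conc_mM), c_tot, tolerance = 1e-9 * c_tot)
    # electroneutrality after counterion assignment
    expect_lt(abs(net_charge(s)) / c_tot, 1e-9)
  }
})

test_that("invalid buffer definitions are rejected", {
  expect_error(buffer_definition("bad", c(5, 4)), "ascending")
  expect_error(buffer_definition("bad", 5, counterion_charge = 0),
               "non-zero")
  expect_error(speciate("citrate", ph = 15, c_total = 50), "0, 14")
})

test_that("mean valency has the correct limits and monotonicity", {
  expect_equal(mean_valency("acetate", 12)$valency, 1, tolerance = 1e-6)
  expect_equal(mean_valency("citrate", 0.5)$valency, 0, tolerance = 1e-2)
  v55 <- mean_valency("citrate", 5.5)$valency
  expect_equal(v55, sum((0:3) * oracle_alpha(c(3.13, 4.76, 6.40), 5.5)),
               tolerance = 1e-12)
  expect_equal(v55, 1.96, tolerance = 0.005)
  grid <- mean_valency("citrate", seq(1, 13, by = 0.1))
  expect_true(all(diff(grid$valency) >= -1e-12))
  expect_true(all(grid$valency >= 0 & grid$valency <= 3))
})

test_that("ionic strength matches the definition and the printed buffer values", {
  # background only: NaCl 150 mM -> I = 150
  bg_only <- ionic_strength(NULL, background = nacl_background(150))
  expect_equal(bg_only$I_mM, 150)

  # the three 50 mM buffers at pH 5.5 (printed as 151 / 52 / 42)
  I <- vapply(c("citrate", "phosphate", "acetate"), function(b) {
    ionic_strength(speciate(b, 5.5, 50))$I_mM
  }, numeric(1))
  expect_equal(unname(round(I)), c(150, 52, 42))
  expect_true(all(abs(I - c(151, 52, 42)) <= 2))

  # I equals the sum of its own contribution terms exactly
  res <- ionic_strength(speciate("citrate", 5.5, 50),
                        background = nacl_background(150))
  expect_identical(res$I_mM, sum(res$contributions[[1]]$term_mM))
})

test_that("ionic strength is exactly linear in total concentration at fixed pH", {
  set.seed(202)
  for (rep in 1:5) {
    b <- random_buffer()
    ph <- runif(1, 2, 12)
    I1 <- ionic_strength(speciate(b, ph, 10, include_water_ions = FALSE))$I_mM
    I2 <- ionic_strength(speciate(b, ph, 70, include_water_ions = FALSE))$I_mM
    expect_equal(I2 / I1, 7, tolerance = 1e-12)
  }
})

test_that("concentration_for_ionic_strength inverts ionic_strength", {
  bg <- nacl_background(150)
  res <- concentration_for_ionic_strength("acetate", 5.5, 160,
                                          background = bg)
  expect_equal(res$c_total_mM, 11.82, tolerance = 0.005)
  expect_equal(res$I_achieved_mM, 160, tolerance = 1e-6 * 160)

  res_c <- concentration_for_ionic_strength("citrate", 5.5, 300,
                                            background = bg)
  expect_equal(res_c$c_total_mM, 49.86, tolerance = 0.005)
  expect_equal(res_c$I_achieved_mM, 300, tolerance = 1e-6 * 300)

  # target equal to the background alone -> zero buffer
  I_bg <- ionic_strength(speciate("acetate", 5.5, 0), background = bg)$I_mM
  expect_equal(
    concentration_for_ionic_strength("acetate", 5.5, I_bg,
                                     background = bg)$c_total_mM,
    0
  )
  expect_error(
    concentration_for_ionic_strength("acetate", 5.5, 100, background = bg),
    "below the background"
  )

  # round trip on random conditions; pH at or above the first pKa so the
  # buffer is at least partly ionized (otherwise I barely depends on c and
  # the inversion is ill-posed)
  set.seed(303)
  for (rep in 1:5) {
    b <- random_buffer()
    ph <- runif(1, b$pKa[1], 12.5)
    c_tot <- runif(1, 5, 100)
    I <- ionic_strength(speciate(b, ph, c_tot))$I_mM
    back <- concentration_for_ionic_strength(b, ph, I)$c_total_mM
    expect_equal(back, c_tot, tolerance = 1e-6)
  }
})

test_that("speciation glance summarises counterion, valency and ionic strength", {
  g <- glance(speciate("citrate", 5.5, 50))
  expect_equal(nrow(g), 1L)
  expect_equal(g$mean_valency, 1.96, tolerance = 0.005)
  expect_equal(g$I_mM, 150.4, tolerance = 0.001)
})

test_that("buffer YAML configs round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "buffers:",
    "  - name: citrate",
    "    pKa: [3.13, 4.76, 6.40]",
    "  - name: acetate",
    "    pKa: [4.76]"
  ), path)
  defs <- read_buffer_config(path)
  expect_named(defs, c("citrate", "acetate"))
  expect_equal(defs$citrate$pKa, c(3.13, 4.76, 6.40))
})
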