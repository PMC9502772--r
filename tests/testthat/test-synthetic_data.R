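test_that("true_viability reproduces the Hill-family anchor points", {
  inh <- effect_spec("INHIBITOR", ec50 = 2, hill = 1, bottom = 0)
  enh <- effect_spec("ENHANCER", ec50 = 2, hill = 1, emax = 2)
  bip <- effect_spec("BIPHASIC", ec50 = 0.1, hill = 1, emax = 2,
                     kill_ec50 = 10)
  expect_equal(true_viability(inh, 2), 0.5)          # midpoint
  expect_equal(true_viability(enh, 2), 1.5)          # midpoint
  for (fx in list(effect_spec("INERT"), inh, enh, bip)) {
    expect_identical(true_viability(fx, 0), 1)       # vehicle anchor
  }
  # biphasic: enhancement at low dose, kill above kill_ec50
  expect_gt(true_viability(bip, 1), 1.2)
  expect_lt(true_viability(bip, 100), 0.2)

  inh_floor <- effect_spec("INHIBITOR", ec50 = 1, hill = 2, bottom = 0.3)
  expect_equal(true_viability(inh_floor, 1e6), 0.3, tolerance = 1e-6)

  expect_error(true_viability(inh, -1), ">= 0")
  expect_error(effect_spec("BIPHASIC", ec50 = 5, kill_ec50 = 5),
               "kill_ec50 > ec50")
})

test_that("dilution follows the stock-into-well ratio law", {
  expect_equal(dilution(500, 10, 40), 100)  # top EIPA stock
  expect_equal(dilution(25, 10, 40), 5)     # top Torin1 stock
  expect_equal(dilution(125, 10, 40), 25)   # top library stock
  set.seed(4)
  x <- runif(20, 0.1, 1000)
  expect_equal(dilution(x, 10, 40), x / 5)
  k <- runif(1, 0.5, 10)
  expect_equal(dilution(k * x, 10, 40), k * dilution(x, 10, 40))
  expect_error(dilution(10, 0, 40), "volumes")
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- screen_config(n_compounds = 42L, seed = 7L)
  s1 <- generate_screen(cfg)
  s2 <- generate_screen(cfg)
  expect_identical(s1, s2)
  s3 <- generate_screen(screen_config(n_compounds = 42L, seed = 8L))
  expect_false(identical(s1$measurements$luminescence,
                         s3$measurements$luminescence))

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  simulate_screen(cfg, out_dir = dir1)
  simulate_screen(cfg, out_dir = dir2)
  expect_identical(unname(md5_of_dir(dir1)), unname(md5_of_dir(dir2)))
})

test_that("adding compounds (hence plates) never perturbs earlier plates", {
  small <- generate_screen(screen_config(n_compounds = 21L, seed = 7L),
                           planted_effects(21L, 2L, 1L))
  big <- generate_screen(screen_config(n_compounds = 42L, seed = 7L),
                         planted_effects(42L, 2L, 1L))
  shared <- unique(small$measurements$plate_id)
  subset_big <- big$measurements[big$measurements$plate_id %in% shared, ]
  rownames(subset_big) <- NULL
  expect_identical(small$measurements, subset_big)
})

test_that("a noise-free inert screen passes through the pipeline exactly", {
  cfg <- screen_config(n_compounds = 21L, noise_cv = 0, seed = 1L)
  s <- generate_screen(cfg, planted_effects(21L, 0L, 0L))
  v <- relative_viability(s$measurements)
  lib <- v[!v$compound_id %in% sentinel_ids(), ]
  expect_equal(lib$viability, rep(1, nrow(lib)), tolerance = 1e-12)
  tab <- score_screen(v)
  expect_equal(tab$auc, rep(25, 21), tolerance = 1e-12)
})

test_that("truth table records every planted parameter", {
  fx <- planted_effects(10L, n_inhibitors = 2L, n_enhancers = 1L,
                        n_biphasic = 1L)
  s <- generate_screen(screen_config(n_compounds = 10L, seed = 2L), fx)
  expect_equal(s$truth$kind,
               c("INHIBITOR", "INHIBITOR", "ENHANCER", "BIPHASIC",
                 rep("INERT", 6)))
  expect_equal(s$truth$ec50[1], 0.5)
  expect_true(all(is.na(s$truth$ec50[s$truth$kind == "INERT"])))
  expect_true(is.na(s$truth$kill_ec50[1]))      # kill phase is biphasic-only
  expect_false(is.na(s$truth$kill_ec50[4]))

  expect_error(generate_screen(screen_config(n_compounds = 10L),
                               planted_effects(5L, 1L, 1L)),
               "effects missing")
  expect_error(planted_effects(5L, n_inhibitors = 10L), "more planted")
})

test_that("generated luminescence has the configured noise scale", {
  cfg <- screen_config(n_compounds = 21L, noise_cv = 0.1, seed = 3L)
  s <- generate_screen(cfg, planted_effects(21L, 0L, 0L))
  lib <- s$measurements[!s$measurements$compound_id %in% sentinel_ids(), ]
  cv_hat <- sd(lib$luminescence) / mean(lib$luminescence)
  expect_lt(abs(cv_hat - 0.1), 0.02)
  # expected brightness: baseline x rescue fold
  expect_lt(abs(mean(lib$luminescence) /
                  (cfg$baseline_luminescence * cfg$rescue_fold) - 1), 0.02)
})
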