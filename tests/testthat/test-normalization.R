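test_that("relative viability is luminescence over the plate DMSO mean", {
  v <- relative_viability(tiny_measurements())
  expect_equal(v$viability[v$well == "A02"], 0.5)   # 50k / 100k
  expect_equal(v$viability[v$well == "A03"], 0.25)
  expect_true(all(v$viability >= 0))
})

test_that("per-plate DMSO wells average exactly 1 and plates never pool", {
  set.seed(42)
  plates <- lapply(1:3, function(i) {
    plate_measurements(
      compound_viability = list(C001 = runif(4)),
      dmso_mean = 10^i,  # wildly different plate brightness
      plate_id = sprintf("P%02d", i), replicate = i)
  })
  m <- do.call(rbind, plates)
  m$luminescence <- m$luminescence * exp(rnorm(nrow(m), sd = 0.1))
  v <- relative_viability(m)
  dmso <- v[v$compound_id == "DMSO", ]
  per_plate <- tapply(dmso$viability, dmso$plate_id, mean)
  expect_equal(as.numeric(per_plate), rep(1, 3), tolerance = 1e-12)
})

test_that("normalization is invariant to per-plate scaling", {
  m <- plate_measurements(compound_viability = list(C001 = c(0.9, 0.7, 0.4, 0.2)))
  v1 <- relative_viability(m)
  m$luminescence <- m$luminescence * 137.5
  v2 <- relative_viability(m)
  expect_equal(v1$viability, v2$viability, tolerance = 1e-12)
})

test_that("a plate without vehicle wells is a named error", {
  m <- tiny_measurements()
  m <- m[m$compound_id != "DMSO", ]
  expect_error(relative_viability(m), "without DMSO vehicle wells.*P01")
})

test_that("planted viability is recovered from a noisy plate", {
  # plant viability 0.3 with 5% multiplicative noise, 4 replicate wells
  truth <- 0.3; cv <- 0.05; n <- 4L
  set.seed(11)
  reps <- lapply(1:n, function(r) {
    p <- plate_measurements(compound_viability = list(C001 = rep(truth, 4)),
                            plate_id = sprintf("P%02d", r), replicate = r)
    p$luminescence <- p$luminescence * exp(rnorm(nrow(p), sd = cv))
    p
  })
  v <- relative_viability(do.call(rbind, reps))
  est <- mean(v$viability[v$compound_id == "C001"])
  se <- truth * cv / sqrt(n * 4)  # 16 wells total
  expect_lt(abs(est - truth), 3 * se + 3 * truth * cv / sqrt(n * 4))
})

test_that("fold_change matches direct arithmetic and flags degeneracy", {
  df <- data.frame(condition = rep(c("GLN_STARVED", "GLN_STARVED_BSA"), each = 4),
                   viability = c(1, 1.1, 0.9, 1, 1, 1.1, 0.9, 1))
  fc <- fold_change(df)
  expect_equal(fc$fold, 1)
  expect_gt(fc$p_value, 0.95)
  expect_false(fc$degenerate)

  zv <- data.frame(condition = rep(c("GLN_STARVED", "GLN_STARVED_BSA"), each = 4),
                   viability = c(1, 1, 1, 1, 2, 2, 2, 2))
  fc <- fold_change(zv)
  expect_equal(fc$fold, 2)
  expect_true(fc$degenerate)
  expect_identical(fc$t_statistic, Inf)

  expect_error(
    fold_change(data.frame(condition = c("GLN_STARVED", "GLN_STARVED_BSA"),
                           viability = c(1, 2))),
    ">= 2 replicates")
})

test_that("swapping treated and reference inverts the fold", {
  set.seed(3)
  for (i in 1:10) {
    df <- data.frame(
      condition = rep(c("GLN_STARVED", "GLN_STARVED_BSA"), each = 3),
      viability = rlnorm(6))
    f_ab <- fold_change(df)$fold
    f_ba <- fold_change(df, treated = "GLN_STARVED",
                        reference = "GLN_STARVED_BSA")$fold
    expect_equal(f_ab * f_ba, 1, tolerance = 1e-12)
  }
})

test_that("the BSA-rescue generator plants a recoverable fold", {
  fold <- 9.6; cv <- 0.1; n <- 3L
  d <- generate_rescue_experiment(rescue_fold = fold, cv = cv,
                                  n_replicates = n, seed = 5)
  fc <- fold_change(d, group = "group")
  # SE of a ratio of lognormal means: fold * cv * sqrt(2/n)
  expect_lt(abs(fc$fold - fold), 3 * fold * cv * sqrt(2 / n))
  expect_equal(fc$n_treated, n)
  # Welch option keeps the fold but uses unpooled degrees of freedom
  fc_w <- fold_change(d, group = "group", welch = TRUE)
  expect_equal(fc_w$fold, fc$fold)
  expect_false(identical(fc_w$p_value, fc$p_value))
})
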