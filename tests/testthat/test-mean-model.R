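test_that("exposure clocks count treated periods including the current one", {
  des <- swd_design(3, 2, 1, cohort_size = 2, il_split = 0.5)
  # cluster 1 is in sequence 1 (crossover at 2); individual 2 is IL-treated
  e <- exposure_history(des, cluster = 1, individual = 2, period = 3)
  expect_equal(e$calendar_period, 3L)
  expect_equal(e$il_periods_on, 3L)
  expect_equal(e$cl_periods_on, 2L)
  expect_equal(e$joint_periods_on, 2L)

  e1 <- exposure_history(des, 1, 2, 1)
  expect_equal(e1$cl_periods_on, 0L)   # before any crossover

  ctrl <- exposure_history(des, 1, 1, 3)
  expect_equal(ctrl$il_periods_on, 0L)
  expect_equal(ctrl$joint_periods_on, 0L)

  expect_error(exposure_history(des, 1, 3, 1), "out of range")
  expect_error(exposure_history(des, 9, 1, 1), "out of range")
})

test_that("incremental design rows scale exposure counts", {
  spec <- iim_model(scaling = c(il = 3, cl = 3, int = 3))
  exposure <- list(calendar_period = 3L, il_periods_on = 3L,
                   cl_periods_on = 2L, joint_periods_on = 2L,
                   membership_periods_on = 2L, il_arm = 1L)
  row <- design_row(exposure, spec, n_periods = 6)
  expect_equal(unname(row), c(1, 3, 1, 2 / 3, 2 / 3), tolerance = 1e-12)
  expect_named(row, c("(Intercept)", "period", "il", "cl", "il_cl"))
})

test_that("average-effects rows are exposure indicators", {
  spec <- mean_model("average", "categorical", link = "identity",
                     theta = rep(0, 6))
  ref <- design_row(list(calendar_period = 1L, il_periods_on = 0L,
                         cl_periods_on = 0L, joint_periods_on = 0L,
                         membership_periods_on = 0L), spec, n_periods = 3)
  expect_equal(unname(ref), c(1, 0, 0, 0, 0, 0))
  both <- design_row(list(calendar_period = 2L, il_periods_on = 1L,
                          cl_periods_on = 1L, joint_periods_on = 1L,
                          membership_periods_on = 1L), spec, n_periods = 3)
  expect_equal(unname(both[c("il", "cl", "il_cl")]), c(1, 1, 1))
})

test_that("cluster design matrices stack control then treated individuals", {
  des <- swd_design(2, 1, 1, cohort_size = 2, il_split = 0.5)
  spec <- iim_model(theta = c(0, 0, 0.1, 0.1, 0.1),
                    scaling = c(il = 2, cl = 2, int = 2))
  X <- cluster_design_matrix(des, spec, 1)
  expect_equal(dim(X), c(4, 5))
  expect_equal(X[, "il"], c(0, 0, 0.5, 1))       # control rows first
  expect_equal(X[, "cl"], c(0, 0.5, 0, 0.5))     # crossover at period 2
  expect_equal(X[, "il_cl"], c(0, 0, 0, 0.5))

  empty <- swd_design(2, 1, 1, cohort_size = 0)
  expect_equal(nrow(cluster_design_matrix(empty, spec, 1)), 0)

  big <- swd_design(4, 2, 2, cohort_size = 3)
  expect_equal(nrow(cluster_design_matrix(big, spec, 2)), 12)
})

test_that("link functions invert the linear predictor", {
  spec0 <- iim_model(theta = rep(0, 5))
  X <- matrix(rnorm(10), 2, 5)
  expect_equal(linear_predictor(X, spec0)$mu, c(0, 0))

  lgt <- iim_model(theta = rep(0, 5), link = "logit")
  expect_equal(linear_predictor(matrix(0, 1, 5), lgt)$mu, 0.5)

  lg <- iim_model(theta = c(log(2), 0, 0, 0, 0), link = "log")
  expect_equal(linear_predictor(matrix(c(1, 0, 0, 0, 0), 1), lg)$mu, 2)

  expect_error(linear_predictor(matrix(0, 1, 4), lgt), "columns")
})

test_that("average and incremental models agree for single-period exposures", {
  # with unit scaling and only one post-crossover period every exposure
  # count is 0 or 1, so the incremental covariates equal the indicators
  des <- swd_design(2, 1, 2, cohort_size = 3, il_split = 0.5,
                    crossover_period = 2)
  inc <- mean_model("incremental", "linear", theta = rep(0, 5),
                    scaling = c(il = 1, cl = 1, int = 1))
  avg <- mean_model("average", "linear", theta = rep(0, 5))
  Xi <- cluster_design_matrix(des, inc, 1)
  Xa <- cluster_design_matrix(des, avg, 1)
  # IL exposure accrues from period 1, so compare the post-baseline rows
  idx <- Xi[, "period"] == 1 | Xi[, "il"] <= 1
  expect_equal(Xi[Xi[, "cl"] >= 0 & idx, c("cl", "il_cl")],
               Xa[Xi[, "cl"] >= 0 & idx, c("cl", "il_cl")])
})

test_that("incremental covariates are nondecreasing in calendar time", {
  des <- swd_design(6, 5, 1, cohort_size = 2, il_split = 0.5)
  spec <- iim_model()
  for (cl in c(1, 3, 5)) {
    X <- cluster_design_matrix(des, spec, cl)
    for (k in 0:1) {
      rows <- X[seq_len(6) + k * 6, c("il", "cl", "il_cl")]
      expect_true(all(diff(rows[, 1]) >= 0))
      expect_true(all(diff(rows[, 2]) >= 0))
      expect_true(all(diff(rows[, 3]) >= 0))
    }
  }
})

test_that("under the identity link the intercept does not affect power", {
  b <- example_bundle()
  spec_shift <- iim_model(theta = b$mean_model$theta + c(7, 0, 0, 0, 0))
  p0 <- mli_power(b$design, b$mean_model, b$correlation, b$variance,
                  b$contrasts, b$plan)
  p1 <- mli_power(b$design, spec_shift, b$correlation, b$variance,
                  b$contrasts, b$plan)
  expect_equal(p0$power, p1$power, tolerance = 1e-12)
})

test_that("polynomial trends emit raw powers of the period index", {
  spec <- mean_model("incremental", "polynomial", poly_degree = 2,
                     theta = rep(0, 6), scaling = c(il = 1, cl = 1, int = 1))
  row <- design_row(list(calendar_period = 3L, il_periods_on = 0L,
                         cl_periods_on = 0L, joint_periods_on = 0L,
                         membership_periods_on = 0L), spec, n_periods = 4)
  expect_equal(unname(row[1:3]), c(1, 3, 9))
})
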