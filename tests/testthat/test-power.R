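test_that("scalar one-observation information gives unit covariance", {
  des <- swd_design(1, 1, 1, cohort_size = 1, il_split = 0,
                    crossover_period = 2)
  spec <- mean_model("average", "linear", theta = 0,
                     scaling = c(il = 1, cl = 1, int = 1))
  # single cell: only the intercept is identified; build directly
  X <- matrix(1, 1, 1)
  R <- matrix(1, 1, 1)
  V <- build_covariance(R, 0, gaussian_spec())
  expect_equal(solve(t(X) %*% solve(V) %*% X), matrix(1, 1, 1))
})

test_that("independence working correlation reduces to the OLS covariance", {
  des <- swd_design(4, 3, 2, cohort_size = 2)
  spec <- iim_model(theta = c(0, 0, .1, .1, .1))
  om <- model_covariance(des, spec, correlation_structure("independence"),
                         gaussian_spec())
  xtx <- matrix(0, 5, 5)
  for (i in seq_len(des$n_clusters))
    xtx <- xtx + crossprod(cluster_design_matrix(des, spec, i))
  expect_equal(unname(om), unname(solve(xtx)), tolerance = 1e-10)
})

test_that("structured covariance matches the dense block-diagonal oracle", {
  for (seed in 1:6) {
    inst <- random_instance(seed)
    om <- model_covariance(inst$design, inst$spec, inst$cspec, inst$vspec)
    oracle <- dense_oracle_covariance(inst$design, inst$spec,
                                      inst$vspec$family,
                                      inst$vspec$dispersion,
                                      unname(inst$cspec$alpha))
    expect_lt(max(abs(om - oracle)) / max(abs(oracle)), 1e-8)
  }
})

test_that("a never-exposed interaction is reported as non-identified", {
  des <- swd_design(4, 3, 2, cohort_size = 2, il_split = 0)  # no IL-treated
  spec <- iim_model(theta = c(0, 0, .1, .1, .1))
  expect_error(model_covariance(des, spec, block_spec(), gaussian_spec()),
               "non-identified")
})

test_that("the Wald test is calibrated at the null and at a classic point", {
  om <- diag(c(1, 0.25))
  null_ct <- contrast(c(1, 0), ell = 0.5, alpha = 0.05)
  wp <- wald_power(om, theta = c(0.5, 0), null_ct, n_clusters = 30,
                   method = "chisq")
  expect_equal(wp$lambda, 0)
  expect_equal(wp$power, 0.05, tolerance = 1e-12)

  # lambda = 7.849 with q = 1, alpha = .05 is the textbook 80% power point
  om1 <- matrix(1 / 7.849, 1, 1)
  wp80 <- wald_power(om1, theta = 1, contrast(1, alpha = 0.05),
                     n_clusters = 100, method = "chisq")
  expect_equal(wp80$lambda, 7.849, tolerance = 1e-9)
  expect_equal(wp80$power, 0.80, tolerance = 5e-4)
})

test_that("chi-square power bounds the small-sample F power from above", {
  om <- matrix(0.004, 1, 1)
  ct <- contrast(1, alpha = 0.05)
  for (I in c(8, 20, 60)) {
    f <- wald_power(om, 0.15, ct, I, method = "f_small_sample")
    ch <- wald_power(om, 0.15, ct, I, method = "chisq")
    expect_gte(ch$power, f$power)
  }
  f_big <- wald_power(om, 0.15, ct, 1001, method = "f_small_sample")
  ch_big <- wald_power(om, 0.15, ct, 1001, method = "chisq")
  expect_equal(f_big$power, ch_big$power, tolerance = 5e-3)
})

test_that("dispersion scales the covariance and deflates the noncentrality", {
  b <- example_bundle()
  om1 <- model_covariance(b$design, b$mean_model, b$correlation,
                          variance_structure("gaussian", 1))
  om3 <- model_covariance(b$design, b$mean_model, b$correlation,
                          variance_structure("gaussian", 3))
  expect_equal(3 * om1, om3, tolerance = 1e-10)
  ct <- contrast(c(0, 0, 1, 0, 0), alpha = 0.05)
  l1 <- wald_power(om1, b$mean_model$theta, ct, 65)$lambda
  l3 <- wald_power(om3, b$mean_model$theta, ct, 65)$lambda
  expect_equal(l1 / 3, l3, tolerance = 1e-10)
})

test_that("power grows with the effect size and the cohort size", {
  b <- example_bundle()
  ct <- contrast(c(0, 0, 1, 1, 1), alpha = 0.05)
  om <- model_covariance(b$design, b$mean_model, b$correlation, b$variance)
  effects <- seq(0, 0.3, by = 0.05)
  pw_eff <- vapply(effects, function(e)
    wald_power(om, c(0, 0, e, 0, 0), ct, 65)$power, numeric(1))
  expect_true(all(diff(pw_eff) >= 0))

  sizes <- c(5, 10, 20, 40)
  pw_n <- vapply(sizes, function(n) {
    des <- mliswd:::with_cohort_size(b$design, n)
    omn <- model_covariance(des, b$mean_model, b$correlation, b$variance)
    wald_power(omn, b$mean_model$theta, ct, 65)$power
  }, numeric(1))
  expect_true(all(diff(pw_n) > 0))
})

test_that("multiplicity plans resolve per-test significance levels", {
  cts <- list(contrast(c(1, 0), alpha = 0.04, label = "own"),
              contrast(c(0, 1), family = "second", label = "f1"),
              contrast(c(1, 1), family = "second", label = "f2"))
  plan <- list(list(name = "second", alpha = 0.1, adjust = "bonferroni"))
  expect_equal(mliswd:::resolve_alphas(cts, plan), c(0.04, 0.05, 0.05))
  plan_none <- list(list(name = "second", alpha = 0.1, adjust = "none"))
  expect_equal(mliswd:::resolve_alphas(cts, plan_none), c(0.04, 0.1, 0.1))
  expect_error(mliswd:::resolve_alphas(cts[2], NULL), "no significance")
  expect_error(contrast(c(1, 0), alpha = 0.05, family = "second"),
               "not both")
})

test_that("a single-test plan reduces to the plain Wald computation", {
  b <- example_bundle()
  ct <- contrast(c(0, 0, 0, 1, 0), family = "only", label = "cl")
  plan <- list(list(name = "only", alpha = 0.05))
  tab <- mli_power(b$design, b$mean_model, b$correlation, b$variance,
                   list(ct), plan)
  om <- attr(tab, "omega")
  direct <- wald_power(om, b$mean_model$theta,
                       contrast(c(0, 0, 0, 1, 0), alpha = 0.05), 65)
  expect_equal(tab$power, direct$power)
  expect_equal(tab$alpha, 0.05)
})

test_that("degenerate requests fail loudly", {
  om <- diag(2)
  expect_error(wald_power(om, c(0, 0), contrast(c(1, 0), alpha = .05),
                          n_clusters = 2), "I - d > 0")
  L <- rbind(c(1, 0), c(1, 0))
  expect_error(contrast(L, alpha = .05), "full row rank")
  expect_error(wald_power(om, c(0, 0, 0), contrast(c(1, 0), alpha = .05),
                          10), "match")
})
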