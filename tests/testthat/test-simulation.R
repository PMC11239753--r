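sim_setup <- function() {
  list(design = swd_design(2, 1, 1, cohort_size = 2, il_split = 0.5,
                           crossover_period = 2),
       spec = iim_model(theta = c(0, 0, 0, 0, 0),
                        scaling = c(il = 3, cl = 3, int = 3)),
       cspec = block_spec(0.05, 0.025, 0.5),
       vspec = gaussian_spec())
}

test_that("a fixed seed reproduces the outcome table exactly", {
  s <- sim_setup()
  a <- simulate_swd(s$design, s$spec, s$cspec, s$vspec, seed = 11,
                    replicate = 3)
  b <- simulate_swd(s$design, s$spec, s$cspec, s$vspec, seed = 11,
                    replicate = 3)
  expect_identical(a, b)
  c <- simulate_swd(s$design, s$spec, s$cspec, s$vspec, seed = 11,
                    replicate = 4)
  expect_false(identical(a$outcome, c$outcome))
  expect_equal(nrow(a), 4)
  expect_named(a, c("cluster", "sequence", "individual", "period", "il_arm",
                    "cl_exposed", "outcome"))
})

test_that("gaussian outcomes reproduce the working correlation", {
  s <- sim_setup()
  prep <- mliswd:::sim_prep(s$design, s$spec, s$cspec, s$vspec,
                            "gaussian_exact")
  n_rep <- 20000
  draws <- matrix(NA_real_, n_rep, 4)
  for (r in seq_len(n_rep))
    draws[r, ] <- mliswd:::sim_draw(prep, 20240515, r)[[1]]
  emp <- cor(draws)
  target <- build_correlation(s$cspec, 2, 2)
  expect_lt(max(abs(emp - target)), 0.025)
  expect_lt(max(abs(colMeans(draws))), 0.03)
})

test_that("independent effects-free outcomes are standard normal", {
  des <- swd_design(2, 1, 1, cohort_size = 2, il_split = 0.5)
  spec <- iim_model(theta = c(1.5, 0.2, 0, 0, 0))
  ind <- correlation_structure("independence")
  prep <- mliswd:::sim_prep(des, spec, ind, gaussian_spec(),
                            "gaussian_exact")
  draws <- t(vapply(1:8000, function(r)
    mliswd:::sim_draw(prep, 5, r)[[1]], numeric(4)))
  X <- cluster_design_matrix(des, spec, 1)
  expect_lt(max(abs(colMeans(draws) - drop(X %*% spec$theta))), 0.05)
  offdiag <- cor(draws); diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 0.05)
  expect_lt(max(abs(apply(draws, 2, sd) - 1)), 0.05)
})

test_that("generator and link combinations are enforced", {
  s <- sim_setup()
  expect_error(simulate_swd(s$design, s$spec, s$cspec, s$vspec, seed = 1,
                            generator = "binary_copula"),
               "logit link")
  lgt <- iim_model(theta = c(0, 0, 0, 0, 0), link = "logit")
  expect_error(simulate_swd(s$design, lgt, s$cspec, s$vspec, seed = 1,
                            generator = "gaussian_exact"),
               "identity link")
  expect_error(empirical_power(s$design, lgt, s$cspec,
                               variance_structure("binomial"),
                               list(contrast(c(0, 0, 1, 0, 0), alpha = .05)),
                               n_replicates = 2, seed = 1),
               "gaussian/identity")
})

test_that("binary copula outcomes match the marginal means and correlate", {
  des <- swd_design(2, 1, 1, cohort_size = 2, il_split = 0.5)
  spec <- iim_model(theta = c(-0.3, 0.1, 0.2, 0.2, 0), link = "logit")
  vb <- variance_structure("binomial", 1)
  cs <- block_spec(0.05, 0.025, 0.4)
  prep <- mliswd:::sim_prep(des, spec, cs, vb, "binary_copula")
  draws <- t(vapply(1:6000, function(r)
    mliswd:::sim_draw(prep, 99, r)[[1]], numeric(4)))
  X <- cluster_design_matrix(des, spec, 1)
  mu <- plogis(drop(X %*% spec$theta))
  expect_lt(max(abs(colMeans(draws) - mu)), 0.025)
  # within-individual pairs (1,2) and (3,4) carry the strongest correlation
  expect_equal(cor(draws)[1, 2], 0.4, tolerance = 0.06)
  expect_equal(cor(draws)[3, 4], 0.4, tolerance = 0.06)
  expect_lt(cor(draws)[1, 3], 0.15)
})

test_that("the GLS estimator is unbiased with the model-based variance", {
  des <- swd_design(3, 2, 3, cohort_size = 3, il_split = 0.5)
  spec <- iim_model(theta = c(0.5, 0.1, 0.3, 0.3, -0.1),
                    scaling = c(il = 2, cl = 2, int = 2))
  cs <- block_spec(0.05, 0.025, 0.4)
  cts <- list(contrast(c(0, 0, 1, 0, 0), alpha = 0.05, label = "il"))
  emp <- empirical_power(des, spec, cs, gaussian_spec(), cts,
                         n_replicates = 800, seed = 3, method = "chisq")
  draws <- attr(emp, "theta_draws")
  omega <- attr(emp, "omega")
  mc_se <- sqrt(diag(omega) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - spec$theta) <= 3 * mc_se))
  # model-based variance matches the sampling variance of the estimator
  expect_lt(max(abs(diag(cov(draws)) / diag(omega) - 1)), 0.15)
  expect_equal(attr(emp, "n_failed"), 0)
})
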