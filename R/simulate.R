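#' Simulate one replicate of trial outcomes
#'
#' Generates outcomes under the marginal model and working correlation.
#' The `"gaussian_exact"` generator draws each cluster's outcome vector from
#' a multivariate normal with mean `X theta` and covariance
#' `phi * A^{1/2} R A^{1/2}` (identity link, gaussian variance), so the
#' target moments hold exactly. The `"binary_copula"` generator (logit link,
#' binomial variance) thresholds a latent Gaussian vector whose pairwise
#' correlations are calibrated so that the binary outcomes' Pearson
#' correlations approximate the working correlation; the calibration is
#' approximate and its error grows near the Frechet bounds.
#'
#' The random stream is replicate-indexed: replicate `r` under seed `s`
#' always uses the stream seeded by `s + r`, so replicates are reproducible
#' independently and in parallel.
#'
#' @inheritParams model_covariance
#' @param seed Base integer seed.
#' @param replicate Replicate index (>= 1).
#' @param generator `"gaussian_exact"` or `"binary_copula"`.
#' @return A long-format data frame with columns `cluster`, `sequence`,
#'   `individual`, `period`, `il_arm`, `cl_exposed`, `outcome`.
#' @export
simulate_swd <- function(design, spec, cspec, vspec, seed, replicate = 1L,
                         generator = c("gaussian_exact", "binary_copula")) {
  generator <- match.arg(generator)
  check_generator(generator, spec, vspec)
  prep <- sim_prep(design, spec, cspec, vspec, generator)
  y <- sim_draw(prep, seed, replicate)

  rows <- lapply(seq_len(design$n_clusters), function(i) {
    N <- design$cohort_size[i]
    if (N == 0L) return(NULL)
    Tt <- design$n_periods
    s <- design$cluster_sequence[i]
    k <- rep(seq_len(N), each = Tt)
    j <- rep.int(seq_len(Tt), N)
    data.frame(cluster = i, sequence = s, individual = k, period = j,
               il_arm = as.integer(k > design$il_control[i]),
               cl_exposed = as.integer(j >= design$crossover_period[s]),
               outcome = y[[i]])
  })
  do.call(rbind, rows)
}

check_generator <- function(generator, spec, vspec) {
  if (generator == "gaussian_exact" &&
      (spec$link != "identity" || vspec$family != "gaussian"))
    stop("gaussian_exact requires the identity link and gaussian variance",
         call. = FALSE)
  if (generator == "binary_copula" &&
      (spec$link != "logit" || vspec$family != "binomial"))
    stop("binary_copula requires the logit link and binomial variance",
         call. = FALSE)
}

# Precompute per-cluster generation pieces (group-cached by design symmetry).
sim_prep <- function(design, spec, cspec, vspec, generator) {
  check_theta(spec, design$n_periods)
  cache <- new.env(parent = emptyenv())
  per_cluster <- lapply(seq_len(design$n_clusters), function(i) {
    key <- paste(design$cluster_sequence[i], design$il_control[i],
                 design$il_treated[i], sep = "/")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cc <- cluster_components(design, spec, cspec, vspec, i)
    if (is.null(cc)) {
      cache[[key]] <- list(n = 0L)
      return(cache[[key]])
    }
    out <- if (generator == "gaussian_exact") {
      list(n = length(cc$mu), mu = cc$mu, upper = chol(cc$V))
    } else {
      h <- stats::qnorm(cc$mu)  # threshold: Y = 1{Z <= h}, P(Y=1) = mu
      N <- design$cohort_size[i]
      R <- build_correlation(cspec, N, design$n_periods, design$cohort_type)
      Rlat <- calibrate_latent(R, cc$mu, h)
      list(n = length(cc$mu), mu = cc$mu, h = h,
           upper = tryCatch(chol(Rlat), error = function(e)
             stop("calibrated latent correlation is not positive definite",
                  call. = FALSE)))
    }
    cache[[key]] <- out
    out
  })
  list(clusters = per_cluster, generator = generator,
       total_n = sum(vapply(per_cluster, `[[`, integer(1), "n")))
}

# One replicate's outcome vectors (list over clusters), replicate-indexed.
sim_draw <- function(prep, seed, replicate) {
  set.seed((as.integer(seed) + as.integer(replicate)) %% 2147483647L)
  z <- stats::rnorm(prep$total_n)
  pos <- 0L
  lapply(prep$clusters, function(pc) {
    if (pc$n == 0L) return(numeric(0))
    zi <- z[pos + seq_len(pc$n)]
    pos <<- pos + pc$n
    latent <- drop(crossprod(pc$upper, zi))
    if (prep$generator == "gaussian_exact") pc$mu + latent
    else as.numeric(latent <= pc$h)
  })
}

# Bivariate standard normal CDF by a one-dimensional integral in the
# correlation (Plackett's identity); adequate for calibration tolerances.
pbinorm <- function(h, k, rho) {
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  f <- function(r) {
    om <- 1 - r^2
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * om)) / (2 * pi * sqrt(om))
  }
  base + stats::integrate(f, 0, rho, rel.tol = 1e-9)$value
}

# Latent Gaussian correlation r such that the thresholded binaries have
# Pearson correlation `target` given success probabilities p1, p2.
latent_corr <- function(p1, p2, target) {
  if (target == 0) return(0)
  h <- stats::qnorm(p1); k <- stats::qnorm(p2)
  s <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  g <- function(r) (pbinorm(h, k, r) - p1 * p2) / s - target
  lo <- -0.999; hi <- 0.999
  if (g(lo) > 0 || g(hi) < 0)
    stop(sprintf("binary correlation %.3g is unattainable for means %.3g, %.3g",
                 target, p1, p2), call. = FALSE)
  stats::uniroot(g, c(lo, hi), tol = 1e-8)$root
}

calibrate_latent <- function(R, mu, h) {
  n <- nrow(R)
  Rlat <- diag(n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      key <- paste(signif(mu[i], 10), signif(mu[j], 10),
                   signif(R[i, j], 10), sep = "/")
      r <- cache[[key]]
      if (is.null(r)) {
        r <- latent_corr(mu[i], mu[j], R[i, j])
        cache[[key]] <- r
      }
      Rlat[i, j] <- Rlat[j, i] <- r
    }
  }
  Rlat
}

#' Empirical power by Monte Carlo simulation
#'
#' Simulates Gaussian outcomes, estimates the coefficients in each replicate
#' by generalized least squares with the true working correlation plugged in
#' (no correlation estimation, isolating validation of the power formula),
#' and reports the fraction of replicates in which each contrast's Wald test
#' rejects. Replicates in which the estimator fails are excluded and
#' counted, never silently dropped.
#'
#' @inheritParams mli_power
#' @param n_replicates Number of Monte Carlo replicates.
#' @param seed Base seed; replicate `r` uses the stream seeded by `seed + r`
#'   (matching [simulate_swd()]).
#' @return Data frame with one row per contrast: `label`, `alpha`,
#'   `n_reject`, `n_used`, `power`, `mc_se`; the number of failed replicates
#'   in `attr(, "n_failed")` and the replicate-wise coefficient estimates in
#'   `attr(, "theta_draws")` (a `n_used x d` matrix).
#' @export
empirical_power <- function(design, spec, cspec, vspec, contrasts,
                            plan = NULL, n_replicates = 1000L, seed = 1L,
                            method = c("f_small_sample", "chisq")) {
  method <- match.arg(method)
  if (spec$link != "identity" || vspec$family != "gaussian")
    stop("the GLS validation estimator supports the gaussian/identity case",
         call. = FALSE)
  if (!is_count(n_replicates))
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  alphas <- resolve_alphas(contrasts, plan)

  omega <- model_covariance(design, spec, cspec, vspec)
  d <- ncol(omega)
  prep <- sim_prep(design, spec, cspec, vspec, "gaussian_exact")
  # per-cluster projection M_i = V_i^{-1} X_i (theta_hat = Omega sum M_i'y_i)
  Ms <- lapply(seq_len(design$n_clusters), function(i) {
    cc <- cluster_components(design, spec, cspec, vspec, i)
    if (is.null(cc)) return(NULL)
    solve(cc$V, cc$X)
  })

  crit <- lapply(seq_along(contrasts), function(i) {
    L <- contrasts[[i]]$L
    q <- nrow(L)
    df <- design$n_clusters - d
    cut <- if (method == "chisq") stats::qchisq(1 - alphas[i], q)
           else q * stats::qf(1 - alphas[i], q, df)
    list(L = L, ell = contrasts[[i]]$ell, q = q, cut = cut,
         Minv = solve(L %*% omega %*% t(L)))
  })

  draws <- matrix(NA_real_, n_replicates, d)
  rejects <- matrix(FALSE, n_replicates, length(contrasts))
  failed <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    y <- sim_draw(prep, seed, r)
    est <- tryCatch({
      score <- numeric(d)
      for (i in seq_along(Ms))
        if (!is.null(Ms[[i]])) score <- score + crossprod(Ms[[i]], y[[i]])
      drop(omega %*% score)
    }, error = function(e) NULL)
    if (is.null(est)) { failed[r] <- TRUE; next }
    draws[r, ] <- est
    for (i in seq_along(crit)) {
      dev <- drop(crit[[i]]$L %*% est) - crit[[i]]$ell
      W <- drop(crossprod(dev, crit[[i]]$Minv %*% dev))
      rejects[r, i] <- W > crit[[i]]$cut
    }
  }
  used <- !failed
  n_used <- sum(used)
  out <- data.frame(
    label = vapply(contrasts, `[[`, character(1), "label"),
    alpha = alphas,
    n_reject = colSums(rejects[used, , drop = FALSE]),
    n_used = n_used)
  out$power <- out$n_reject / n_used
  out$mc_se <- sqrt(out$power * (1 - out$power) / n_used)
  attr(out, "n_failed") <- sum(failed)
  attr(out, "theta_draws") <- draws[used, , drop = FALSE]
  attr(out, "omega") <- omega
  out
}
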