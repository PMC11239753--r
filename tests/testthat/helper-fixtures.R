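# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures beyond the packaged example configuration.

example_bundle <- function() {
  read_mli_config(system.file("extdata", "diabetes_example.yaml",
                              package = "mliswd"))
}

gaussian_spec <- function() variance_structure("gaussian", dispersion = 1)

block_spec <- function(a0 = 0.05, a1 = 0.025, a2 = 0.5) {
  correlation_structure("block_exchangeable",
                        alpha = c(within_period = a0, inter_period = a1,
                                  within_individual = a2))
}

iim_model <- function(theta = c(0, 0, 0.1, 0.15, -0.1), link = "identity",
                      scaling = c(il = 3, cl = 3, int = 3)) {
  mean_model("incremental", "linear", link = link, theta = theta,
             scaling = scaling)
}

# A random small trial instance for oracle comparisons.
random_instance <- function(seed) {
  set.seed(seed)
  # at least two sequences so the CL exposure kink separates it from the
  # linear time trend; at most 4 clusters total; both IL arms present
  S <- sample(2:3, 1)
  Tt <- if (S == 3) 4L else sample(3:4, 1)
  m <- if (S == 3) c(sample(1:2, 1), 1, 1) else sample(1:2, S, replace = TRUE)
  N <- sample(2:3, 1)
  link <- sample(c("identity", "log", "logit"), 1)
  vfam <- switch(link, identity = "gaussian", log = "poisson",
                 logit = "binomial")
  design <- swd_design(Tt, S, m, cohort_size = N, il_split = 0.5)
  d <- 2L + 3L
  theta0 <- switch(link, identity = 0, log = 0.1, logit = -0.2)
  theta <- c(theta0, 0.02, stats::runif(3, -0.2, 0.2))
  spec <- iim_model(theta = theta, link = link,
                    scaling = c(il = 2, cl = 2, int = 2))
  cspec <- block_spec(0.04, 0.02, 0.3)
  vspec <- variance_structure(vfam,
                              dispersion = if (vfam == "binomial") 1
                                           else stats::runif(1, 0.5, 2))
  list(design = design, spec = spec, cspec = cspec, vspec = vspec)
}

# Independent dense oracle for the model-based covariance: one giant design
# matrix and block-diagonal covariance, built from first principles (its own
# exposure, correlation and variance code), then a single dense inversion.
dense_oracle_covariance <- function(design, spec, vspec_family, dispersion,
                                    alpha) {
  Tt <- design$n_periods
  theta <- spec$theta
  cc <- spec$scaling
  Xs <- list(); Vs <- list()
  for (i in seq_len(design$n_clusters)) {
    N <- design$cohort_size[i]
    if (N == 0) next
    cross <- design$crossover_period[design$cluster_sequence[i]]
    n0 <- design$il_control[i]
    rows <- matrix(0, N * Tt, 5)
    r <- 0
    for (k in seq_len(N)) {
      treated <- k > n0
      for (j in seq_len(Tt)) {
        r <- r + 1
        ail <- if (treated) j else 0
        acl <- max(0, j - cross + 1)
        aint <- if (treated) acl else 0
        rows[r, ] <- c(1, j, ail / cc[["il"]], acl / cc[["cl"]],
                       aint / cc[["int"]])
      }
    }
    eta <- drop(rows %*% theta)
    mu <- switch(spec$link, identity = eta, log = exp(eta),
                 logit = plogis(eta))
    delta <- switch(spec$link, identity = rep(1, length(mu)), log = mu,
                    logit = mu * (1 - mu))
    vfun <- switch(vspec_family, gaussian = rep(1, length(mu)),
                   poisson = mu, binomial = mu * (1 - mu))
    ind <- rep(seq_len(N), each = Tt)
    per <- rep(seq_len(Tt), N)
    R <- matrix(alpha[2], N * Tt, N * Tt)
    R[outer(per, per, "==")] <- alpha[1]
    R[outer(ind, ind, "==")] <- alpha[3]
    diag(R) <- 1
    V <- dispersion * sqrt(vfun) * R * rep(sqrt(vfun), each = length(vfun))
    Xs[[length(Xs) + 1]] <- delta * rows
    Vs[[length(Vs) + 1]] <- V
  }
  ns <- vapply(Vs, nrow, integer(1))
  total <- sum(ns)
  bigX <- do.call(rbind, Xs)
  bigV <- matrix(0, total, total)
  at <- 0
  for (b in seq_along(Vs)) {
    idx <- at + seq_len(ns[b])
    bigV[idx, idx] <- Vs[[b]]
    at <- at + ns[b]
  }
  solve(t(bigX) %*% solve(bigV) %*% bigX)
}
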