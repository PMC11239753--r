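#' Specify the working correlation structure
#'
#' The block exchangeable structure for a closed cohort has three
#' parameters: the within-period correlation `alpha0` (different people,
#' same period), the inter-period correlation `alpha1` (different people,
#' different periods), and the within-individual correlation `alpha2` (same
#' person, different periods). The block autoregressive variant decays the
#' within-individual correlation as `alpha2^|lag|`; by default correlations
#' between different individuals keep the block-exchangeable pattern, and
#' `inter_decay = TRUE` makes the inter-period correlation decay as
#' `alpha1 * alpha2^(|lag| - 1)` as well. The independence structure has no
#' parameters.
#'
#' @param family `"block_exchangeable"`, `"block_autoregressive"` or
#'   `"independence"`.
#' @param alpha Named numeric triple `c(within_period =, inter_period =,
#'   within_individual =)`, each in (-1, 1). Ignored for independence.
#' @param inter_decay Logical; see above (autoregressive family only).
#' @return An object of class `correlation_structure`.
#' @examples
#' correlation_structure("block_exchangeable",
#'                       alpha = c(within_period = 0.05,
#'                                 inter_period = 0.025,
#'                                 within_individual = 0.5))
#' @export
correlation_structure <- function(family = c("block_exchangeable",
                                             "block_autoregressive",
                                             "independence"),
                                  alpha = NULL, inter_decay = FALSE) {
  family <- match.arg(family)
  if (family == "independence") {
    alpha <- c(within_period = 0, inter_period = 0, within_individual = 0)
  } else {
    alpha <- as.numeric(alpha[c("within_period", "inter_period",
                                "within_individual")])
    names(alpha) <- c("within_period", "inter_period", "within_individual")
    if (anyNA(alpha) || any(abs(alpha) >= 1))
      stop("`alpha` needs entries named within_period, inter_period, ",
           "within_individual, each in (-1, 1)", call. = FALSE)
  }
  structure(list(family = family, alpha = alpha,
                 inter_decay = isTRUE(inter_decay)),
            class = "correlation_structure")
}

#' Build a cluster's working correlation matrix
#'
#' Rows follow the individual-major convention: (individual 1, periods
#' `1..J`), (individual 2, periods `1..J`), and so on. For cross-sectional
#' sampling the observations in the same slot at different periods belong to
#' different people, so they receive the inter-period (not the
#' within-individual) correlation.
#'
#' @param spec A [correlation_structure()].
#' @param n_individuals Cohort size `N` (or per-period sample size for
#'   cross-sectional designs).
#' @param n_periods Number of periods `J`.
#' @param cohort_type As in [swd_design()].
#' @return An `N*J` square correlation matrix, checked for positive
#'   definiteness.
#' @export
build_correlation <- function(spec, n_individuals, n_periods,
                              cohort_type = "closed_cohort") {
  stopifnot(inherits(spec, "correlation_structure"))
  if (!is_count(n_individuals) || !is_count(n_periods))
    stop("`n_individuals` and `n_periods` must be positive integers",
         call. = FALSE)
  N <- as.integer(n_individuals); J <- as.integer(n_periods)
  a0 <- spec$alpha[["within_period"]]
  a1 <- spec$alpha[["inter_period"]]
  a2 <- spec$alpha[["within_individual"]]

  ind <- rep(seq_len(N), each = J)
  per <- rep.int(seq_len(J), N)
  same_ind <- outer(ind, ind, `==`) & cohort_type != "cross_sectional"
  same_per <- outer(per, per, `==`)
  lag <- abs(outer(per, per, `-`))

  R <- matrix(a1, N * J, N * J)
  if (spec$family == "block_autoregressive") {
    R[same_ind] <- (a2^lag)[same_ind]
    if (spec$inter_decay)
      R[!same_ind & !same_per] <- (a1 * a2^(lag - 1))[!same_ind & !same_per]
  } else {
    R[same_ind] <- a2
  }
  R[!same_ind & same_per] <- a0
  diag(R) <- 1

  ok <- tryCatch({min(diag(chol(R))) > 1e-5}, error = function(e) FALSE)
  if (!ok)
    stop(sprintf(paste0("working correlation is not positive definite for ",
                        "alpha = (%.3g, %.3g, %.3g) with N = %d, J = %d"),
                 a0, a1, a2, N, J), call. = FALSE)
  R
}

#' Specify the variance model
#'
#' The variance of an observation is `phi * v(mu)` where `v` is the family's
#' variance function: 1 for gaussian, `mu (1 - mu)` for binomial, `mu` for
#' poisson. For the gaussian family `phi` is the outcome variance; the
#' binomial family conventionally has `phi = 1`.
#'
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param dispersion Positive dispersion `phi`.
#' @return An object of class `variance_structure`.
#' @export
variance_structure <- function(family = c("gaussian", "binomial", "poisson"),
                               dispersion = 1) {
  family <- match.arg(family)
  if (!is.numeric(dispersion) || length(dispersion) != 1L ||
      is.na(dispersion) || dispersion <= 0)
    stop("`dispersion` must be a positive number", call. = FALSE)
  structure(list(family = family, dispersion = as.numeric(dispersion)),
            class = "variance_structure")
}

variance_function <- function(mu, vspec) {
  v <- switch(vspec$family,
              gaussian = rep(1, length(mu)),
              binomial = mu * (1 - mu),
              poisson = mu)
  if (any(v <= 0))
    stop("variance function is nonpositive: for the ", vspec$family,
         " family the mean must keep v(mu) > 0 (binomial: mu in (0, 1); ",
         "poisson: mu > 0)", call. = FALSE)
  v
}

#' Assemble a working covariance matrix
#'
#' `V = phi * A^{1/2} R A^{1/2}` with `A = diag(v(mu))`.
#'
#' @param R Working correlation matrix.
#' @param mu Mean vector, one entry per row of `R`.
#' @param vspec A [variance_structure()].
#' @return The covariance matrix `V`.
#' @export
build_covariance <- function(R, mu, vspec) {
  stopifnot(inherits(vspec, "variance_structure"))
  if (length(mu) != nrow(R))
    stop("`mu` must have one entry per row of `R`", call. = FALSE)
  s <- sqrt(variance_function(mu, vspec))
  vspec$dispersion * (R * tcrossprod(s))
}
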