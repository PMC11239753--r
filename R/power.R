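#' Specify a Wald-test contrast
#'
#' Hypotheses take the form `H0: L theta = ell` against a two-sided
#' alternative, with `L` a full-row-rank `q x d` matrix.
#'
#' @param L Numeric matrix (`q x d`) or vector (treated as one row).
#' @param ell Null-value vector of length `q` (default zeros).
#' @param alpha Per-test significance level, or `NULL` when the level is
#'   resolved through a multiplicity plan (see [mli_power()]).
#' @param label Name used in reports.
#' @param family Optional multiplicity-family name (e.g. `"secondary"`).
#' @param include_in_search Should [solve_cohort_size()] require this
#'   contrast to meet the power goal? Default `TRUE`.
#' @return An object of class `contrast_spec`.
#' @examples
#' contrast(c(0, 0, 1, 1, 1), alpha = 0.05, label = "combined")
#' @export
contrast <- function(L, ell = NULL, alpha = NULL, label = NULL,
                     family = NULL, include_in_search = TRUE) {
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  L <- as.matrix(L)
  if (qr(L)$rank < nrow(L))
    stop("`L` must have full row rank", call. = FALSE)
  if (is.null(ell)) ell <- rep(0, nrow(L))
  if (length(ell) != nrow(L))
    stop("`ell` must have one entry per row of `L`", call. = FALSE)
  if (!is.null(alpha) && !is.null(family))
    stop("give `alpha` or `family`, not both (contradictory plan)",
         call. = FALSE)
  if (!is.null(alpha) &&
      (!is.numeric(alpha) || alpha <= 0 || alpha >= 1))
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  structure(list(L = L, ell = as.numeric(ell), alpha = alpha,
                 label = label %||% "contrast", family = family,
                 include_in_search = isTRUE(include_in_search)),
            class = "contrast_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-cluster pieces of the GEE information: restricted design matrix X,
# mean mu, derivative diag Delta, covariance V. Shared by the power engine
# and the simulator.
cluster_components <- function(design, spec, cspec, vspec, cluster,
                               pattern = NULL) {
  X <- cluster_design_matrix(design, spec, cluster)
  N <- design$cohort_size[cluster]
  if (N == 0L) return(NULL)
  R <- build_correlation(cspec, N, design$n_periods, design$cohort_type)
  if (!is.null(pattern)) {
    inc <- build_incidence(pattern, design, cluster)
    sel <- apply_incidence(inc, X, R)
    X <- sel$design_matrix
    R <- sel$correlation
  }
  lp <- linear_predictor(X, spec)
  V <- build_covariance(R, lp$mu, vspec)
  delta <- mean_derivative(lp$mu, spec$link)
  list(X = X, mu = lp$mu, delta = delta, V = V)
}

#' Model-based covariance of the GEE coefficient estimator
#'
#' Computes `Omega = (sum_i D_i' V_i^{-1} D_i)^{-1}` over all clusters,
#' where `D_i = Delta_i X_i` is the derivative of the cluster's mean vector
#' with respect to the coefficients and `V_i` the working covariance. When
#' observation patterns are supplied, each cluster's design and correlation
#' matrices are first restricted to the observed rows.
#'
#' @param design An [swd_design()].
#' @param spec A [mean_model()].
#' @param cspec A [correlation_structure()].
#' @param vspec A [variance_structure()].
#' @param patterns `NULL` for a complete design, or an
#'   [observation_pattern()] (applied to every cluster), or a list of
#'   patterns of length `S` (per sequence) or `I` (per cluster).
#' @return The `d x d` covariance matrix of the coefficient estimator, with
#'   the design-matrix column names.
#' @export
model_covariance <- function(design, spec, cspec, vspec, patterns = NULL) {
  stopifnot(inherits(design, "swd_design"))
  d <- check_theta(spec, design$n_periods)
  pats <- resolve_patterns(patterns, design)
  info <- matrix(0, d, d)
  cn <- NULL

  if (is.null(pats)) {
    for (g in cluster_groups(design)) {
      cc <- cluster_components(design, spec, cspec, vspec, g$cluster)
      if (is.null(cc)) next
      info <- info + g$count * crossprod(cc$delta * cc$X,
                                         solve(cc$V, cc$delta * cc$X))
      cn <- colnames(cc$X)
    }
  } else {
    for (i in seq_len(design$n_clusters)) {
      cc <- cluster_components(design, spec, cspec, vspec, i, pats[[i]])
      if (is.null(cc)) next
      info <- info + crossprod(cc$delta * cc$X,
                               solve(cc$V, cc$delta * cc$X))
      cn <- colnames(cc$X)
    }
  }

  qr_info <- qr(info)
  if (qr_info$rank < d) {
    bad <- setdiff(seq_len(d), qr_info$pivot[seq_len(qr_info$rank)])
    stop("design information matrix is singular; non-identified column(s): ",
         paste(cn[bad] %||% bad, collapse = ", "),
         " (e.g. an interaction never jointly exposed)", call. = FALSE)
  }
  omega <- solve(info)
  dimnames(omega) <- list(cn, cn)
  omega
}

# power of a Wald test given its noncentrality
power_from_lambda <- function(lambda, q, alpha, df, method) {
  if (method == "chisq") {
    suppressWarnings(
      p <- stats::pchisq(stats::qchisq(1 - alpha, df = q), df = q,
                         ncp = lambda, lower.tail = FALSE))
  } else {
    suppressWarnings(
      p <- stats::pf(stats::qf(1 - alpha, q, df), q, df,
                     ncp = lambda, lower.tail = FALSE))
  }
  # distribution functions lose accuracy for extreme noncentrality
  if (is.na(p)) p <- 1
  min(max(p, 0), 1)
}

#' Wald-test power for one contrast
#'
#' The noncentrality is
#' `lambda = (L theta - ell)' (L Omega L')^{-1} (L theta - ell)`. Under the
#' `"chisq"` method power is evaluated against the noncentral chi-square
#' with `q` degrees of freedom; under `"f_small_sample"` (the default,
#' recommended when clusters are few) against the noncentral `F(q, I - d)`,
#' which for `q = 1` is the two-sided noncentral-t test with `I - d`
#' degrees of freedom.
#'
#' @param omega Model-based covariance from [model_covariance()].
#' @param theta Coefficient vector under the alternative.
#' @param contrast A [contrast()] (its `alpha` must be set, or supply
#'   `alpha` here).
#' @param n_clusters Number of clusters `I` (sets the denominator degrees of
#'   freedom `I - d`).
#' @param method `"f_small_sample"` or `"chisq"`.
#' @param alpha Optional override of the contrast's significance level.
#' @return An object of class `wald_power`: list with `lambda`, `df`, `q`,
#'   `alpha`, `power`, `method`.
#' @examples
#' om <- diag(0.01, 3)
#' wald_power(om, theta = c(0.3, 0, 0), contrast(c(1, 0, 0), alpha = .05),
#'            n_clusters = 20)
#' @export
wald_power <- function(omega, theta, contrast, n_clusters,
                       method = c("f_small_sample", "chisq"), alpha = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(contrast, "contrast_spec"))
  alpha <- alpha %||% contrast$alpha
  if (is.null(alpha))
    stop("no significance level: set `alpha` on the contrast or pass it",
         call. = FALSE)
  L <- contrast$L
  d <- ncol(omega)
  if (ncol(L) != d || length(theta) != d)
    stop("contrast and theta must match the ", d, "-dimensional model",
         call. = FALSE)
  q <- nrow(L)
  df <- n_clusters - d
  if (method == "f_small_sample" && df <= 0)
    stop("small-sample F needs more clusters than coefficients (I - d > 0)",
         call. = FALSE)
  dev <- drop(L %*% theta) - contrast$ell
  M <- L %*% omega %*% t(L)
  lambda <- tryCatch(drop(crossprod(dev, solve(M, dev))),
                     error = function(e)
                       stop("L Omega L' is singular", call. = FALSE))
  structure(list(lambda = lambda, df = df, q = q, alpha = alpha,
                 power = power_from_lambda(lambda, q, alpha, df, method),
                 method = method, label = contrast$label),
            class = "wald_power")
}

#' @export
print.wald_power <- function(x, ...) {
  cat(sprintf("Wald test '%s': q = %d, alpha = %.4g, lambda = %.4g, %s%s\n",
              x$label, x$q, x$alpha, x$lambda,
              if (x$method == "chisq") "chi-square"
              else sprintf("F(%d, %d)", x$q, x$df),
              sprintf(", power = %.4f", x$power)))
  invisible(x)
}

# Resolve per-test significance levels from explicit alphas and a
# multiplicity plan. `plan` is a list of families:
# list(list(name = "secondary", alpha = 0.1, adjust = "bonferroni"), ...)
resolve_alphas <- function(contrasts, plan = NULL) {
  fams <- vapply(contrasts, function(ct) ct$family %||% NA_character_,
                 character(1))
  alphas <- lapply(contrasts, `[[`, "alpha")
  if (!is.null(plan)) {
    plan_names <- vapply(plan, `[[`, character(1), "name")
    for (f in unique(stats::na.omit(fams))) {
      idx <- which(fams == f)
      pf <- plan[[match(f, plan_names)]]
      if (is.na(match(f, plan_names)))
        stop("contrast family '", f, "' has no entry in the multiplicity ",
             "plan", call. = FALSE)
      adjust <- pf$adjust %||% "bonferroni"
      per_test <- switch(adjust,
                         bonferroni = pf$alpha / length(idx),
                         none = pf$alpha,
                         stop("unknown adjustment '", adjust, "'",
                              call. = FALSE))
      for (i in idx) alphas[[i]] <- per_test
    }
  }
  miss <- vapply(alphas, is.null, logical(1))
  if (any(miss))
    stop("no significance level for contrast(s): ",
         paste(vapply(contrasts[miss], `[[`, character(1), "label"),
               collapse = ", "), call. = FALSE)
  unlist(alphas)
}

#' Power for a set of contrasts with a multiplicity plan
#'
#' Resolves each contrast's per-test significance level (explicit, or a
#' family-wise level divided equally under Bonferroni), computes the
#' model-based covariance once, and evaluates Wald power for every contrast.
#'
#' @inheritParams model_covariance
#' @param contrasts List of [contrast()] objects.
#' @param plan Multiplicity plan: list of families, each
#'   `list(name =, alpha =, adjust = "bonferroni"|"none")`. Contrasts carry
#'   either their own `alpha` or a `family` named in the plan.
#' @param method Reference distribution, as in [wald_power()].
#' @param power_goal Optional goal reported against each contrast.
#' @return A data frame of class `mli_power` with one row per contrast
#'   (label, q, alpha, lambda, df, power, method, meets_goal) and the
#'   covariance in `attr(, "omega")`.
#' @export
mli_power <- function(design, spec, cspec, vspec, contrasts, plan = NULL,
                      method = c("f_small_sample", "chisq"),
                      patterns = NULL, power_goal = NA) {
  method <- match.arg(method)
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  alphas <- resolve_alphas(contrasts, plan)
  omega <- model_covariance(design, spec, cspec, vspec, patterns)
  rows <- lapply(seq_along(contrasts), function(i) {
    wp <- wald_power(omega, spec$theta, contrasts[[i]], design$n_clusters,
                     method = method, alpha = alphas[i])
    data.frame(label = contrasts[[i]]$label, q = wp$q, alpha = wp$alpha,
               lambda = wp$lambda, df = wp$df, power = wp$power,
               method = method,
               meets_goal = if (is.na(power_goal)) NA
                            else wp$power >= power_goal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "omega") <- omega
  class(out) <- c("mli_power", class(out))
  out
}

#' @export
print.mli_power <- function(x, digits = 4, ...) {
  cat("GEE Wald-test power\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
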