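#' Specify the marginal mean model
#'
#' The expected response on the scale of the link function is a linear
#' combination of a calendar-time trend and three intervention-effect
#' covariates: the individual-level (IL) effect, the cluster-level (CL)
#' effect, and their interaction. Two effect parameterizations are
#' supported:
#'
#' * **average** ("any exposure") effects: each treatment covariate is an
#'   indicator that the corresponding exposure count is at least one, so the
#'   effect does not grow with time on treatment;
#' * **incremental** effects: each treatment covariate is the number of
#'   periods on treatment divided by a scaling constant `c`, so the
#'   coefficient is the effect after `c` periods of exposure. The
#'   interaction covariate is the cumulative count of periods in which both
#'   interventions were active (divided by its constant) — linear in
#'   calendar time, unlike the product of the two exposure counts.
#'
#' @param effect_model `"incremental"` or `"average"`.
#' @param time_trend `"linear"`, `"categorical"` (reference period 1
#'   absorbed into the intercept), or `"polynomial"` (raw powers of the
#'   1-based period index up to `poly_degree`).
#' @param link `"identity"`, `"log"` or `"logit"`.
#' @param theta Coefficient vector: time-trend coefficients first (intercept
#'   included), then the IL, CL and interaction effects. Its length must
#'   equal the number of design-matrix columns.
#' @param scaling Named positive numbers `c(il =, cl =, int =)` scaling the
#'   incremental exposure counts (ignored for the average model).
#' @param poly_degree Degree for the polynomial trend.
#' @param il_start_period First calendar period in which IL-treated
#'   individuals are on the IL intervention (1 = from study start, the
#'   default for concurrent randomization at baseline).
#' @param membership_covariate If `TRUE`, append an extra covariate counting
#'   the periods the individual has belonged to a cluster on the CL
#'   intervention (distinct from the cluster's own exposure clock only in
#'   open cohorts; collinear with the CL covariate in complete designs).
#'
#' @return An object of class `mean_model` with element `d`, the coefficient
#'   dimension.
#' @examples
#' mm <- mean_model(effect_model = "incremental", time_trend = "linear",
#'                  link = "identity", theta = c(0, 0, 0.1, 0.15, -0.1),
#'                  scaling = c(il = 3, cl = 3, int = 3))
#' @export
mean_model <- function(effect_model = c("incremental", "average"),
                       time_trend = c("linear", "categorical", "polynomial"),
                       link = c("identity", "log", "logit"),
                       theta, scaling = c(il = 1, cl = 1, int = 1),
                       poly_degree = 2L, il_start_period = 1L,
                       membership_covariate = FALSE) {
  effect_model <- match.arg(effect_model)
  time_trend <- match.arg(time_trend)
  link <- match.arg(link)
  scaling <- as.numeric(scaling[c("il", "cl", "int")])
  names(scaling) <- c("il", "cl", "int")
  if (anyNA(scaling) || any(scaling <= 0))
    stop("`scaling` needs positive entries named il, cl, int", call. = FALSE)
  if (time_trend == "polynomial" && !is_count(poly_degree))
    stop("`poly_degree` must be a positive integer", call. = FALSE)
  if (!is_count(il_start_period))
    stop("`il_start_period` must be a positive integer", call. = FALSE)
  spec <- structure(
    list(effect_model = effect_model, time_trend = time_trend, link = link,
         theta = as.numeric(theta), scaling = scaling,
         poly_degree = as.integer(poly_degree),
         il_start_period = as.integer(il_start_period),
         membership_covariate = isTRUE(membership_covariate)),
    class = "mean_model")
  spec
}

# number of mean-model columns for a given number of periods
model_dimension <- function(spec, n_periods) {
  time_cols <- switch(spec$time_trend,
                      linear = 2L,
                      categorical = n_periods,
                      polynomial = spec$poly_degree + 1L)
  time_cols + 3L + as.integer(spec$membership_covariate)
}

check_theta <- function(spec, n_periods) {
  d <- model_dimension(spec, n_periods)
  if (length(spec$theta) != d)
    stop("`theta` has length ", length(spec$theta),
         " but the mean model emits ", d, " columns", call. = FALSE)
  d
}

#' Exposure history of one observation
#'
#' Counts, as of a calendar period, how long the individual has been on the
#' IL intervention, how long the cluster has been on the CL intervention,
#' and in how many periods both interventions were simultaneously active
#' (all counts include the current period).
#'
#' @inheritParams build_incidence
#' @param individual Index within the cluster; IL-control individuals come
#'   first (`1, ..., N_i0`), then IL-treated.
#' @param period Calendar period.
#' @param spec Optional [mean_model()]; supplies the IL start period
#'   (default 1).
#' @param entry_period Period the individual joined the cluster (open
#'   cohorts; default 1). Used only for the membership covariate.
#' @return A list with `calendar_period`, `il_periods_on`, `cl_periods_on`,
#'   `joint_periods_on`, `membership_periods_on`, `il_arm`.
#' @examples
#' des <- swd_design(3, 2, 1, cohort_size = 2, il_split = 0.5)
#' exposure_history(des, cluster = 1, individual = 2, period = 3)
#' @export
exposure_history <- function(design, cluster, individual, period,
                             spec = NULL, entry_period = 1L) {
  stopifnot(inherits(design, "swd_design"))
  if (!is_count(cluster) || cluster > design$n_clusters ||
      !is_count(period) || period > design$n_periods ||
      !is_count(individual) || individual > design$cohort_size[cluster])
    stop("cluster, individual or period index out of range", call. = FALSE)
  il_start <- if (is.null(spec)) 1L else spec$il_start_period
  treated <- individual > design$il_control[cluster]
  cross <- design$crossover_period[design$cluster_sequence[cluster]]

  il_on <- if (treated) max(0L, period - il_start + 1L) else 0L
  cl_on <- max(0L, period - cross + 1L)
  joint_on <- if (treated)
    max(0L, period - max(il_start, cross) + 1L) else 0L
  member_on <- max(0L, period - max(entry_period, cross) + 1L)

  list(calendar_period = as.integer(period),
       il_periods_on = as.integer(il_on),
       cl_periods_on = as.integer(cl_on),
       joint_periods_on = as.integer(joint_on),
       membership_periods_on = as.integer(member_on),
       il_arm = as.integer(treated))
}

#' One design-matrix row from an exposure history
#'
#' @param exposure A list as returned by [exposure_history()].
#' @param spec A [mean_model()].
#' @param n_periods Number of calendar periods (fixes the categorical-trend
#'   width).
#' @return A named numeric vector of length `d`.
#' @export
design_row <- function(exposure, spec, n_periods) {
  stopifnot(inherits(spec, "mean_model"))
  t <- exposure$calendar_period
  time_part <- switch(spec$time_trend,
    linear = c("(Intercept)" = 1, period = t),
    categorical = {
      v <- c(1, as.numeric(seq(2L, n_periods) == t))
      names(v) <- c("(Intercept)", paste0("period", seq(2L, n_periods)))
      v
    },
    polynomial = {
      v <- t^(0:spec$poly_degree)
      names(v) <- c("(Intercept)", paste0("period", seq_len(spec$poly_degree)))
      v
    })
  eff <- if (spec$effect_model == "average") {
    c(il = as.numeric(exposure$il_periods_on >= 1),
      cl = as.numeric(exposure$cl_periods_on >= 1),
      il_cl = as.numeric(exposure$il_periods_on >= 1 &&
                           exposure$cl_periods_on >= 1))
  } else {
    c(il = exposure$il_periods_on / spec$scaling[["il"]],
      cl = exposure$cl_periods_on / spec$scaling[["cl"]],
      il_cl = exposure$joint_periods_on / spec$scaling[["int"]])
  }
  row <- c(time_part, eff)
  if (spec$membership_covariate)
    row <- c(row, member = exposure$membership_periods_on /
               spec$scaling[["cl"]])
  row
}

#' Complete design matrix of one cluster
#'
#' Stacks [design_row()] over every (individual, period) cell of the
#' complete layout in individual-major order, IL-control individuals first
#' and IL-treated individuals last.
#'
#' @inheritParams exposure_history
#' @param spec A [mean_model()].
#' @return A numeric matrix with `N_i * T` rows and `d` named columns.
#' @export
cluster_design_matrix <- function(design, spec, cluster) {
  stopifnot(inherits(design, "swd_design"), inherits(spec, "mean_model"))
  N <- design$cohort_size[cluster]
  Tt <- design$n_periods
  d <- model_dimension(spec, Tt)
  X <- matrix(0, nrow = N * Tt, ncol = d)
  r <- 0L
  for (k in seq_len(N)) {
    for (j in seq_len(Tt)) {
      r <- r + 1L
      X[r, ] <- design_row(exposure_history(design, cluster, k, j, spec),
                           spec, Tt)
    }
  }
  if (N > 0L)
    colnames(X) <- names(design_row(
      exposure_history(design, cluster, 1L, 1L, spec), spec, Tt))
  X
}

#' Linear predictor and mean
#'
#' Evaluates `eta = X theta` and the mean `mu = g^{-1}(eta)` under the
#' model's link function.
#'
#' @param X Design matrix with `d` columns.
#' @param spec A [mean_model()].
#' @return List with numeric vectors `eta` and `mu`.
#' @export
linear_predictor <- function(X, spec) {
  stopifnot(inherits(spec, "mean_model"))
  if (ncol(X) != length(spec$theta))
    stop("design matrix has ", ncol(X), " columns but theta has length ",
         length(spec$theta), call. = FALSE)
  eta <- drop(X %*% spec$theta)
  mu <- switch(spec$link,
               identity = eta,
               log = exp(eta),
               logit = 1 / (1 + exp(-eta)))
  list(eta = eta, mu = mu)
}

# derivative of the mean with respect to the linear predictor
mean_derivative <- function(mu, link) {
  switch(link,
         identity = rep(1, length(mu)),
         log = mu,
         logit = mu * (1 - mu))
}
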