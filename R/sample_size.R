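#' Smallest cohort size meeting a power goal
#'
#' Searches the per-cluster cohort size `N` for the smallest value at which
#' every contrast (marked `include_in_search`) attains the power goal. The
#' search brackets the solution by doubling, bisects inside the bracket
#' (power is monotone nondecreasing in `N` for the standard designs), and
#' certifies minimality by checking `N - 1`; if the certificate fails —
#' a non-monotone configuration — it falls back to a linear scan.
#'
#' @inheritParams mli_power
#' @param power_goal Required power for every searched contrast.
#' @param n_max Largest cohort size considered.
#' @return The minimal cohort size (integer), with the power table at the
#'   solution in `attr(, "power")`.
#' @export
solve_cohort_size <- function(design, spec, cspec, vspec, contrasts,
                              plan = NULL, power_goal = 0.8, n_max = 1000L,
                              method = c("f_small_sample", "chisq"),
                              patterns = NULL) {
  method <- match.arg(method)
  if (!is.numeric(power_goal) || power_goal <= 0 || power_goal >= 1)
    stop("`power_goal` must be in (0, 1)", call. = FALSE)
  if (!is_count(n_max)) stop("`n_max` must be a positive integer",
                             call. = FALSE)
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  searched <- vapply(contrasts, `[[`, logical(1), "include_in_search")
  if (!any(searched))
    stop("no contrast is marked include_in_search", call. = FALSE)

  at_n <- function(n) {
    des <- with_cohort_size(design, n)
    tryCatch(
      mli_power(des, spec, cspec, vspec, contrasts, plan, method, patterns,
                power_goal),
      error = function(e) NULL)  # singular at tiny n: treat as failing
  }
  passes <- function(tab) !is.null(tab) && all(tab$power[searched] >=
                                                 power_goal)

  # bracket by doubling
  lo <- 0L; hi <- 1L
  tab_hi <- at_n(hi)
  while (!passes(tab_hi) && hi < n_max) {
    lo <- hi
    hi <- min(2L * hi, n_max)
    tab_hi <- at_n(hi)
  }
  if (!passes(tab_hi)) {
    pw <- if (is.null(tab_hi)) rep(NA_real_, sum(searched))
          else tab_hi$power[searched]
    stop(sprintf(paste0("power goal %.3g not reachable by n_max = %d ",
                        "(attained: %s)"), power_goal, n_max,
                 paste(sprintf("%.3f", pw), collapse = ", ")),
         call. = FALSE)
  }
  # bisect (lo fails, hi passes)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (passes(at_n(mid))) hi <- mid else lo <- mid
  }
  # certificate; non-monotone fallback
  if (hi > 1L && passes(at_n(hi - 1L))) {
    n <- 1L
    while (!passes(at_n(n))) n <- n + 1L
    hi <- n
  }
  out <- hi
  attr(out, "power") <- at_n(hi)
  out
}

with_cohort_size <- function(design, n) {
  swd_design(design$n_periods, design$n_sequences,
             design$clusters_per_sequence, cohort_size = n,
             il_split = design$il_split, cohort_type = design$cohort_type,
             crossover_period = design$crossover_period)
}

#' Feasibility frontier over cluster numbers
#'
#' For each total number of clusters `I` in `cluster_range` (distributed
#' over the sequences as evenly as possible, remainders to the earliest
#' sequences), finds the minimal cohort size meeting the power goal.
#'
#' @inheritParams solve_cohort_size
#' @param cluster_range Integer vector of total cluster counts to examine.
#' @return Data frame with columns `clusters`, `per_sequence`,
#'   `cohort_size` (NA when infeasible), `feasible`, and the attained power
#'   of each contrast at the solution.
#' @export
power_frontier <- function(design, spec, cspec, vspec, contrasts,
                           plan = NULL, cluster_range, power_goal = 0.8,
                           n_max = 1000L,
                           method = c("f_small_sample", "chisq")) {
  method <- match.arg(method)
  if (length(cluster_range) == 0L)
    stop("`cluster_range` is empty", call. = FALSE)
  if (inherits(contrasts, "contrast_spec")) contrasts <- list(contrasts)
  labels <- vapply(contrasts, `[[`, character(1), "label")
  rows <- lapply(as.integer(cluster_range), function(I) {
    S <- design$n_sequences
    m <- rep(I %/% S, S)
    extra <- I %% S
    if (extra > 0) m[seq_len(extra)] <- m[seq_len(extra)] + 1L
    if (any(m < 1L))
      return(data.frame(clusters = I,
                        per_sequence = paste(m, collapse = "+"),
                        cohort_size = NA_integer_, feasible = FALSE))
    des <- swd_design(design$n_periods, S, m, cohort_size = 1L,
                      il_split = design$il_split,
                      cohort_type = design$cohort_type,
                      crossover_period = design$crossover_period)
    n <- tryCatch(
      solve_cohort_size(des, spec, cspec, vspec, contrasts, plan,
                        power_goal, n_max, method),
      error = function(e) NA_integer_)
    base <- data.frame(clusters = I, per_sequence = paste(m, collapse = "+"),
                       cohort_size = as.integer(n), feasible = !is.na(n))
    pw <- rep(NA_real_, length(contrasts))
    if (!is.na(n)) pw <- attr(n, "power")$power
    base[paste0("power_", labels)] <- as.list(pw)
    base
  })
  do.call(rbind, rows)
}
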