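#' Planned observation pattern for incomplete designs
#'
#' Encodes which calendar periods are observed. For closed cohorts and
#' cross-sectional samples a single representative pattern (a logical vector
#' over the `T` calendar periods) suffices and is replicated over the
#' cluster; for open cohorts a list gives each individual's own pattern.
#' Cross-sectional sampling is a special case of an open cohort in which
#' each individual's pattern observes exactly one period.
#'
#' @param observed A logical vector of length `T` (representative
#'   individual), or a list of such vectors (open cohort, one per
#'   individual).
#' @param n_periods Number of calendar periods `T`.
#' @return An object of class `observation_pattern`.
#' @examples
#' observation_pattern(c(TRUE, TRUE, FALSE, FALSE), n_periods = 4)
#' @export
observation_pattern <- function(observed, n_periods) {
  if (!is_count(n_periods))
    stop("`n_periods` must be a positive integer", call. = FALSE)
  n_periods <- as.integer(n_periods)
  per_individual <- is.list(observed)
  pats <- if (per_individual) observed else list(observed)
  for (p in pats) {
    if (!is.logical(p) || length(p) != n_periods || anyNA(p))
      stop("each pattern must be a logical vector of length ", n_periods,
           call. = FALSE)
    if (!any(p))
      stop("each observed individual needs at least one observed period",
           call. = FALSE)
  }
  structure(list(observed = pats, per_individual = per_individual,
                 n_periods = n_periods),
            class = "observation_pattern")
}

complete_pattern <- function(n_periods) {
  observation_pattern(rep(TRUE, n_periods), n_periods)
}

#' Build a cluster's incidence matrix
#'
#' The incidence matrix `K` has one row per planned observation and one
#' column per calendar period; each row contains a single 1 marking the
#' period in which that observation is taken. For a closed cohort the
#' representative individual's incidence block `K_s` is replicated over the
#' cohort by a Kronecker product (in the package's individual-major row
#' order, `K = 1_N %x% K_s`); for an open cohort the per-individual blocks
#' are stacked. Alongside `K`, the row-selection indices into the complete
#' individual-major observation layout are returned; these are what
#' [apply_incidence()] uses to restrict design and correlation matrices.
#'
#' @param pattern An [observation_pattern()].
#' @param design An [swd_design()].
#' @param cluster Cluster index in `1, ..., I`.
#' @return An object of class `incidence_matrix`: list with the binary
#'   matrix `K`, the selection indices `rows`, `n_obs` and `n_periods`.
#' @export
build_incidence <- function(pattern, design, cluster) {
  stopifnot(inherits(pattern, "observation_pattern"),
            inherits(design, "swd_design"))
  if (!is_count(cluster) || cluster > design$n_clusters)
    stop("`cluster` out of range", call. = FALSE)
  Tt <- design$n_periods
  if (pattern$n_periods != Tt)
    stop("pattern has ", pattern$n_periods, " periods but the design has ",
         Tt, call. = FALSE)
  N <- design$cohort_size[cluster]

  if (pattern$per_individual) {
    if (length(pattern$observed) != N)
      stop("open-cohort pattern lists ", length(pattern$observed),
           " individuals but cluster ", cluster, " has ", N, call. = FALSE)
    blocks <- lapply(pattern$observed, individual_incidence, n_periods = Tt)
    K <- do.call(rbind, blocks)
    rows <- unlist(lapply(seq_len(N), function(k)
      (k - 1L) * Tt + which(pattern$observed[[k]])))
  } else {
    Ks <- individual_incidence(pattern$observed[[1L]], Tt)
    # individual-major replication of the representative block
    K <- kronecker(matrix(1, N, 1L), Ks)
    rows <- as.integer(outer(which(pattern$observed[[1L]]),
                             (seq_len(N) - 1L) * Tt, `+`))
  }
  validate_incidence(K)
  structure(list(K = K, rows = rows, n_obs = nrow(K), n_periods = Tt),
            class = "incidence_matrix")
}

individual_incidence <- function(observed, n_periods) {
  diag(n_periods)[observed, , drop = FALSE]
}

validate_incidence <- function(K) {
  rs <- rowSums(K)
  if (any(rs != 1))
    stop("malformed incidence matrix: every row must contain exactly one 1",
         call. = FALSE)
  invisible(K)
}

#' Restrict complete-design matrices to the observed rows
#'
#' Applies the row-selection operator induced by an incidence matrix to a
#' complete observation-level design matrix and working correlation matrix:
#' the design matrix keeps the selected rows and the correlation matrix the
#' selected rows and columns (`S R S^T`).
#'
#' @param incidence An [build_incidence()] result.
#' @param design_matrix Complete design matrix, one row per
#'   (individual, period) cell in individual-major order.
#' @param correlation Complete working correlation matrix over the same rows.
#' @return A list with elements `design_matrix` and `correlation`.
#' @export
apply_incidence <- function(incidence, design_matrix, correlation) {
  stopifnot(inherits(incidence, "incidence_matrix"))
  n <- max(incidence$rows)
  if (nrow(design_matrix) < n)
    stop("design matrix has ", nrow(design_matrix),
         " rows; selection needs at least ", n, call. = FALSE)
  if (nrow(correlation) != nrow(design_matrix) ||
      ncol(correlation) != nrow(design_matrix))
    stop("correlation must be square over the design matrix rows",
         call. = FALSE)
  i <- incidence$rows
  list(design_matrix = design_matrix[i, , drop = FALSE],
       correlation = correlation[i, i, drop = FALSE])
}

# Resolve a `patterns` argument (NULL, single pattern, per-sequence list, or
# per-cluster list) to one observation_pattern per cluster, or NULL.
resolve_patterns <- function(patterns, design) {
  if (is.null(patterns)) return(NULL)
  if (inherits(patterns, "observation_pattern"))
    return(rep(list(patterns), design$n_clusters))
  if (!is.list(patterns))
    stop("`patterns` must be an observation_pattern or a list of them",
         call. = FALSE)
  if (length(patterns) == design$n_sequences)
    return(lapply(seq_len(design$n_clusters), function(i)
      patterns[[design$cluster_sequence[i]]]))
  if (length(patterns) == design$n_clusters)
    return(patterns)
  stop("`patterns` must have length S (per sequence) or I (per cluster)",
       call. = FALSE)
}
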