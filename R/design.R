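#' Specify a multilevel-intervention stepped wedge design
#'
#' Describes the randomization topology of a trial in which clusters cross
#' over from control to a cluster-level (CL) intervention at randomized
#' times, while individuals within each cluster are independently randomized
#' to an individual-level (IL) intervention arm.
#'
#' By default the design is a standard complete wedge: sequence `s` crosses
#' over at calendar period `s + 1`, so no cluster is on the CL intervention
#' in period 1 and every sequence has crossed over by the final period.
#' Non-standard crossover schedules, including comparator sequences that
#' never cross over (encoded as `n_periods + 1`), can be given explicitly.
#'
#' @param n_periods Total number of calendar periods `T` (for a complete
#'   design every individual is observed in every period, so `J = T`).
#' @param n_sequences Number of distinct crossover sequences `S`.
#' @param clusters_per_sequence Number of clusters randomized to each
#'   sequence; a scalar is recycled to length `S`.
#' @param cohort_size Individuals per cluster `N_i`; a scalar or a vector
#'   over all `I` clusters.
#' @param il_split Fraction of each cluster's cohort randomized to the IL
#'   intervention arm. The IL-treated count is `ceiling(N_i * il_split)`,
#'   the remainder is IL-control, so an odd cohort deterministically rounds
#'   toward the treated arm.
#' @param cohort_type `"closed_cohort"` (same individuals every period),
#'   `"cross_sectional"` (a fresh sample each period; `cohort_size` is then
#'   the per-period sample size and the same-slot observations in different
#'   periods are different people), or `"open_cohort"`.
#' @param crossover_period Optional integer vector of length `S`: the first
#'   calendar period each sequence is on the CL intervention, each in
#'   `2, ..., T + 1` where `T + 1` means the sequence never crosses over.
#'   Defaults to the standard wedge `(2, 3, ..., S + 1)`, which requires
#'   `S <= T - 1`.
#'
#' @return An object of class `swd_design`: a list with elements
#'   `n_periods`, `n_sequences`, `clusters_per_sequence`, `crossover_period`,
#'   `cohort_type`, `n_clusters`, `cluster_sequence`, `cohort_size`,
#'   `il_treated`, `il_control`.
#'
#' @examples
#' # the six-period, five-sequence design with 13 clusters per sequence
#' des <- swd_design(n_periods = 6, n_sequences = 5,
#'                   clusters_per_sequence = 13, cohort_size = 15,
#'                   il_split = 0.5)
#' print(des)
#' @export
swd_design <- function(n_periods, n_sequences, clusters_per_sequence,
                       cohort_size, il_split = 0.5,
                       cohort_type = c("closed_cohort", "cross_sectional",
                                       "open_cohort"),
                       crossover_period = NULL) {
  cohort_type <- match.arg(cohort_type)
  if (!is_count(n_periods) || !is_count(n_sequences))
    stop("`n_periods` and `n_sequences` must be positive integers",
         call. = FALSE)
  n_periods <- as.integer(n_periods)
  n_sequences <- as.integer(n_sequences)

  if (length(clusters_per_sequence) == 1L)
    clusters_per_sequence <- rep(clusters_per_sequence, n_sequences)
  if (length(clusters_per_sequence) != n_sequences ||
      !all(vapply(clusters_per_sequence, is_count, logical(1))))
    stop("`clusters_per_sequence` must be positive integers of length ",
         n_sequences, call. = FALSE)
  clusters_per_sequence <- as.integer(clusters_per_sequence)

  if (is.null(crossover_period)) {
    if (n_sequences > n_periods - 1L)
      stop("a standard complete wedge needs n_sequences <= n_periods - 1; ",
           "supply `crossover_period` for other schedules", call. = FALSE)
    crossover_period <- seq(2L, n_sequences + 1L)
  }
  crossover_period <- as.integer(crossover_period)
  if (length(crossover_period) != n_sequences ||
      any(crossover_period < 2L) || any(crossover_period > n_periods + 1L))
    stop("`crossover_period` must have length ", n_sequences,
         " with entries in 2, ..., T + 1 (T + 1 = never crosses over)",
         call. = FALSE)
  if (is.unsorted(crossover_period, strictly = FALSE))
    stop("crossover periods must be nondecreasing across sequences",
         call. = FALSE)

  if (!is.numeric(il_split) || length(il_split) != 1L ||
      is.na(il_split) || il_split < 0 || il_split > 1)
    stop("`il_split` must be a single number in [0, 1]", call. = FALSE)

  n_clusters <- sum(clusters_per_sequence)
  cluster_sequence <- rep(seq_len(n_sequences), clusters_per_sequence)

  if (length(cohort_size) == 1L)
    cohort_size <- rep(cohort_size, n_clusters)
  if (length(cohort_size) != n_clusters ||
      !all(cohort_size >= 0) || any(cohort_size != floor(cohort_size)))
    stop("`cohort_size` must be nonnegative integers, scalar or of length ",
         n_clusters, call. = FALSE)
  cohort_size <- as.integer(cohort_size)

  il_treated <- as.integer(ceiling(cohort_size * il_split))
  il_control <- cohort_size - il_treated

  structure(
    list(n_periods = n_periods,
         n_sequences = n_sequences,
         clusters_per_sequence = clusters_per_sequence,
         crossover_period = crossover_period,
         cohort_type = cohort_type,
         n_clusters = n_clusters,
         cluster_sequence = cluster_sequence,
         cohort_size = cohort_size,
         il_split = as.numeric(il_split),
         il_treated = il_treated,
         il_control = il_control),
    class = "swd_design")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

#' @export
print.swd_design <- function(x, ...) {
  cat("Multilevel-intervention stepped wedge design\n")
  cat(sprintf("  periods: %d   sequences: %d   clusters: %d (%s)\n",
              x$n_periods, x$n_sequences, x$n_clusters,
              paste(x$clusters_per_sequence, collapse = "+")))
  cat(sprintf("  sampling: %s   individuals: %d (IL-treated %d / control %d)\n",
              x$cohort_type, sum(x$cohort_size), sum(x$il_treated),
              sum(x$il_control)))
  cat(schematic(x), sep = "\n")
  invisible(x)
}

#' Plain-text wedge schematic
#'
#' One row per sequence and one column per calendar period; `.` marks the
#' control condition and `X` the CL intervention condition.
#'
#' @param design An [swd_design()] object.
#' @return A character vector, one element per printed line.
#' @export
schematic <- function(design) {
  stopifnot(inherits(design, "swd_design"))
  header <- paste0("  sequence ", format(seq_len(design$n_sequences)), "  ")
  lines <- vapply(seq_len(design$n_sequences), function(s) {
    cells <- ifelse(seq_len(design$n_periods) >= design$crossover_period[s],
                    "X", ".")
    paste0(header[s], paste(cells, collapse = " "),
           sprintf("   (m=%d)", design$clusters_per_sequence[s]))
  }, character(1))
  c(paste0("  period     ",
           paste(seq_len(design$n_periods), collapse = " ")), lines)
}

# Clusters sharing (sequence, N0, N1) have identical design matrices and
# covariance; power loops run over these groups instead of all I clusters.
cluster_groups <- function(design) {
  key <- paste(design$cluster_sequence, design$il_control,
               design$il_treated, sep = "/")
  idx <- split(seq_len(design$n_clusters), key)
  lapply(idx, function(i)
    list(cluster = i[1L], count = length(i)))
}
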