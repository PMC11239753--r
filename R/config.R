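#' Read a study configuration file
#'
#' Parses a YAML configuration into the specification bundle used by the
#' power, sample-size, frontier and simulation commands. Parsing is strict:
#' unknown keys are rejected and all missing required keys are reported
#' together. Scientific parameters (coefficients, correlations, significance
#' levels, scaling constants) have no defaults and must be explicit.
#'
#' @param path Path to the YAML file.
#' @return An object of class `mli_config`: list with `design`,
#'   `mean_model`, `correlation`, `variance`, `contrasts`, `plan`,
#'   `simulation` (may be `NULL`), `power_goal`, `n_max`, and the source
#'   file's MD5 in `attr(, "hash")`.
#' @examples
#' cfg <- read_mli_config(system.file("extdata", "diabetes_example.yaml",
#'                                    package = "mliswd"))
#' @export
read_mli_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  bundle <- build_config(raw)
  attr(bundle, "hash") <- unname(tools::md5sum(path))
  bundle
}

build_config <- function(raw) {
  errs <- character(0)
  need <- function(block, keys, where) {
    missing <- setdiff(keys, names(block))
    if (length(missing))
      errs <<- c(errs, paste0("missing key(s) in ", where, ": ",
                              paste(missing, collapse = ", ")))
    length(missing) == 0L
  }
  reject_unknown <- function(block, keys, where) {
    extra <- setdiff(names(block), keys)
    if (length(extra))
      errs <<- c(errs, paste0("unknown key(s) in ", where, ": ",
                              paste(extra, collapse = ", ")))
  }

  top_keys <- c("design", "mean_model", "correlation", "variance",
                "contrasts", "multiplicity", "simulation", "power_goal",
                "n_max")
  reject_unknown(raw, top_keys, "top level")
  need(raw, c("design", "mean_model", "correlation", "variance",
              "contrasts"), "top level")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  dz <- raw$design
  reject_unknown(dz, c("n_periods", "n_sequences", "clusters_per_sequence",
                       "cohort_size", "il_split", "cohort_type",
                       "crossover_period"), "design")
  need(dz, c("n_periods", "n_sequences", "clusters_per_sequence",
             "cohort_size", "il_split"), "design")

  mm <- raw$mean_model
  reject_unknown(mm, c("effect_model", "time_trend", "poly_degree", "link",
                       "theta", "scaling", "il_start_period",
                       "membership_covariate"), "mean_model")
  need(mm, c("effect_model", "time_trend", "link", "theta", "scaling"),
       "mean_model")
  if (is.list(mm$scaling))
    reject_unknown(mm$scaling, c("il", "cl", "int"), "mean_model$scaling")

  cr <- raw$correlation
  reject_unknown(cr, c("family", "alpha", "inter_decay"), "correlation")
  need(cr, "family", "correlation")
  if (!identical(cr$family, "independence")) {
    need(cr, "alpha", "correlation")
    if (is.list(cr$alpha))
      reject_unknown(cr$alpha, c("within_period", "inter_period",
                                 "within_individual"), "correlation$alpha")
  }

  vr <- raw$variance
  reject_unknown(vr, c("family", "dispersion"), "variance")
  need(vr, c("family", "dispersion"), "variance")

  if (!is.list(raw$contrasts) || length(raw$contrasts) == 0L)
    errs <- c(errs, "contrasts: need a nonempty list")
  for (i in seq_along(raw$contrasts)) {
    ct <- raw$contrasts[[i]]
    reject_unknown(ct, c("label", "L", "ell", "alpha", "family",
                         "include_in_search"), paste0("contrasts[", i, "]"))
    need(ct, c("label", "L"), paste0("contrasts[", i, "]"))
    if (!is.null(ct$alpha) && !is.null(ct$family))
      errs <- c(errs, paste0("contrasts[", i, "]: give alpha or family, ",
                             "not both"))
    if (is.null(ct$alpha) && is.null(ct$family))
      errs <- c(errs, paste0("contrasts[", i, "]: needs alpha or family"))
  }
  for (i in seq_along(raw$multiplicity)) {
    fm <- raw$multiplicity[[i]]
    reject_unknown(fm, c("name", "alpha", "adjust"),
                   paste0("multiplicity[", i, "]"))
    need(fm, c("name", "alpha"), paste0("multiplicity[", i, "]"))
  }
  if (!is.null(raw$simulation)) {
    reject_unknown(raw$simulation, c("n_replicates", "seed", "generator"),
                   "simulation")
    need(raw$simulation, c("n_replicates", "seed"), "simulation")
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  design <- swd_design(
    n_periods = dz$n_periods, n_sequences = dz$n_sequences,
    clusters_per_sequence = unlist(dz$clusters_per_sequence),
    cohort_size = unlist(dz$cohort_size), il_split = dz$il_split,
    cohort_type = dz$cohort_type %||% "closed_cohort",
    crossover_period = if (!is.null(dz$crossover_period))
      unlist(dz$crossover_period))

  scaling <- unlist(mm$scaling)
  model <- mean_model(
    effect_model = mm$effect_model, time_trend = mm$time_trend,
    link = mm$link, theta = unlist(mm$theta), scaling = scaling,
    poly_degree = mm$poly_degree %||% 2L,
    il_start_period = mm$il_start_period %||% 1L,
    membership_covariate = mm$membership_covariate %||% FALSE)
  check_theta(model, design$n_periods)

  corr <- correlation_structure(
    family = cr$family, alpha = unlist(cr$alpha),
    inter_decay = cr$inter_decay %||% FALSE)
  varr <- variance_structure(family = vr$family, dispersion = vr$dispersion)

  contrasts <- lapply(raw$contrasts, function(ct) {
    L <- if (is.list(ct$L)) do.call(rbind, lapply(ct$L, unlist))
         else unlist(ct$L)
    contrast(L, ell = if (!is.null(ct$ell)) unlist(ct$ell),
             alpha = ct$alpha, label = ct$label, family = ct$family,
             include_in_search = ct$include_in_search %||% TRUE)
  })
  plan <- if (!is.null(raw$multiplicity))
    lapply(raw$multiplicity, function(fm)
      list(name = fm$name, alpha = fm$alpha,
           adjust = fm$adjust %||% "bonferroni"))
  resolve_alphas(contrasts, plan)  # fail fast on unresolvable levels

  structure(list(design = design, mean_model = model, correlation = corr,
                 variance = varr, contrasts = contrasts, plan = plan,
                 simulation = raw$simulation,
                 power_goal = raw$power_goal %||% 0.8,
                 n_max = raw$n_max %||% 1000L),
            class = "mli_config")
}

#' Write a configuration bundle back to YAML
#'
#' Round-trips with [read_mli_config()]: the written file parses to an
#' equivalent bundle.
#'
#' @param bundle An `mli_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mli_config <- function(bundle, path) {
  stopifnot(inherits(bundle, "mli_config"))
  dz <- bundle$design
  mm <- bundle$mean_model
  cr <- bundle$correlation
  raw <- list(
    design = list(
      n_periods = dz$n_periods, n_sequences = dz$n_sequences,
      clusters_per_sequence = as.list(dz$clusters_per_sequence),
      cohort_size = as.list(dz$cohort_size),
      il_split = dz$il_split,
      cohort_type = dz$cohort_type,
      crossover_period = as.list(dz$crossover_period)),
    mean_model = list(
      effect_model = mm$effect_model, time_trend = mm$time_trend,
      poly_degree = mm$poly_degree, link = mm$link,
      theta = as.list(mm$theta),
      scaling = as.list(mm$scaling),
      il_start_period = mm$il_start_period,
      membership_covariate = mm$membership_covariate),
    correlation = list(family = cr$family,
                       alpha = as.list(cr$alpha),
                       inter_decay = cr$inter_decay),
    variance = list(family = bundle$variance$family,
                    dispersion = bundle$variance$dispersion),
    contrasts = lapply(bundle$contrasts, function(ct) {
      out <- list(label = ct$label,
                  L = if (nrow(ct$L) == 1L) as.list(drop(ct$L))
                      else lapply(seq_len(nrow(ct$L)),
                                  function(i) as.list(ct$L[i, ])),
                  ell = as.list(ct$ell),
                  include_in_search = ct$include_in_search)
      if (!is.null(ct$alpha)) out$alpha <- ct$alpha
      if (!is.null(ct$family)) out$family <- ct$family
      out
    }),
    power_goal = bundle$power_goal,
    n_max = bundle$n_max)
  if (!is.null(bundle$plan)) raw$multiplicity <- bundle$plan
  if (!is.null(bundle$simulation)) raw$simulation <- bundle$simulation
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Run an analysis command on a configuration bundle
#'
#' Executes one of the analysis commands and writes a machine-readable
#' report (CSV or JSON) plus a human-readable summary including the wedge
#' schematic, the package version and the configuration hash.
#'
#' @param bundle An `mli_config` from [read_mli_config()].
#' @param command `"power"` (Wald power for every contrast, under both the
#'   small-sample F and chi-square references), `"samplesize"` (minimal
#'   cohort size for the configured goal), `"frontier"`, `"simulate"`
#'   (empirical power), or `"schematic"`.
#' @param out_dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @param method Reference distribution for searches and simulation.
#' @param seed Overrides the configuration's simulation seed.
#' @param cluster_range Total-cluster counts for the frontier command.
#' @return List with the computed `result` and the written `files`,
#'   invisibly.
#' @export
run_report <- function(bundle, command = c("power", "samplesize", "frontier",
                                           "simulate", "schematic"),
                       out_dir = ".", format = c("csv", "json"),
                       method = c("f_small_sample", "chisq"), seed = NULL,
                       cluster_range = NULL) {
  stopifnot(inherits(bundle, "mli_config"))
  command <- match.arg(command)
  format <- match.arg(format)
  method <- match.arg(method)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  result <- switch(command,
    power = {
      tabs <- lapply(c("f_small_sample", "chisq"), function(m)
        mli_power(bundle$design, bundle$mean_model, bundle$correlation,
                  bundle$variance, bundle$contrasts, bundle$plan, method = m,
                  power_goal = bundle$power_goal))
      out <- do.call(rbind, lapply(tabs, as.data.frame))
      attr(out, "omega") <- attr(tabs[[1L]], "omega")
      out
    },
    samplesize = {
      n <- solve_cohort_size(bundle$design, bundle$mean_model,
                             bundle$correlation, bundle$variance,
                             bundle$contrasts, bundle$plan,
                             power_goal = bundle$power_goal,
                             n_max = bundle$n_max, method = method)
      cbind(data.frame(cohort_size = as.integer(n),
                       total_individuals = as.integer(n) *
                         bundle$design$n_clusters,
                       power_goal = bundle$power_goal),
            stats::setNames(
              as.data.frame(t(attr(n, "power")$power)),
              paste0("power_", attr(n, "power")$label)))
    },
    frontier = {
      rng <- cluster_range %||% bundle$design$n_clusters
      power_frontier(bundle$design, bundle$mean_model, bundle$correlation,
                     bundle$variance, bundle$contrasts, bundle$plan,
                     cluster_range = rng, power_goal = bundle$power_goal,
                     n_max = bundle$n_max, method = method)
    },
    simulate = {
      sim <- bundle$simulation %||%
        stop("config has no simulation block", call. = FALSE)
      empirical_power(bundle$design, bundle$mean_model, bundle$correlation,
                      bundle$variance, bundle$contrasts, bundle$plan,
                      n_replicates = sim$n_replicates,
                      seed = seed %||% sim$seed, method = method)
    },
    schematic = data.frame(line = schematic(bundle$design)))

  stem <- file.path(out_dir, paste0(command, "_report"))
  report_file <- if (format == "csv") {
    utils::write.csv(as.data.frame(result), paste0(stem, ".csv"),
                     row.names = FALSE)
    paste0(stem, ".csv")
  } else {
    jsonlite::write_json(as.data.frame(result), paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA)
    paste0(stem, ".json")
  }

  summary_file <- file.path(out_dir, paste0(command, "_summary.txt"))
  lines <- c(
    sprintf("mliswd %s  |  command: %s  |  config hash: %s",
            as.character(utils::packageVersion("mliswd")), command,
            attr(bundle, "hash") %||% "(in-memory)"),
    "", schematic(bundle$design), "",
    utils::capture.output(print(as.data.frame(result), row.names = FALSE)))
  writeLines(lines, summary_file)

  invisible(list(result = result, files = c(report_file, summary_file)))
}
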