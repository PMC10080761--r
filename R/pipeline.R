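#' Default end-to-end pipeline configuration
#'
#' A demonstration-scale configuration: a 500-gene universe, 200 case
#' trios and 92 sibling trios at 1.02 coding DNMs per trio, 20 spiked risk
#' genes at relative risk 20, an MLE grid of 5..200 in steps of 5 with
#' 2000 permutations, and 500 TADA null samplings. Every filtering
#' threshold is present so a saved configuration fully determines a run.
#'
#' @return Nested named list; edit fields and pass to [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 101L,
    sim = list(
      n_genes = 500L, n_trios = 200L, n_sib_trios = 92L,
      total_coding_rate = 1.02, damaging_frac = 0.30,
      class_props = c(syn = 0.25, mis = 0.62, lof = 0.13),
      g_true = 20L, gamma = 20,
      inject_failures = c(gq = 3L, alt_depth = 5L)
    ),
    filter = default_filter_config(),
    mle = list(grid_min = 5L, grid_max = 200L, grid_step = 5L,
               permutations = 2000L, match_rule = "exact"),
    tada = list(beta = 1, n_null_samplings = 500L, missense = "all"),
    enrich = list(min_count = 2L)
  )
}

required_config_fields <- function() {
  list(
    c("seed"),
    c("sim", "n_genes"), c("sim", "n_trios"), c("sim", "n_sib_trios"),
    c("sim", "total_coding_rate"), c("sim", "damaging_frac"),
    c("sim", "g_true"), c("sim", "gamma"),
    c("filter", "ibd_min"), c("filter", "ibd_max"), c("filter", "k_sd"),
    c("filter", "gq_min"), c("filter", "fs_max"), c("filter", "dp_min"),
    c("filter", "depth_ratio_min"), c("filter", "alt_depth_min"),
    c("filter", "ab_min"), c("filter", "parent_alt_tol"),
    c("mle", "grid_min"), c("mle", "grid_max"), c("mle", "grid_step"),
    c("mle", "permutations"), c("mle", "match_rule"),
    c("tada", "beta"), c("tada", "n_null_samplings"), c("tada", "missense"),
    c("enrich", "min_count")
  )
}

#' Validate a pipeline configuration
#'
#' Checks that every required field is present, naming the first missing
#' one.
#'
#' @param config Configuration list (see [default_config()]).
#' @return `config`, invisibly, on success.
#' @export
validate_config <- function(config) {
  for (path in required_config_fields()) {
    node <- config
    for (key in path) {
      node <- node[[key]]
      if (is.null(node)) {
        stop("configuration is missing required field: ",
             paste(path, collapse = "$"), call. = FALSE)
      }
    }
  }
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#' @param config Configuration list.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  # named atomic vectors must become maps to survive the YAML round trip
  if (!is.null(config$sim$class_props)) {
    config$sim$class_props <- as.list(config$sim$class_props)
  }
  if (!is.null(config$sim$inject_failures)) {
    config$sim$inject_failures <- as.list(config$sim$inject_failures)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  config <- yaml::read_yaml(path)
  if (!is.null(config$sim$class_props)) {
    config$sim$class_props <- unlist(config$sim$class_props)
  }
  if (!is.null(config$sim$inject_failures)) {
    config$sim$inject_failures <- unlist(config$sim$inject_failures)
  }
  validate_config(config)
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-cohort DNM analysis pipeline
#'
#' Executes, in order: rate-table simulation, risk-gene spiking, case and
#' sibling cohort simulation, raw-call generation with the configured
#' QC-failure injections, the filtering cascade, class-wise burden testing,
#' the damaging-DNM recurrence summary and risk-gene MLE, de novo TADA, and
#' the recurrent-gene screen. All randomness fans out deterministically
#' from `config$seed` (fixed per-stage offsets), so two runs of the same
#' configuration are identical.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Optional directory; when given, per-stage artifacts are
#'   written (`rates.tsv`, `dnms.tsv`, `burden.tsv`, `mle.json`,
#'   `tada.tsv`, `audit.json`, `truth.json`, `summary.json`).
#' @return List of class `dnmrisk_report` with elements `config_hash`,
#'   `seed`, `rates`, `truth`, `filter`, `dnms`, `class_mix`, `burden`,
#'   `summary`, `mle`, `tada`, `recurrent`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  seed <- as.integer(config$seed)
  sim <- config$sim

  rates <- simulate_rates(sim$n_genes, sim$total_coding_rate, seed + 1L,
                          class_props = sim$class_props %||%
                            c(syn = 0.25, mis = 0.62, lof = 0.13))
  risk_genes <- withr::with_seed(seed + 2L,
                                 sample(rates$gene, sim$g_true))
  truth <- risk_truth(risk_genes, sim$gamma, seed + 3L)
  cases <- simulate_dnm_cohort(rates, sim$n_trios, truth, sim$damaging_frac)
  sibs <- simulate_dnm_cohort(rates, sim$n_sib_trios,
                              risk_truth(character(), 1, seed + 4L),
                              sim$damaging_frac)
  inject <- sim$inject_failures %||% integer()
  calls <- simulate_raw_calls(cases, inject, seed = seed + 5L)
  filt <- filter_cohort(calls, config = config$filter)
  dnms <- filt$dnms

  burden <- cohort_burden(dnms, rates, sim$n_trios)
  summ <- summarize_cohort(dnms, sibs$dnms, sim$n_trios, sim$n_sib_trios)
  grid <- seq(config$mle$grid_min, config$mle$grid_max, config$mle$grid_step)
  mle <- mle_risk_genes(summ, rates, grid = grid,
                        n_permutations = config$mle$permutations,
                        match_rule = config$mle$match_rule, seed = seed + 6L)
  tada <- run_tada(dnms, sibs$dnms, rates, n_trios = sim$n_trios,
                   mle_G = mle$mle_G, total_genes = nrow(rates),
                   beta = config$tada$beta,
                   n_null_samplings = config$tada$n_null_samplings,
                   seed = seed + 7L, missense = config$tada$missense)
  recurrent <- recurrence_screen(dnms, config$enrich$min_count)

  mix <- table(factor(dnms$class,
                      levels = c("synonymous", "missense", "lof",
                                 "nonframeshift")))
  class_mix <- 100 * as.numeric(mix) / max(1L, sum(mix))
  names(class_mix) <- names(mix)

  report <- structure(
    list(config_hash = config_hash(config), seed = seed,
         rates = rates, truth = truth, filter = filt, dnms = dnms,
         class_mix = class_mix, burden = burden, summary = summ,
         mle = mle, tada = tada, recurrent = recurrent),
    class = "dnmrisk_report"
  )
  if (!is.null(out_dir)) write_report(report, config, out_dir)
  report
}

write_report <- function(report, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stamp <- list(config_hash = report$config_hash, seed = report$seed)
  write_rates_tsv(report$rates, file.path(out_dir, "rates.tsv"))
  write_dnms_tsv(report$dnms, file.path(out_dir, "dnms.tsv"))
  utils::write.table(report$burden, file.path(out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_mle_json(c(stamp, unclass(report$mle)),
                 file.path(out_dir, "mle.json"))
  utils::write.table(report$tada$genes, file.path(out_dir, "tada.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_audit_json(report$filter, file.path(out_dir, "audit.json"))
  write_truth_json(report$truth, file.path(out_dir, "truth.json"))
  jsonlite::write_json(
    c(stamp, list(
      n_dnms = nrow(report$dnms),
      class_mix_percent = as.list(report$class_mix),
      summary = unclass(report$summary),
      mle_G = report$mle$mle_G,
      tada_params = unclass(report$tada$params),
      n_candidates_q10 = sum(report$tada$genes$q_value <= 0.1),
      recurrent_genes = report$recurrent$gene)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
#' @method print dnmrisk_report
print.dnmrisk_report <- function(x, ...) {
  cat("dnmrisk pipeline report (seed", x$seed, ", config",
      substr(x$config_hash, 1, 8), ")\n")
  cat(" DNMs retained:", nrow(x$dnms), "| class mix (%):",
      paste(sprintf("%s %.1f", names(x$class_mix), x$class_mix),
            collapse = ", "), "\n")
  cat(" Risk-gene MLE:", x$mle$mle_G, "| TADA candidates (q <= 0.1):",
      sum(x$tada$genes$q_value <= 0.1), "\n")
  invisible(x)
}
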