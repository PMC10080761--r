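#' Describe an external DNM cohort
#'
#' @param name Cohort label (e.g. a disease abbreviation).
#' @param n_samples Number of sequenced probands/trios (>= 1).
#' @param dnm_genes Data frame of the cohort's DNMs with at least a `gene`
#'   column; optional `class` and `damaging` columns refine which DNMs
#'   count as damaging.
#' @return An object of class `external_cohort`.
#' @export
external_cohort <- function(name, n_samples, dnm_genes) {
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  if (!is.data.frame(dnm_genes) || !"gene" %in% names(dnm_genes)) {
    stop("`dnm_genes` must be a data frame with a gene column", call. = FALSE)
  }
  structure(list(name = name, n_samples = as.integer(n_samples),
                 dnm_genes = dnm_genes),
            class = "external_cohort")
}

#' Poisson-tail enrichment of candidate genes in an external cohort
#'
#' For each queried gene, the expected number of damaging DNMs in the
#' external cohort is `2 * n_samples * (mu_mis + mu_lof)` and the p-value
#' is the Poisson upper tail `P(X >= observed)`. By default only DNMs
#' flagged damaging (LOF or probably-damaging missense, when those columns
#' are present) are counted as observations.
#'
#' @param genes Character vector of gene symbols to test.
#' @param cohort An [external_cohort()].
#' @param rates Per-gene mutation-rate table covering `genes`.
#' @param damaging_only Count only damaging DNMs (default) or all DNMs.
#' @return Data frame: `gene`, `cohort`, `n_samples`, `observed`,
#'   `expected`, `p_value`.
#' @export
external_enrichment <- function(genes, cohort, rates, damaging_only = TRUE) {
  stopifnot(inherits(cohort, "external_cohort"))
  validate_rates(rates)
  missing <- setdiff(genes, rates$gene)
  if (length(missing)) {
    stop("gene(s) absent from the rate table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- cohort$dnm_genes
  if (damaging_only) {
    if (!is.null(d$damaging)) {
      d <- d[as.logical(d$damaging), , drop = FALSE]
    } else if (!is.null(d$class) && !is.null(d$damaging_pred)) {
      d <- d[d$class == "lof" |
               (!is.na(d$damaging_pred) & d$damaging_pred == "probably"), ,
             drop = FALSE]
    }
  }
  idx <- match(genes, rates$gene)
  expected <- 2 * cohort$n_samples * (rates$mu_mis[idx] + rates$mu_lof[idx])
  observed <- as.integer(table(factor(d$gene, levels = genes)))
  data.frame(
    gene = genes, cohort = cohort$name, n_samples = cohort$n_samples,
    observed = observed, expected = expected,
    p_value = stats::ppois(observed - 1, expected, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Fisher's exact carrier burden test (case vs control)
#'
#' Two-sided exact test on the 2x2 carrier table, using the standard
#' minimum-likelihood convention (sum of hypergeometric tables no more
#' probable than the observed one) and the conditional maximum-likelihood
#' odds ratio, as implemented in [stats::fisher.test()].
#'
#' @param case_carriers,case_n Carriers and total among cases.
#' @param control_carriers,control_n Carriers and total among controls.
#' @return List with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
#' @examples
#' fisher_burden(9, 1155, 2, 2813)
fisher_burden <- function(case_carriers, case_n, control_carriers, control_n) {
  counts <- c(case_carriers, case_n, control_carriers, control_n)
  if (any(counts < 0) || case_carriers > case_n || control_carriers > control_n) {
    stop("invalid 2x2 carrier counts", call. = FALSE)
  }
  tab <- matrix(c(case_carriers, case_n - case_carriers,
                  control_carriers, control_n - control_carriers),
                nrow = 2,
                dimnames = list(c("carrier", "non_carrier"),
                                c("case", "control")))
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Genes with recurrent damaging DNMs
#'
#' Tallies damaging DNMs per gene and keeps genes reaching `min_count`
#' hits — the screen that nominates genes for gene-level testing.
#'
#' @param dnms DNM record data frame with `gene` and `damaging` columns.
#' @param min_count Minimum number of damaging DNMs (default 2, i.e.
#'   "multiple hits").
#' @return Data frame `gene`, `n_damaging`, sorted by decreasing count.
#' @export
recurrence_screen <- function(dnms, min_count = 2) {
  if (min_count < 1) stop("`min_count` must be >= 1", call. = FALSE)
  dmg <- dnms[dnms$damaging, , drop = FALSE]
  tal <- table(dmg$gene)
  tal <- tal[tal >= min_count]
  out <- data.frame(gene = as.character(names(tal)),
                    n_damaging = as.integer(tal),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) return(out)
  out <- out[order(-out$n_damaging, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
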