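#' Derive de novo-only TADA hyperparameters from cohort counts
#'
#' The prior fraction of risk genes is `pi = mle_G / total_genes`. The fold
#' enrichment for a damaging class is the case count divided by the sibling
#' count scaled by the cohorts' synonymous ratio,
#' `lambda = caseX / (sibX * caseSyn / sibSyn)` (synonymous mutations act
#' as the neutral yardstick for cohort size and detection sensitivity), and
#' the prior mean relative risk is `gamma = 1 + (lambda - 1) / pi`.
#'
#' @param case_counts,sib_counts Named lists/vectors with elements `mis`,
#'   `lof`, `syn`: DNM counts per class in cases and sibling controls.
#' @param mle_G Estimated number of risk genes (>= 1), e.g. from
#'   [mle_risk_genes()].
#' @param total_genes Size of the gene universe the estimate refers to.
#' @param beta Dispersion of the Gamma prior on the relative risk
#'   (shape = gamma * beta, rate = beta); larger beta concentrates the
#'   prior around its mean.
#' @param n_trios Number of case trios (used for the Poisson means).
#' @param n_null_samplings Random null data sets used for empirical
#'   p-values.
#' @return An object of class `tada_params`.
#' @export
derive_tada_params <- function(case_counts, sib_counts, mle_G, total_genes,
                               beta = 1, n_trios, n_null_samplings = 1000) {
  need <- c("mis", "lof", "syn")
  case_counts <- as.list(case_counts)[need]
  sib_counts <- as.list(sib_counts)[need]
  if (any(vapply(c(case_counts, sib_counts), is.null, logical(1)))) {
    stop("counts need elements mis, lof, syn", call. = FALSE)
  }
  if (any(unlist(sib_counts) <= 0)) {
    stop("sibling class counts must all be > 0 to anchor the enrichment ",
         "ratios", call. = FALSE)
  }
  if (mle_G < 1 || total_genes < mle_G) {
    stop("need 1 <= mle_G <= total_genes", call. = FALSE)
  }
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  pi <- mle_G / total_genes
  syn_ratio <- case_counts$syn / sib_counts$syn
  lambda_mis <- case_counts$mis / (sib_counts$mis * syn_ratio)
  lambda_lof <- case_counts$lof / (sib_counts$lof * syn_ratio)
  gamma_mis <- 1 + (lambda_mis - 1) / pi
  gamma_lof <- 1 + (lambda_lof - 1) / pi
  if (gamma_mis < 1 || gamma_lof < 1) {
    warning("fold enrichment below 1 gives a prior mean relative risk ",
            "below 1; the corresponding class carries no signal")
  }
  structure(
    list(pi = pi, lambda_mis = lambda_mis, lambda_lof = lambda_lof,
         gamma_mis = gamma_mis, gamma_lof = gamma_lof, beta = beta,
         n_trios = as.integer(n_trios),
         n_null_samplings = as.integer(n_null_samplings)),
    class = "tada_params"
  )
}

#' @export
#' @method print tada_params
print.tada_params <- function(x, ...) {
  cat(sprintf(
    "TADA parameters: pi = %.5f\n  mis: lambda = %.3f, gamma = %.2f\n  lof: lambda = %.3f, gamma = %.2f\n  beta = %g, %d trios, %d null samplings\n",
    x$pi, x$lambda_mis, x$gamma_mis, x$lambda_lof, x$gamma_lof, x$beta,
    x$n_trios, x$n_null_samplings))
  invisible(x)
}

# log Bayes factor of the de novo count model for one class.
# Null: x ~ Poisson(nu), nu = 2 * n_trios * mu.
# Alternative: x ~ Poisson(nu * g) marginalised over g ~ Gamma(gamma_bar *
# beta, beta), i.e. a negative binomial. All arithmetic in log space.
log_bf_class <- function(x, mu, n_trios, gamma_bar, beta) {
  nu <- 2 * n_trios * mu
  gb <- gamma_bar * beta
  marg <- lgamma(x + gb) - lgamma(gb) - lfactorial(x) +
    gb * (log(beta) - log(beta + nu)) + x * (log(nu) - log(beta + nu))
  null <- stats::dpois(x, nu, log = TRUE)
  marg - null
}

#' De novo TADA Bayes factor for one mutation class
#'
#' Marginal likelihood ratio of the risk model (Poisson rate inflated by a
#' Gamma-distributed relative risk with mean `gamma_bar` and dispersion
#' `beta`) to the null Poisson model, for an observed count `x` at per-gene
#' rate `mu` over `n_trios` trios. Vectorised over `x` and `mu`; evaluated
#' in log space via log-gamma so large `gamma_bar * beta` cannot overflow.
#'
#' @param x Observed DNM count(s) (>= 0).
#' @param mu Per-gene class mutation rate(s) (> 0).
#' @param n_trios Number of trios.
#' @param gamma_bar Prior mean relative risk.
#' @param beta Gamma-prior dispersion (> 0).
#' @return Bayes factor(s), same length as `x`.
#' @export
#' @examples
#' bf_class(x = 2, mu = 1e-5, n_trios = 473, gamma_bar = 20, beta = 1)
bf_class <- function(x, mu, n_trios, gamma_bar, beta) {
  if (any(mu <= 0)) stop("`mu` must be > 0", call. = FALSE)
  if (any(x < 0)) stop("`x` must be >= 0", call. = FALSE)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  exp(log_bf_class(x, mu, n_trios, gamma_bar, beta))
}

#' Per-gene TADA Bayes factors for a DNM cohort
#'
#' Tallies de novo missense and LOF counts per gene over the whole rate
#' table (genes without DNMs enter with zero counts), computes class Bayes
#' factors under the hyperparameters, and multiplies them into `bf_total`.
#' By default all missense DNMs count towards `x_mis` (the usual TADA
#' input); set `missense = "damaging"` to restrict to probably-damaging
#' missense.
#'
#' @param dnms Case DNM record data frame (`gene`, `class`,
#'   `damaging_pred`).
#' @param rates Per-gene mutation-rate table (defines the gene universe).
#' @param params A `tada_params` object.
#' @param missense Which missense DNMs to count: `"all"` or `"damaging"`.
#' @return Data frame with one row per gene: `gene`, `x_mis`, `x_lof`,
#'   `mu_mis`, `mu_lof`, `bf_mis`, `bf_lof`, `bf_total`.
#' @export
tada_gene_table <- function(dnms, rates, params,
                            missense = c("all", "damaging")) {
  missense <- match.arg(missense)
  validate_rates(rates)
  stopifnot(inherits(params, "tada_params"))
  mis <- dnms[dnms$class == "missense", , drop = FALSE]
  if (missense == "damaging") {
    mis <- mis[!is.na(mis$damaging_pred) & mis$damaging_pred == "probably", ,
               drop = FALSE]
  }
  lof <- dnms[dnms$class == "lof", , drop = FALSE]
  x_mis <- as.integer(table(factor(mis$gene, levels = rates$gene)))
  x_lof <- as.integer(table(factor(lof$gene, levels = rates$gene)))
  lb_mis <- log_bf_class(x_mis, rates$mu_mis, params$n_trios,
                         params$gamma_mis, params$beta)
  lb_lof <- log_bf_class(x_lof, rates$mu_lof, params$n_trios,
                         params$gamma_lof, params$beta)
  data.frame(
    gene = rates$gene, x_mis = x_mis, x_lof = x_lof,
    mu_mis = rates$mu_mis, mu_lof = rates$mu_lof,
    bf_mis = exp(lb_mis), bf_lof = exp(lb_lof),
    bf_total = exp(lb_mis + lb_lof),
    stringsAsFactors = FALSE
  )
}

#' Sampling-based null p-values for TADA Bayes factors
#'
#' For each of `params$n_null_samplings` replicates, per-gene null counts
#' are drawn from each gene's own Poisson null (`2 * n_trios * mu` per
#' class) and the total Bayes factor recomputed; the empirical p-value is
#' `(1 + #{null BF >= observed BF}) / (1 + samplings)` (add-one so p is
#' never zero).
#'
#' @param results Gene table from [tada_gene_table()].
#' @param rates Per-gene mutation-rate table (same gene order/universe).
#' @param params A `tada_params` object.
#' @param seed Integer seed for the null samplings.
#' @return `results` with a `p_value` column appended.
#' @export
tada_null_pvalues <- function(results, rates, params, seed = 1L) {
  stopifnot(inherits(params, "tada_params"))
  B <- params$n_null_samplings
  if (B < 1) stop("need at least one null sampling", call. = FALSE)
  rates <- rates[match(results$gene, rates$gene), , drop = FALSE]
  n <- nrow(results)
  nu_mis <- 2 * params$n_trios * rates$mu_mis
  nu_lof <- 2 * params$n_trios * rates$mu_lof
  # recompute the observed log BF from the counts so the comparison with
  # null draws is exact (log(exp(.)) would lose ties at identical counts)
  obs_lb <- log_bf_class(results$x_mis, rates$mu_mis, params$n_trios,
                         params$gamma_mis, params$beta) +
    log_bf_class(results$x_lof, rates$mu_lof, params$n_trios,
                 params$gamma_lof, params$beta)
  exceed <- withr::with_seed(seed, {
    cnt <- integer(n)
    for (b in seq_len(B)) {
      xm <- stats::rpois(n, nu_mis)
      xl <- stats::rpois(n, nu_lof)
      lb <- log_bf_class(xm, rates$mu_mis, params$n_trios,
                         params$gamma_mis, params$beta) +
        log_bf_class(xl, rates$mu_lof, params$n_trios,
                     params$gamma_lof, params$beta)
      cnt <- cnt + (lb >= obs_lb)
    }
    cnt
  })
  results$p_value <- (1 + exceed) / (1 + B)
  results
}

#' Bayesian FDR q-values from TADA Bayes factors
#'
#' The per-gene posterior probability of the null is
#' `P(H0 | x) = (1 - pi) / ((1 - pi) + pi * BF)`. Genes are ranked by
#' decreasing `bf_total` and the q-value of the i-th gene is the running
#' mean of the posterior null probability over the top i genes — the
#' estimated FDR of calling everything down to that gene. A
#' Benjamini-Hochberg adjustment of the sampling p-values is appended as
#' `q_bh` when p-values are present.
#'
#' @param results Gene table (with `bf_total`; optionally `p_value`).
#' @param pi Prior fraction of risk genes.
#' @return `results` with `q_value` (and possibly `q_bh`) appended.
#' @export
tada_qvalues <- function(results, pi) {
  if (pi <= 0 || pi >= 1) stop("`pi` must be in (0, 1)", call. = FALSE)
  post0 <- (1 - pi) / ((1 - pi) + pi * results$bf_total)
  ord <- order(results$bf_total, decreasing = TRUE)
  q <- numeric(length(post0))
  q[ord] <- cumsum(post0[ord]) / seq_along(ord)
  results$q_value <- q
  if (!is.null(results$p_value)) {
    results$q_bh <- stats::p.adjust(results$p_value, method = "BH")
  }
  results
}

#' Run the full de novo TADA analysis
#'
#' Convenience wrapper: derives hyperparameters from the case and sibling
#' class counts, builds the per-gene Bayes-factor table, attaches
#' sampling-based p-values and Bayesian FDR q-values, and sorts by
#' decreasing `bf_total`.
#'
#' @param case_dnms,sib_dnms DNM record data frames.
#' @param rates Per-gene mutation-rate table.
#' @param n_trios Number of case trios.
#' @param mle_G Estimated number of risk genes.
#' @param total_genes Gene universe size for `pi` (defaults to the rate
#'   table size).
#' @param beta Gamma-prior dispersion.
#' @param n_null_samplings Null replicates for p-values.
#' @param seed Integer seed.
#' @param missense Which missense DNMs enter the per-gene counts
#'   (see [tada_gene_table()]).
#' @return List with `params` (`tada_params`) and `genes` (the result
#'   table, one row per gene).
#' @export
run_tada <- function(case_dnms, sib_dnms, rates, n_trios, mle_G,
                     total_genes = nrow(rates), beta = 1,
                     n_null_samplings = 1000, seed = 1L,
                     missense = "all") {
  class_counts <- function(d) {
    list(mis = sum(d$class == "missense"),
         lof = sum(d$class == "lof"),
         syn = sum(d$class == "synonymous"))
  }
  params <- derive_tada_params(class_counts(case_dnms),
                               class_counts(sib_dnms),
                               mle_G = mle_G, total_genes = total_genes,
                               beta = beta, n_trios = n_trios,
                               n_null_samplings = n_null_samplings)
  genes <- tada_gene_table(case_dnms, rates, params, missense = missense)
  genes <- tada_null_pvalues(genes, rates, params, seed = seed)
  genes <- tada_qvalues(genes, params$pi)
  genes <- genes[order(genes$bf_total, decreasing = TRUE), , drop = FALSE]
  rownames(genes) <- NULL
  list(params = params, genes = genes)
}
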