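#' Expected DNM count for a mutation class under the null model
#'
#' The null mutation model says the number of DNMs of class `c` in gene `g`
#' over `N` trios is Poisson with mean `2 * N * mu_gc`; the class-wise
#' expectation is the sum over genes. The protein-altering class (`prot`)
#' is missense + LOF by definition.
#'
#' @param rates Per-gene mutation-rate table.
#' @param mutation_class One of `"syn"`, `"mis"`, `"lof"`, `"prot"`.
#' @param n_trios Cohort size (>= 1).
#' @return Expected count (a single number).
#' @export
#' @examples
#' r <- simulate_rates(50, 1.02, seed = 1)
#' expected_count(r, "lof", n_trios = 473)
expected_count <- function(rates, mutation_class, n_trios) {
  validate_rates(rates)
  mutation_class <- match.arg(mutation_class, c("syn", "mis", "lof", "prot"))
  if (!is.numeric(n_trios) || length(n_trios) != 1L || n_trios < 1) {
    stop("`n_trios` must be a single count >= 1", call. = FALSE)
  }
  mu <- switch(mutation_class,
               syn = rates$mu_syn,
               mis = rates$mu_mis,
               lof = rates$mu_lof,
               prot = rates$mu_mis + rates$mu_lof)
  2 * n_trios * sum(mu)
}

#' Exact Poisson burden test for one mutation class
#'
#' Enrichment is observed/expected. The p-value is the one-sided upper tail
#' `P(X >= observed | X ~ Poisson(expected))` (the enrichment direction; set
#' `alternative = "less"` for depletion). The 95% confidence interval is the
#' exact (Garwood) Poisson interval on the observed count divided by the
#' expectation.
#'
#' @param observed Observed count (>= 0).
#' @param expected Expected count under the null (> 0).
#' @param conf_level Confidence level for the enrichment interval.
#' @param alternative `"greater"` (default, upper tail) or `"less"`.
#' @return One-row data frame with `observed`, `expected`, `enrichment`,
#'   `p_value`, `ci_low`, `ci_high`.
#' @export
burden_test <- function(observed, expected, conf_level = 0.95,
                        alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.numeric(expected) || length(expected) != 1L || expected <= 0) {
    stop("`expected` must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(observed) || length(observed) != 1L || observed < 0) {
    stop("`observed` must be a single count >= 0", call. = FALSE)
  }
  p <- if (alternative == "greater") {
    stats::ppois(observed - 1, expected, lower.tail = FALSE)
  } else {
    stats::ppois(observed, expected)
  }
  alpha <- (1 - conf_level) / 2
  lo <- if (observed == 0) 0 else stats::qgamma(alpha, observed)
  hi <- stats::qgamma(1 - alpha, observed + 1)
  data.frame(observed = observed, expected = expected,
             enrichment = observed / expected, p_value = p,
             ci_low = lo / expected, ci_high = hi / expected)
}

#' Class-wise DNM burden for a cohort
#'
#' Tallies observed DNMs per functional class (`syn`, `mis`, `lof`, and
#' `prot` = mis + LOF), computes the matching null expectations from the
#' rate table and runs the exact Poisson burden test for each class. DNMs
#' in genes absent from the rate table are excluded from the tally with a
#' warning (the null model carries no expectation for them).
#'
#' @param dnms DNM record data frame with `gene` and `class` columns
#'   (classes `synonymous`, `missense`, `lof`; other classes are ignored
#'   for the tally).
#' @param rates Per-gene mutation-rate table.
#' @param n_trios Cohort size.
#' @inheritParams burden_test
#' @return Data frame with one row per class: `mutation_class`, `n_trios`,
#'   `observed`, `expected`, `enrichment`, `p_value`, `ci_low`, `ci_high`.
#' @export
cohort_burden <- function(dnms, rates, n_trios, conf_level = 0.95,
                          alternative = "greater") {
  validate_rates(rates)
  unknown <- setdiff(unique(dnms$gene), rates$gene)
  if (length(unknown)) {
    warning("dropping ", sum(dnms$gene %in% unknown),
            " DNM(s) in gene(s) absent from the rate table: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    dnms <- dnms[!dnms$gene %in% unknown, , drop = FALSE]
  }
  obs <- c(
    syn = sum(dnms$class == "synonymous"),
    mis = sum(dnms$class == "missense"),
    lof = sum(dnms$class == "lof")
  )
  obs["prot"] <- obs[["mis"]] + obs[["lof"]]
  out <- do.call(rbind, lapply(names(obs), function(cl) {
    res <- burden_test(obs[[cl]], expected_count(rates, cl, n_trios),
                       conf_level = conf_level, alternative = alternative)
    cbind(data.frame(mutation_class = cl, n_trios = n_trios), res)
  }))
  rownames(out) <- NULL
  out
}
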