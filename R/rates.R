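#' Simulate a per-gene de novo mutation-rate table
#'
#' Draws per-gene coding mutation rates from a heavy-tailed log-normal
#' distribution and rescales them so that the expected number of coding DNMs
#' per trio equals `total_coding_rate`. The expectation for a cohort of `N`
#' trios is `2 * N * mu` summed over genes and classes (the factor 2 counts
#' the two transmitted haploid genomes per child). Each gene's total rate is
#' split into synonymous, missense and loss-of-function components at fixed
#' proportions.
#'
#' @param n_genes Number of genes to simulate (>= 1).
#' @param total_coding_rate Expected number of coding DNMs per trio after
#'   rescaling, i.e. `sum(2 * (mu_syn + mu_mis + mu_lof))`.
#' @param seed Integer seed; the function never touches the caller's RNG
#'   stream.
#' @param class_props Named proportions for the `syn`, `mis` and `lof`
#'   components of each gene's rate. Normalised to sum to 1.
#' @param sdlog Standard deviation of the log-normal on the log scale;
#'   controls gene-to-gene rate heterogeneity.
#'
#' @return A data frame with columns `gene`, `mu_syn`, `mu_mis`, `mu_lof`.
#'   Rates are per gene, per chromosome, per generation.
#' @export
#' @examples
#' r <- simulate_rates(100, total_coding_rate = 1.02, seed = 1)
#' sum(2 * (r$mu_syn + r$mu_mis + r$mu_lof))  # 1.02
simulate_rates <- function(n_genes, total_coding_rate, seed,
                           class_props = c(syn = 0.25, mis = 0.62, lof = 0.13),
                           sdlog = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || is.na(n_genes) ||
      n_genes < 1) {
    stop("`n_genes` must be a single count >= 1", call. = FALSE)
  }
  if (!is.numeric(total_coding_rate) || length(total_coding_rate) != 1L ||
      is.na(total_coding_rate) || total_coding_rate <= 0) {
    stop("`total_coding_rate` must be a single value > 0", call. = FALSE)
  }
  if (!all(c("syn", "mis", "lof") %in% names(class_props)) ||
      any(class_props < 0) || sum(class_props) <= 0) {
    stop("`class_props` must be non-negative with names syn, mis, lof",
         call. = FALSE)
  }
  n_genes <- as.integer(n_genes)
  props <- class_props[c("syn", "mis", "lof")] / sum(class_props)
  mu <- withr::with_seed(seed, stats::rlnorm(n_genes, meanlog = 0, sdlog = sdlog))
  mu <- mu * total_coding_rate / (2 * sum(mu))
  data.frame(
    gene = sprintf("G%05d", seq_len(n_genes)),
    mu_syn = mu * props[["syn"]],
    mu_mis = mu * props[["mis"]],
    mu_lof = mu * props[["lof"]],
    stringsAsFactors = FALSE
  )
}

# minimal structural check shared by every consumer of a rate table
validate_rates <- function(rates) {
  need <- c("gene", "mu_syn", "mu_mis", "mu_lof")
  if (!is.data.frame(rates) || !all(need %in% names(rates))) {
    stop("rate table must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(rates) == 0L) stop("rate table is empty", call. = FALSE)
  if (anyDuplicated(rates$gene)) {
    stop("rate table gene symbols must be unique", call. = FALSE)
  }
  mu <- as.matrix(rates[, c("mu_syn", "mu_mis", "mu_lof")])
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("mutation rates must be finite and >= 0", call. = FALSE)
  }
  invisible(rates)
}

#' Read or write a per-gene mutation-rate table as TSV
#'
#' Columns: `gene`, `mu_syn`, `mu_mis`, `mu_lof`.
#'
#' @param rates Rate table data frame.
#' @param path File path.
#' @return `read_rates_tsv` returns the rate table; `write_rates_tsv`
#'   returns `path` invisibly.
#' @export
write_rates_tsv <- function(rates, path) {
  validate_rates(rates)
  utils::write.table(rates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates_tsv
#' @export
read_rates_tsv <- function(path) {
  rates <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_rates(rates)
  rates
}
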