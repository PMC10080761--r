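#' Construct the ground truth for a spiked synthetic cohort
#'
#' Bundles the risk-gene set, the relative risk applied to their damaging
#' mutation rates, and the RNG seed that drives cohort generation. Used both
#' to generate cohorts and, afterwards, to score parameter recovery.
#'
#' @param risk_genes Character vector of risk-gene symbols (may be empty for
#'   a null cohort).
#' @param gamma_true Relative risk multiplier (>= 1) applied to the damaging
#'   classes (LOF and probably-damaging missense) of risk genes.
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_truth`.
#' @export
risk_truth <- function(risk_genes = character(), gamma_true = 1, seed = 1L) {
  if (!is.numeric(gamma_true) || length(gamma_true) != 1L || gamma_true < 1) {
    stop("`gamma_true` must be a single value >= 1", call. = FALSE)
  }
  structure(
    list(risk_genes = as.character(risk_genes),
         gamma_true = as.numeric(gamma_true),
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Simulate de novo mutations for a trio cohort
#'
#' Per-gene, per-class DNM counts are Poisson with mean
#' `2 * n_trios * mu * m`, where `m = gamma_true` for the damaging classes
#' (LOF, and the damaging fraction of missense) of risk genes and 1
#' otherwise. Counts are expanded into individual DNM records assigned to
#' uniformly random trios. A fixed fraction of missense mutations is flagged
#' "probably damaging" at generation time; the pipeline downstream only ever
#' consumes that binary flag.
#'
#' @param rates Per-gene mutation-rate table (see [simulate_rates()]).
#' @param n_trios Number of trios (>= 1).
#' @param truth A [risk_truth()] object; its seed drives all randomness here.
#' @param damaging_frac Fraction of missense DNMs flagged probably damaging.
#' @return An object of class `synthetic_cohort`: a list with `n_trios`,
#'   `dnms` (data frame: `trio_id`, `gene`, `class`, `damaging`,
#'   `damaging_pred`, `chrom`, `pos`, `ref`, `alt`) and `truth`.
#' @export
simulate_dnm_cohort <- function(rates, n_trios, truth = risk_truth(),
                                damaging_frac = 0.30) {
  validate_rates(rates)
  if (!is.numeric(n_trios) || length(n_trios) != 1L || n_trios < 1) {
    stop("`n_trios` must be a single count >= 1", call. = FALSE)
  }
  if (!inherits(truth, "synthetic_truth")) {
    stop("`truth` must be built with risk_truth()", call. = FALSE)
  }
  unknown <- setdiff(truth$risk_genes, rates$gene)
  if (length(unknown)) {
    stop("risk genes absent from the rate table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (damaging_frac < 0 || damaging_frac > 1) {
    stop("`damaging_frac` must be in [0, 1]", call. = FALSE)
  }
  n_trios <- as.integer(n_trios)
  m <- ifelse(rates$gene %in% truth$risk_genes, truth$gamma_true, 1)

  # expected counts per gene for the four generative categories
  lam <- cbind(
    syn          = 2 * n_trios * rates$mu_syn,
    mis_benign   = 2 * n_trios * rates$mu_mis * (1 - damaging_frac),
    mis_damaging = 2 * n_trios * rates$mu_mis * damaging_frac * m,
    lof          = 2 * n_trios * rates$mu_lof * m
  )

  dnms <- withr::with_seed(truth$seed, {
    counts <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam),
                     dimnames = list(NULL, colnames(lam)))
    cat_of <- rep(colnames(counts), each = nrow(counts))
    gene_of <- rep(rates$gene, times = ncol(counts))
    n_rep <- as.vector(counts)
    gene <- rep(gene_of, n_rep)
    category <- rep(cat_of, n_rep)
    n <- length(gene)
    cls <- c(syn = "synonymous", mis_benign = "missense",
             mis_damaging = "missense", lof = "lof")[category]
    pred <- c(syn = NA_character_, mis_benign = "benign",
              mis_damaging = "probably", lof = NA_character_)[category]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    data.frame(
      trio_id = sprintf("T%04d", sample.int(n_trios, n, replace = TRUE)),
      gene = gene,
      class = unname(cls),
      damaging = unname(category %in% c("mis_damaging", "lof")),
      damaging_pred = unname(pred),
      chrom = sprintf("chr%d", sample.int(22L, n, replace = TRUE)),
      pos = sample.int(100000000L, n, replace = TRUE),
      ref = ref,
      alt = unname(alt),
      stringsAsFactors = FALSE
    )
  })
  rownames(dnms) <- NULL
  structure(
    list(n_trios = n_trios, dnms = dnms, truth = truth, raw_calls = NULL),
    class = "synthetic_cohort"
  )
}

#' @export
#' @method print synthetic_cohort
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic DNM cohort:", x$n_trios, "trios,", nrow(x$dnms), "DNMs",
      sprintf("(%d risk genes, gamma = %g)\n",
              length(x$truth$risk_genes), x$truth$gamma_true))
  invisible(x)
}

# Filter-rule names understood by simulate_raw_calls(); each maps to a record
# constructed to fail that rule and (where arithmetic allows) no other.
qc_fail_rules <- function() {
  c("vqsr", "gq", "fs", "dp", "parent_gt", "depth_ratio", "alt_depth",
    "noncoding", "allele_balance")
}

#' Generate raw trio call records with controlled QC failures
#'
#' Emits one fully passing candidate call per true DNM in the cohort, plus
#' exactly `n_fail_per_rule[r]` records constructed to fail rule `r` of the
#' variant-QC / DNM-candidate cascade while satisfying every other rule.
#' (Exception: a child-depth failure forces an alternate-depth failure too,
#' since alt reads cannot exceed total reads; the audit attributes it to the
#' first failing stage, `dp`.) Used as the fixture generator for round-trip
#' filtering tests: filtering the output at default thresholds recovers the
#' cohort's true DNM set exactly.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_fail_per_rule Named integer vector; names must be among
#'   `r toString(qc_fail_rules())`.
#' @param seed Integer seed for the failure records' placement.
#' @return A data frame of trio call records (one row per candidate call)
#'   with the genotype, depth, quality and annotation fields consumed by
#'   [filter_cohort()].
#' @export
simulate_raw_calls <- function(cohort, n_fail_per_rule = integer(), seed = 1L) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must be a synthetic_cohort", call. = FALSE)
  }
  rules <- qc_fail_rules()
  if (length(n_fail_per_rule)) {
    bad <- setdiff(names(n_fail_per_rule), rules)
    if (length(bad) || is.null(names(n_fail_per_rule))) {
      stop("unknown filter rule(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           "; known rules: ", paste(rules, collapse = ", "), call. = FALSE)
    }
  }

  passing_call <- function(d) {
    data.frame(
      trio_id = d$trio_id, chrom = d$chrom, pos = d$pos,
      ref = d$ref, alt = d$alt, gene = d$gene,
      class = d$class, damaging_pred = d$damaging_pred, coding = TRUE,
      child_gt = "0/1", father_gt = "0/0", mother_gt = "0/0",
      child_dp = 40L, father_dp = 40L, mother_dp = 40L,
      child_alt_depth = 16L, father_alt_depth = 0L, mother_alt_depth = 0L,
      gq = 99, fs = 1, vqsr_pass = TRUE,
      stringsAsFactors = FALSE
    )
  }
  calls <- passing_call(cohort$dnms)

  n_fail_per_rule <- n_fail_per_rule[n_fail_per_rule > 0]
  if (length(n_fail_per_rule)) {
    total <- sum(n_fail_per_rule)
    fails <- withr::with_seed(seed, {
      n <- as.integer(total)
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, n, replace = TRUE)
      d <- data.frame(
        trio_id = sprintf("T%04d", sample.int(cohort$n_trios, n, replace = TRUE)),
        chrom = sprintf("chr%d", sample.int(22L, n, replace = TRUE)),
        pos = 100000000L + sample.int(100000000L, n, replace = TRUE),
        ref = ref,
        alt = vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1)),
        gene = sample(c(cohort$dnms$gene, "GFILL"), n, replace = TRUE),
        class = "missense", damaging_pred = "benign",
        stringsAsFactors = FALSE
      )
      d
    })
    fails <- passing_call(fails)
    rule <- rep(names(n_fail_per_rule), times = n_fail_per_rule)
    # each block breaks exactly one rule relative to the passing template
    fails$vqsr_pass[rule == "vqsr"] <- FALSE
    fails$gq[rule == "gq"] <- 30
    fails$fs[rule == "fs"] <- 45
    fails$child_dp[rule == "dp"] <- 8L
    fails$child_alt_depth[rule == "dp"] <- 4L      # AB 0.5; see note above
    fails$father_gt[rule == "parent_gt"] <- "0/1"
    fails$father_alt_depth[rule == "parent_gt"] <- 15L
    fails$father_dp[rule == "depth_ratio"] <- 150L # 40/150 < 0.3
    fails$child_dp[rule == "alt_depth"] <- 30L
    fails$child_alt_depth[rule == "alt_depth"] <- 9L   # AB 0.3 still passes
    fails$coding[rule == "noncoding"] <- FALSE
    fails$child_dp[rule == "allele_balance"] <- 60L
    fails$child_alt_depth[rule == "allele_balance"] <- 12L  # AB exactly 0.2
    calls <- rbind(calls, fails)
  }
  rownames(calls) <- NULL
  calls
}

#' Write / read cohort DNMs as TSV
#'
#' Columns: `trio_id`, `gene`, `class`, `damaging`, `damaging_pred`,
#' `chrom`, `pos`, `ref`, `alt`.
#' @param dnms DNM record data frame.
#' @param path File path.
#' @export
write_dnms_tsv <- function(dnms, path) {
  utils::write.table(dnms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dnms_tsv
#' @export
read_dnms_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trio_id", "gene", "class", "damaging")
  if (!all(need %in% names(d))) {
    stop("DNM table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d$damaging <- as.logical(d$damaging)
  d
}

#' Write / read raw trio calls in the flat TSV dialect
#' @param calls Trio call record data frame.
#' @param path File path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  d$vqsr_pass <- as.logical(d$vqsr_pass)
  d$coding <- as.logical(d$coding)
  d
}

#' Write ground truth as JSON / read it back
#' @param truth A `synthetic_truth` object.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_truth(x$risk_genes %||% character(), x$gamma_true, x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
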