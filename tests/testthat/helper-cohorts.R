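# Shared fixture builders: everything is generated in code at test time.

make_rates <- function(n_genes = 50, seed = 1, rate = 1.02) {
  simulate_rates(n_genes, total_coding_rate = rate, seed = seed)
}

# a rate table with hand-set class rates for closed-form checks
manual_rates <- function(gene, mu_syn = 0, mu_mis = 0, mu_lof = 0) {
  data.frame(gene = gene, mu_syn = mu_syn, mu_mis = mu_mis, mu_lof = mu_lof,
             stringsAsFactors = FALSE)
}

null_cohort <- function(rates, n_trios, seed) {
  simulate_dnm_cohort(rates, n_trios, risk_truth(seed = seed))
}

# one fully passing trio call record, fields overridable
one_call <- function(...) {
  rec <- data.frame(
    trio_id = "T0001", chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
    gene = "G00001", class = "missense", damaging_pred = "probably",
    coding = TRUE, child_gt = "0/1", father_gt = "0/0", mother_gt = "0/0",
    child_dp = 30L, father_dp = 40L, mother_dp = 35L,
    child_alt_depth = 12L, father_alt_depth = 0L, mother_alt_depth = 0L,
    gq = 99, fs = 10, vqsr_pass = TRUE, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}
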