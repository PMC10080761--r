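# Independent oracles used by several test files. These deliberately avoid
# the package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive enumeration of the risk-gene placement model on a tiny
# universe: risk sets uniform over subsets of size G, C ~ Binomial(K, E),
# C placements over the risk set and K - C over all genes, each weighted by
# the damaging rate. Returns P(R1 = r1, R2 = r2) over all outcomes, named
# "r1 r2".
enumerate_recurrence <- function(rates, G, K, E) {
  n <- nrow(rates)
  w <- rates$mu_mis + rates$mu_lof
  sets <- utils::combn(n, G, simplify = FALSE)
  acc <- list()
  add <- function(counts, p) {
    key <- paste(sum(counts == 2L), sum(counts >= 3L))
    acc[[key]] <<- (acc[[key]] %||% 0) + p
  }
  place <- function(slots, weights, k) {
    if (k == 0) return(list(list(counts = integer(0), p = 1)))
    grids <- expand.grid(rep(list(seq_along(slots)), k))
    pr <- weights[slots] / sum(weights[slots])
    lapply(seq_len(nrow(grids)), function(i) {
      idx <- as.integer(grids[i, ])
      list(counts = slots[idx], p = prod(pr[idx]))
    })
  }
  for (S in sets) {
    pS <- 1 / length(sets)
    for (C in 0:K) {
      pC <- stats::dbinom(C, K, E)
      if (pC == 0) next
      risk_pl <- place(S, w, C)
      null_pl <- place(seq_len(n), w, K - C)
      for (a in risk_pl) for (b in null_pl) {
        tot <- tabulate(c(a$counts, b$counts), nbins = n)
        add(tot, pS * pC * a$p * b$p)
      }
    }
  }
  probs <- unlist(acc)
  probs / sum(probs)
}

# Exhaustive two-sided Fisher oracle: sum of hypergeometric tables whose
# point probability does not exceed the observed one (conventional
# 1 + 1e-7 relative tolerance for ties).
fisher_oracle <- function(a, case_n, c_, control_n) {
  m <- a + c_
  k_range <- max(0, m - control_n):min(m, case_n)
  probs <- stats::dhyper(k_range, case_n, control_n, m)
  obs <- stats::dhyper(a, case_n, control_n, m)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
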