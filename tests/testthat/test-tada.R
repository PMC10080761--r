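test_that("hyperparameter derivation follows the pi, lambda, gamma equations", {
  p <- derive_tada_params(
    case_counts = list(mis = 100, lof = 30, syn = 50),
    sib_counts = list(mis = 20, lof = 4, syn = 10),
    mle_G = 419, total_genes = 17726, beta = 1, n_trios = 473)
  expect_equal(p$pi, 419 / 17726, tolerance = 1e-12)
  expect_equal(p$pi, 0.02364, tolerance = 1e-3)
  # balanced rates: lambda = 100 / (20 * 5) = 1 -> gamma = 1
  expect_equal(p$lambda_mis, 1)
  expect_equal(p$gamma_mis, 1)
  # lof: lambda = 30 / (4 * 5) = 1.5
  expect_equal(p$lambda_lof, 1.5)
  expect_equal(p$gamma_lof, 1 + 0.5 / (419 / 17726))

  # lambda = 2 at pi = 0.025 gives gamma = 41
  p2 <- derive_tada_params(list(mis = 200, lof = 40, syn = 50),
                           list(mis = 20, lof = 4, syn = 10),
                           mle_G = 25, total_genes = 1000, n_trios = 100)
  expect_equal(p2$gamma_mis, 41)

  expect_error(
    derive_tada_params(list(mis = 1, lof = 1, syn = 1),
                       list(mis = 1, lof = 1, syn = 0), 10, 100,
                       n_trios = 10),
    "sibling")
})

test_that("class Bayes factors match the numerical-integration oracle", {
  # quadrature oracle: BF = E_g[ Poisson(x | nu g) / Poisson(x | nu) ]
  # with g ~ Gamma(gamma_bar * beta, beta); integrating the likelihood
  # ratio g^x exp(-nu (g - 1)) keeps the integrand on an O(1) scale
  bf_quad <- function(x, mu, n_trios, gamma_bar, beta) {
    nu <- 2 * n_trios * mu
    shape <- gamma_bar * beta
    # bracket the prior's mass so narrow peaks are not missed
    lo <- stats::qgamma(1e-14, shape, rate = beta)
    hi <- stats::qgamma(1 - 1e-14, shape, rate = beta)
    stats::integrate(function(g) {
      g^x * exp(-nu * (g - 1)) * stats::dgamma(g, shape, rate = beta)
    }, lo, hi, rel.tol = 1e-10)$value
  }

  # degenerate prior at relative risk 1: BF -> 1
  for (x in 0:4) {
    expect_equal(bf_class(x, 1e-5, 473, gamma_bar = 1, beta = 1e9), 1,
                 tolerance = 1e-4)
  }

  # x = 0 closed form: (beta / (beta + nu))^(gamma_bar * beta) * exp(nu)
  nu <- 2 * 473 * 2e-5
  expect_equal(bf_class(0, 2e-5, 473, 20, 1),
               (1 / (1 + nu))^20 * exp(nu), tolerance = 1e-12)

  # randomised grid against quadrature
  grid <- withr::with_seed(5, data.frame(
    x = sample(0:6, 30, replace = TRUE),
    mu = 10^stats::runif(30, -6, -4),
    gamma_bar = stats::runif(30, 1, 50),
    beta = sample(c(0.2, 1, 5), 30, replace = TRUE)))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ours <- bf_class(g$x, g$mu, 473, g$gamma_bar, g$beta)
    oracle <- bf_quad(g$x, g$mu, 473, g$gamma_bar, g$beta)
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
  expect_error(bf_class(1, 0, 100, 2, 1), "mu")
})

test_that("gene table tallies counts and multiplies class Bayes factors", {
  r <- make_rates(30, seed = 101)
  params <- derive_tada_params(list(mis = 60, lof = 20, syn = 25),
                               list(mis = 10, lof = 2, syn = 5),
                               mle_G = 5, total_genes = 30, n_trios = 200)
  co <- simulate_dnm_cohort(r, 200, risk_truth(r$gene[1:3], 10, seed = 102))
  tab <- tada_gene_table(co$dnms, r, params)
  expect_identical(nrow(tab), 30L)
  expect_identical(sum(tab$x_mis), sum(co$dnms$class == "missense"))
  expect_identical(sum(tab$x_lof), sum(co$dnms$class == "lof"))
  expect_equal(tab$bf_total, tab$bf_mis * tab$bf_lof, tolerance = 1e-12)

  # damaging-only missense counting is a subset
  tab_d <- tada_gene_table(co$dnms, r, params, missense = "damaging")
  expect_true(all(tab_d$x_mis <= tab$x_mis))

  # empty cohort: all counts zero; at small nu the zero-count BF sits
  # slightly below 1 and follows the x = 0 closed form
  tab0 <- tada_gene_table(co$dnms[0, ], r, params)
  expect_true(all(tab0$x_mis == 0 & tab0$x_lof == 0))
  closed0 <- function(nu, gb) (1 / (1 + nu))^gb * exp(nu)
  expect_equal(tab0$bf_mis,
               closed0(2 * 200 * r$mu_mis, params$gamma_mis),
               tolerance = 1e-10)

  # monotone in x_lof for fixed everything else
  bfs <- bf_class(0:5, 1e-5, 200, params$gamma_lof, params$beta)
  expect_true(all(diff(bfs) > 0))
})

test_that("sampling p-values are reproducible, add-one bounded, and 1 for empty genes", {
  r <- make_rates(40, seed = 111)
  params <- derive_tada_params(list(mis = 60, lof = 20, syn = 25),
                               list(mis = 10, lof = 2, syn = 5),
                               mle_G = 5, total_genes = 40, n_trios = 300,
                               n_null_samplings = 200)
  co <- simulate_dnm_cohort(r, 300, risk_truth(r$gene[1:2], 20, seed = 112))
  tab <- tada_gene_table(co$dnms, r, params)
  p1 <- tada_null_pvalues(tab, r, params, seed = 9)
  p2 <- tada_null_pvalues(tab, r, params, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
  expect_true(all(p1$p_value > 0 & p1$p_value <= 1))
  expect_true(all(p1$p_value >= 1 / (1 + params$n_null_samplings)))

  # at small nu the BF is strictly increasing in the count, so a
  # zero-count gene can never beat a null draw: its p-value is exactly 1
  tiny <- manual_rates(sprintf("M%d", 1:5), mu_syn = 1e-6,
                       mu_mis = 2e-5, mu_lof = 1e-5)
  params2 <- derive_tada_params(list(mis = 12, lof = 4, syn = 2),
                                list(mis = 3, lof = 1, syn = 1),
                                mle_G = 1, total_genes = 5, n_trios = 300,
                                n_null_samplings = 300)
  none <- data.frame(gene = character(), class = character(),
                     damaging_pred = character())
  tab2 <- tada_gene_table(none, tiny, params2)
  p3 <- tada_null_pvalues(tab2, tiny, params2, seed = 21)
  expect_true(all(p3$p_value == 1))
})

test_that("Bayesian FDR q-values are running means along the BF ranking", {
  toy <- data.frame(gene = c("a", "b", "c", "d"),
                    bf_total = c(100, 10, 1, 0.1))
  q <- tada_qvalues(toy, pi = 0.02)
  post0 <- 0.98 / (0.98 + 0.02 * toy$bf_total)
  expect_equal(q$q_value, cumsum(post0) / 1:4, tolerance = 1e-12)
  expect_true(all(diff(q$q_value) >= 0))

  # equal BFs share the common posterior null probability
  flat <- data.frame(gene = letters[1:3], bf_total = rep(2, 3))
  qf <- tada_qvalues(flat, pi = 0.1)
  expect_equal(qf$q_value, rep(0.9 / (0.9 + 0.1 * 2), 3))

  # pi -> 1 drives q -> 0
  q1 <- tada_qvalues(toy, pi = 1 - 1e-12)
  expect_true(all(q1$q_value < 1e-9))

  expect_error(tada_qvalues(toy, pi = 0), "pi")
})

test_that("the full TADA run separates spiked genes and thresholds at q <= 0.1", {
  r <- make_rates(120, seed = 121)
  risk <- r$gene[1:4]
  co <- simulate_dnm_cohort(r, 500, risk_truth(risk, 25, seed = 122))
  sib <- null_cohort(r, 250, seed = 123)
  res <- run_tada(co$dnms, sib$dnms, r, n_trios = 500, mle_G = 10,
                  n_null_samplings = 200, seed = 124)
  expect_identical(nrow(res$genes), 120L)
  expect_true(!is.unsorted(rev(res$genes$bf_total)))
  expect_true(!is.unsorted(res$genes$q_value))
  candidates <- res$genes$gene[res$genes$q_value <= 0.1]
  expect_gt(length(intersect(candidates, risk)), 0)
})
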