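test_that("trio IBD window is inclusive at both bounds", {
  expect_true(check_trio_ibd(list(ibd_child_father = 0.50,
                                  ibd_child_mother = 0.50))$pass)
  res <- check_trio_ibd(list(ibd_child_father = 0.44,
                             ibd_child_mother = 0.50))
  expect_false(res$pass)
  expect_identical(res$reasons, "ibd_child_father")
  expect_true(check_trio_ibd(list(ibd_child_father = 0.55,
                                  ibd_child_mother = 0.45))$pass)
  expect_error(check_trio_ibd(list(ibd_child_father = NA,
                                   ibd_child_mother = 0.5)), "missing IBD")
})

test_that("PCA outlier screen flags displaced samples and tolerates degeneracy", {
  m <- data.frame(trio_id = sprintf("T%02d", 1:10),
                  a = rep(1, 10), b = rep(2, 10))
  expect_length(flag_sample_outliers(m), 0)  # zero variance, no flags

  set.seed(42)
  m2 <- data.frame(trio_id = sprintf("T%02d", 1:20),
                   a = rnorm(20), b = rnorm(20))
  m2$a[7] <- m2$a[7] + 10 * stats::sd(m2$a)
  expect_identical(flag_sample_outliers(m2, k_sd = 4), "T07")
  expect_length(flag_sample_outliers(m2, k_sd = Inf), 0)

  expect_error(flag_sample_outliers(m2[1:2, ]), "at least 3")
})

test_that("region masks use BED half-open semantics on 1-based positions", {
  recs <- rbind(one_call(pos = 101L), one_call(pos = 102L))
  mask <- region_mask("lcr", "chr1", 100L, 101L)
  res <- apply_region_mask(recs, mask)
  expect_identical(res$retained$pos, 102L)
  expect_identical(unname(res$removed_counts["lcr"]), 1L)

  res0 <- apply_region_mask(recs, list())
  expect_identical(nrow(res0$retained), 2L)

  expect_error(region_mask("bad", "chr1", 10L, 10L), "start >= end")
})

test_that("variant QC applies the boundary semantics literally", {
  v <- apply_variant_qc(rbind(
    one_call(gq = 39, fs = 10, child_dp = 30L),   # GQ < 40 fails
    one_call(gq = 40, fs = 30, child_dp = 10L),   # all at boundary: pass
    one_call(gq = 99, fs = 31, child_dp = 30L),   # FS > 30 fails
    one_call(vqsr_pass = FALSE),
    one_call(gq = NA)
  ))
  expect_identical(v$pass, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(v$first_reason[1], "gq")
  expect_identical(v$first_reason[3], "fs")
  expect_identical(v$first_reason[4], "vqsr")
  expect_identical(v$first_reason[5], "missing_field")
})

test_that("DNM candidate rules: depth ratio, alt depth, coding, allele balance", {
  res <- call_dnm(one_call())  # dp 30, parents 40/35, alt 12 -> AB 0.4
  expect_identical(nrow(res$dnms), 1L)
  expect_true(res$dnms$damaging)
  expect_equal(res$dnms$allele_balance, 0.4)

  r2 <- call_dnm(one_call(child_alt_depth = 9L))
  expect_identical(nrow(r2$dnms), 0L)
  expect_identical(r2$verdicts$first_reason, "alt_depth")

  # AB exactly 0.2 fails the strict inequality
  r3 <- call_dnm(one_call(child_dp = 60L, child_alt_depth = 12L))
  expect_identical(r3$verdicts$first_reason, "allele_balance")

  r4 <- call_dnm(one_call(father_dp = 0L))
  expect_identical(r4$verdicts$first_reason, "parent_depth_zero")

  r5 <- call_dnm(one_call(coding = FALSE))
  expect_identical(r5$verdicts$first_reason, "noncoding")

  # Mendelian configuration: het child, hom-ref parents, few parent alt reads
  r6 <- call_dnm(one_call(father_gt = "0/1", father_alt_depth = 15L))
  expect_identical(r6$verdicts$first_reason, "parent_gt")
  r7 <- call_dnm(one_call(mother_alt_depth = 5L))  # 5/35 > 5% tolerance
  expect_identical(r7$verdicts$first_reason, "parent_gt")
})

test_that("record-level rules are order-independent pure predicates", {
  set.seed(1)
  recs <- do.call(rbind, lapply(1:40, function(i) {
    one_call(gq = sample(c(35, 45, 99), 1), fs = sample(c(5, 35), 1),
             child_dp = sample(c(8L, 12L, 40L), 1),
             child_alt_depth = sample(c(3L, 9L, 12L), 1))
  }))
  recs$child_alt_depth <- pmin(recs$child_alt_depth, recs$child_dp)
  shuffle <- sample(nrow(recs))
  v1 <- apply_variant_qc(recs)
  v2 <- apply_variant_qc(recs[shuffle, ])
  expect_identical(v1$pass[shuffle], v2$pass)
  expect_identical(v1$reasons[shuffle], v2$reasons)
})

test_that("cohort filtering audit conserves records and recovers the truth", {
  r <- make_rates(30, seed = 21)
  co <- null_cohort(r, 100, seed = 22)
  inject <- c(gq = 3L, fs = 2L, vqsr = 4L, alt_depth = 5L, noncoding = 2L,
              allele_balance = 3L, depth_ratio = 2L, dp = 1L, parent_gt = 2L)
  calls <- simulate_raw_calls(co, inject, seed = 23)

  f <- filter_cohort(calls)
  # audit: every injected failure attributed to its rule
  for (rule in names(inject)) {
    expect_identical(unname(f$audit$rejections[rule]), unname(inject[rule]),
                     label = paste("rule", rule))
  }
  # conservation: input = retained + sum of rejections
  expect_identical(f$audit$input_n,
                   f$audit$retained_n + sum(f$audit$rejections))
  # round trip: exactly the true DNM set comes back
  key <- function(d) sort(paste(d$trio_id, d$gene, d$chrom, d$pos))
  expect_identical(key(f$dnms), key(co$dnms))
  expect_equal(sort(unique(f$dnms$class)),
               sort(unique(co$dnms$class)))
})

test_that("trio-level screens remove whole trios before variant rules", {
  r <- make_rates(20, seed = 31)
  co <- null_cohort(r, 30, seed = 32)
  calls <- simulate_raw_calls(co)
  trios <- sprintf("T%04d", 1:30)
  profiles <- data.frame(trio_id = trios,
                         ibd_child_father = rep(0.5, 30),
                         ibd_child_mother = rep(0.5, 30))
  bad_trio <- co$dnms$trio_id[1]
  profiles$ibd_child_father[profiles$trio_id == bad_trio] <- 0.30

  set.seed(33)
  metrics <- data.frame(trio_id = trios, a = rnorm(30), b = rnorm(30))
  out_trio <- setdiff(unique(co$dnms$trio_id), bad_trio)[1]
  metrics$a[metrics$trio_id == out_trio] <- 50

  f <- filter_cohort(calls, profiles = profiles, metrics = metrics)
  expect_setequal(f$audit$excluded_trios, c(bad_trio, out_trio))
  expect_identical(unname(f$audit$rejections["ibd"]),
                   sum(co$dnms$trio_id == bad_trio))
  expect_false(any(f$dnms$trio_id %in% c(bad_trio, out_trio)))
  expect_identical(f$audit$input_n,
                   f$audit$retained_n + sum(f$audit$rejections))
})

test_that("trio VCFs round-trip through write and read", {
  r <- make_rates(15, seed = 41)
  co <- null_cohort(r, 10, seed = 42)
  calls <- simulate_raw_calls(co, c(gq = 2L, fs = 1L), seed = 43)
  dir <- withr::local_tempdir()
  write_trio_vcfs(calls, dir)
  back <- read_trio_vcf_dir(dir)
  expect_identical(nrow(back), nrow(calls))

  ord <- function(d) d[order(d$trio_id, d$chrom, d$pos), , drop = FALSE]
  a <- ord(calls); b <- ord(back)
  for (col in c("gene", "class", "child_gt", "father_gt", "mother_gt",
                "coding", "vqsr_pass")) {
    expect_equal(unname(b[[col]]), unname(a[[col]]), label = col)
  }
  expect_equal(b$child_dp, as.numeric(a$child_dp))
  expect_equal(b$child_alt_depth, as.numeric(a$child_alt_depth))
  expect_equal(b$fs, a$fs)

  f1 <- filter_cohort(back)
  f2 <- filter_cohort(calls)
  expect_identical(f1$audit$rejections[sort(names(f1$audit$rejections))],
                   f2$audit$rejections[sort(names(f2$audit$rejections))])
  expect_identical(f1$audit$retained_n, f2$audit$retained_n)
})

test_that("pedigree + IBD tables build per-trio profiles", {
  tmp <- withr::local_tempdir()
  ped_path <- file.path(tmp, "trios.ped")
  writeLines(c("F1 C1 P1 M1 2 2", "F1 P1 0 0 1 1", "F1 M1 0 0 2 1",
               "F2 C2 P2 M2 2 2", "F2 P2 0 0 1 1", "F2 M2 0 0 2 1"),
             ped_path)
  ibd_path <- file.path(tmp, "ibd.tsv")
  writeLines(c("sample1\tsample2\tpi_hat", "C1\tP1\t0.51", "M1\tC1\t0.49",
               "C2\tP2\t0.38", "C2\tM2\t0.52"), ibd_path)
  prof <- trio_ibd_profiles(read_ped(ped_path), read_ibd_table(ibd_path))
  expect_identical(prof$trio_id, c("F1", "F2"))
  expect_equal(prof$ibd_child_father, c(0.51, 0.38))
  expect_true(check_trio_ibd(prof[1, ])$pass)
  expect_false(check_trio_ibd(prof[2, ])$pass)
})

test_that("per-trio DNM counts on a null cohort are Poisson-distributed", {
  r <- make_rates(200, seed = 51)
  n_trios <- 2000
  co <- null_cohort(r, n_trios, seed = 52)
  counts <- table(factor(co$dnms$trio_id,
                         levels = sprintf("T%04d", seq_len(n_trios))))
  lambda <- mean(counts)
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  p_exp <- c(stats::dpois(0:2, lambda),
             stats::ppois(2, lambda, lower.tail = FALSE))
  chi2 <- sum((obs - n_trios * p_exp)^2 / (n_trios * p_exp))
  p_gof <- stats::pchisq(chi2, df = length(obs) - 2, lower.tail = FALSE)
  expect_gt(p_gof, 0.01)
})
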