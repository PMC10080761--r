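#' Default thresholds for the DNM filtering cascade
#'
#' All values follow the standard trio-QC conventions used throughout the
#' package: parent-child IBD sharing within \[0.45, 0.55\] (inclusive),
#' genotype quality >= 40, Fisher-strand score <= 30, child depth >= 10,
#' VQSR pass required; DNM candidates additionally need a child/parent depth
#' ratio >= 0.3 against each parent, alternate allele depth >= 10, a coding
#' consequence, and allele balance strictly > 0.2. Parental reads supporting
#' the alternate allele are tolerated up to 5% of the parent's depth.
#'
#' @return Named list of thresholds, suitable for editing and passing to
#'   [filter_cohort()].
#' @export
default_filter_config <- function() {
  list(
    ibd_min = 0.45, ibd_max = 0.55,
    k_sd = 4,
    gq_min = 40, fs_max = 30, dp_min = 10,
    depth_ratio_min = 0.3, alt_depth_min = 10, ab_min = 0.2,
    parent_alt_tol = 0.05
  )
}

#' Check parent-child IBD sharing for one trio
#'
#' A trio passes when both parent-child IBD proportions lie inside the
#' inclusive window `[ibd_min, ibd_max]`; values outside it indicate sample
#' swaps, contamination or misreported pedigrees.
#'
#' @param profile List or one-row data frame with `ibd_child_father` and
#'   `ibd_child_mother` in \[0, 1\].
#' @param ibd_min,ibd_max Window bounds (inclusive).
#' @return List with `pass` (logical) and `reasons` (character vector naming
#'   the offending pair(s), empty when passing).
#' @export
check_trio_ibd <- function(profile, ibd_min = 0.45, ibd_max = 0.55) {
  f <- profile$ibd_child_father
  m <- profile$ibd_child_mother
  if (is.null(f) || is.null(m) || is.na(f) || is.na(m)) {
    stop("missing IBD value for trio", call. = FALSE)
  }
  reasons <- character(0)
  if (f < ibd_min || f > ibd_max) reasons <- c(reasons, "ibd_child_father")
  if (m < ibd_min || m > ibd_max) reasons <- c(reasons, "ibd_child_mother")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Flag sample outliers from variant-calling QC metrics
#'
#' Projects the per-sample metric vectors onto their first two principal
#' components and flags samples whose robust z-score (median/MAD) on either
#' component exceeds `k_sd`. Metrics with zero variance are ignored; when
#' the MAD of a component degenerates to zero its standard deviation is used
#' instead, and a fully degenerate component flags nothing.
#'
#' @param metrics Data frame with an identifier column `trio_id` followed by
#'   numeric QC metric columns; at least 3 rows.
#' @param k_sd Robust z-score threshold (default 4).
#' @return Character vector of flagged `trio_id`s (possibly empty).
#' @export
flag_sample_outliers <- function(metrics, k_sd = 4) {
  if (!is.data.frame(metrics) || !"trio_id" %in% names(metrics)) {
    stop("`metrics` must be a data frame with a trio_id column", call. = FALSE)
  }
  if (nrow(metrics) < 3L) {
    stop("sample outlier screening needs at least 3 profiles", call. = FALSE)
  }
  x <- as.matrix(metrics[, setdiff(names(metrics), "trio_id"), drop = FALSE])
  storage.mode(x) <- "double"
  keep <- apply(x, 2, stats::sd) > 0
  if (!any(keep)) return(character(0))
  pc <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  robust_z <- apply(scores, 2, function(s) {
    centre <- stats::median(s)
    scale <- stats::mad(s)
    if (scale == 0) scale <- stats::sd(s)
    if (scale == 0) return(rep(0, length(s)))
    (s - centre) / scale
  })
  robust_z <- matrix(robust_z, nrow = nrow(scores))
  flagged <- apply(abs(robust_z) > k_sd, 1, any)
  metrics$trio_id[flagged]
}

#' Remove calls falling inside region masks
#'
#' Masks are BED-style 0-based half-open intervals; call positions are
#' 1-based, so a call at `pos` is removed when `pos - 1` lies in
#' `[start, end)` of any interval. Overlap testing goes through
#' GenomicRanges.
#'
#' @param records Trio call record data frame.
#' @param masks A single region-mask data frame ([region_mask()]) or a list
#'   of them.
#' @return List with `retained` (records outside every mask) and
#'   `removed_counts` (named per-mask removal counts; a record inside
#'   several masks counts towards the first).
#' @export
apply_region_mask <- function(records, masks) {
  if (is.data.frame(masks)) masks <- list(masks)
  if (!length(masks) || nrow(records) == 0L) {
    return(list(retained = records,
                removed_counts = stats::setNames(
                  integer(length(masks)),
                  vapply(masks, function(m) m$name[1], character(1)))))
  }
  pts <- GenomicRanges::GRanges(records$chrom,
                                IRanges::IRanges(records$pos, records$pos))
  hit_any <- rep(FALSE, nrow(records))
  removed_counts <- integer(0)
  for (m in masks) {
    if (any(m$start >= m$end)) {
      stop("malformed mask interval: start >= end", call. = FALSE)
    }
    gr <- GenomicRanges::GRanges(m$chrom,
                                 IRanges::IRanges(m$start + 1L, m$end))
    hit <- GenomicRanges::countOverlaps(pts, gr) > 0
    new_hit <- hit & !hit_any                    # first-mask attribution
    removed_counts[m$name[1]] <- sum(new_hit)
    hit_any <- hit_any | hit
  }
  list(retained = records[!hit_any, , drop = FALSE],
       removed_counts = removed_counts)
}

# Rule predicates return TRUE when the record FAILS the rule. NA fields fail
# closed and are attributed to missing_field.
variant_qc_matrix <- function(records, config) {
  cbind(
    vqsr = !records$vqsr_pass,
    gq = records$gq < config$gq_min,
    fs = records$fs > config$fs_max,
    dp = records$child_dp < config$dp_min
  )
}

#' Variant-level QC verdicts
#'
#' A record passes when it carries a VQSR pass flag, genotype quality of at
#' least `gq_min`, Fisher-strand score of at most `fs_max` and a child read
#' depth of at least `dp_min`. Every failed rule is listed; missing fields
#' fail closed with reason `missing_field`.
#'
#' @param records Trio call record data frame.
#' @param config Threshold list, see [default_filter_config()].
#' @return Data frame with logical `pass`, `first_reason` (NA when passing;
#'   first failing rule in the order vqsr, gq, fs, dp) and `reasons`
#'   (all failing rules, `;`-separated).
#' @export
apply_variant_qc <- function(records, config = default_filter_config()) {
  fails <- variant_qc_matrix(records, config)
  verdicts_from(fails)
}

verdicts_from <- function(fails) {
  missing <- apply(fails, 1, function(r) any(is.na(r)))
  fails[is.na(fails)] <- TRUE
  first <- apply(fails, 1, function(r) {
    if (!any(r)) NA_character_ else colnames(fails)[which(r)[1]]
  })
  first[missing] <- "missing_field"
  all_reasons <- apply(fails, 1, function(r) {
    paste(colnames(fails)[r], collapse = ";")
  })
  all_reasons[missing] <- paste0("missing_field(",
                                 sub(";.*", "", all_reasons[missing]), ")")
  data.frame(pass = !apply(fails, 1, any) & !missing,
             first_reason = first,
             reasons = ifelse(all_reasons == "", NA_character_, all_reasons),
             stringsAsFactors = FALSE)
}

normalize_gt <- function(gt) gsub("|", "/", gt, fixed = TRUE)

# Candidate-DNM rule matrix; TRUE = fails. Rules, in attribution order:
# parent_gt (Mendelian configuration), parent_depth_zero, depth_ratio,
# alt_depth, noncoding, allele_balance.
dnm_rule_matrix <- function(records, config) {
  child_het <- normalize_gt(records$child_gt) %in% c("0/1", "1/0")
  par_ref <- normalize_gt(records$father_gt) == "0/0" &
    normalize_gt(records$mother_gt) == "0/0"
  if (is.null(records$father_alt_depth) || is.null(records$mother_alt_depth)) {
    par_alt_ok <- rep(TRUE, nrow(records))
  } else {
    par_alt_ok <- records$father_alt_depth <= config$parent_alt_tol * records$father_dp &
      records$mother_alt_depth <= config$parent_alt_tol * records$mother_dp
  }
  parent_zero <- records$father_dp == 0 | records$mother_dp == 0
  ratio_ok <- !parent_zero &
    records$child_dp / records$father_dp >= config$depth_ratio_min &
    records$child_dp / records$mother_dp >= config$depth_ratio_min
  ab <- records$child_alt_depth / records$child_dp
  cbind(
    parent_gt = !(child_het & par_ref & par_alt_ok),
    parent_depth_zero = parent_zero,
    depth_ratio = !parent_zero & !ratio_ok,
    alt_depth = records$child_alt_depth < config$alt_depth_min,
    noncoding = !records$coding,
    allele_balance = !(ab > config$ab_min)
  )
}

#' Call de novo mutations from QC-passing trio records
#'
#' Accepts a record as a DNM when the child is heterozygous with both
#' parents homozygous reference (parental alternate reads tolerated up to
#' `parent_alt_tol` of the parent depth), the child/parent depth ratio is at
#' least `depth_ratio_min` against each parent, the alternate allele depth
#' is at least `alt_depth_min`, the variant is coding, and the child allele
#' balance exceeds `ab_min` strictly. A parent depth of zero leaves the
#' depth ratio undefined and fails closed (`parent_depth_zero`).
#'
#' @param records Trio call record data frame (should already have passed
#'   variant QC).
#' @param config Threshold list, see [default_filter_config()].
#' @return List with `dnms` (accepted DNM records: `trio_id`, `gene`,
#'   `chrom`, `pos`, `ref`, `alt`, `class`, `damaging`, `damaging_pred`,
#'   `allele_balance`) and `verdicts` (per-input pass/reasons as in
#'   [apply_variant_qc()]).
#' @export
call_dnm <- function(records, config = default_filter_config()) {
  if (nrow(records) == 0L) {
    return(list(dnms = empty_dnms(), verdicts = data.frame(
      pass = logical(), first_reason = character(), reasons = character())))
  }
  fails <- dnm_rule_matrix(records, config)
  verdicts <- verdicts_from(fails)
  acc <- records[verdicts$pass, , drop = FALSE]
  dnms <- data.frame(
    trio_id = acc$trio_id, gene = acc$gene, chrom = acc$chrom, pos = acc$pos,
    ref = acc$ref, alt = acc$alt, class = acc$class,
    damaging = acc$class == "lof" |
      (!is.na(acc$damaging_pred) & acc$damaging_pred == "probably"),
    damaging_pred = acc$damaging_pred,
    allele_balance = acc$child_alt_depth / acc$child_dp,
    stringsAsFactors = FALSE
  )
  rownames(dnms) <- NULL
  list(dnms = dnms, verdicts = verdicts)
}

empty_dnms <- function() {
  data.frame(trio_id = character(), gene = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             class = character(), damaging = logical(),
             damaging_pred = character(), allele_balance = numeric(),
             stringsAsFactors = FALSE)
}

#' Run the full DNM filtering cascade over a cohort
#'
#' Stages run in order: trio IBD check, PCA sample-outlier screen, region
#' masks, variant-level QC, DNM candidate criteria. The audit attributes
#' each removed record to the first failing stage/rule, so input count =
#' retained count + sum of per-rule rejections.
#'
#' @param calls Trio call record data frame (all trios combined).
#' @param profiles Optional per-trio IBD profile data frame (`trio_id`,
#'   `ibd_child_father`, `ibd_child_mother`).
#' @param metrics Optional per-trio QC metric data frame for the outlier
#'   screen (`trio_id` + numeric columns).
#' @param masks Optional region mask(s) ([region_mask()] or a list).
#' @param config Threshold list, see [default_filter_config()].
#' @return List of class `filter_result`: `dnms` (accepted DNM records),
#'   `audit` (list with `input_n`, `retained_n`, `rejections` named counts,
#'   `excluded_trios`, `per_trio_counts`).
#' @export
filter_cohort <- function(calls, profiles = NULL, metrics = NULL,
                          masks = NULL, config = default_filter_config()) {
  input_n <- nrow(calls)
  rejections <- integer(0)
  excluded <- character(0)

  if (!is.null(profiles)) {
    bad <- vapply(seq_len(nrow(profiles)), function(i) {
      !check_trio_ibd(profiles[i, , drop = FALSE],
                      config$ibd_min, config$ibd_max)$pass
    }, logical(1))
    bad_trios <- profiles$trio_id[bad]
    drop <- calls$trio_id %in% bad_trios
    rejections["ibd"] <- sum(drop)
    excluded <- union(excluded, bad_trios)
    calls <- calls[!drop, , drop = FALSE]
  }
  if (!is.null(metrics)) {
    flagged <- flag_sample_outliers(metrics, config$k_sd)
    drop <- calls$trio_id %in% flagged
    rejections["pca_outlier"] <- sum(drop)
    excluded <- union(excluded, flagged)
    calls <- calls[!drop, , drop = FALSE]
  }
  if (!is.null(masks)) {
    masked <- apply_region_mask(calls, masks)
    rejections <- c(rejections, masked$removed_counts)
    calls <- masked$retained
  }

  qc <- apply_variant_qc(calls, config)
  qc_counts <- table(qc$first_reason[!qc$pass])
  rejections <- c(rejections,
                  stats::setNames(as.integer(qc_counts), names(qc_counts)))
  calls <- calls[qc$pass, , drop = FALSE]

  dn <- call_dnm(calls, config)
  dn_counts <- table(dn$verdicts$first_reason[!dn$verdicts$pass])
  rejections <- c(rejections,
                  stats::setNames(as.integer(dn_counts), names(dn_counts)))

  per_trio <- table(dn$dnms$trio_id)
  audit <- list(
    input_n = input_n,
    retained_n = nrow(dn$dnms),
    rejections = rejections,
    excluded_trios = excluded,
    per_trio_counts = per_trio
  )
  structure(list(dnms = dn$dnms, audit = audit), class = "filter_result")
}

#' @export
#' @method print filter_result
print.filter_result <- function(x, ...) {
  cat("DNM filtering:", x$audit$input_n, "candidate calls ->",
      x$audit$retained_n, "DNMs\n")
  if (length(x$audit$rejections)) {
    cat("Rejections by rule:\n")
    print(x$audit$rejections)
  }
  invisible(x)
}

#' Write a filtering audit as JSON
#' @param result A `filter_result` from [filter_cohort()].
#' @param path Output path.
#' @export
write_audit_json <- function(result, path) {
  a <- result$audit
  jsonlite::write_json(
    list(input_n = a$input_n, retained_n = a$retained_n,
         rejections = as.list(a$rejections),
         excluded_trios = a$excluded_trios,
         per_trio_counts = as.list(stats::setNames(as.integer(a$per_trio_counts),
                                                   names(a$per_trio_counts)))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
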