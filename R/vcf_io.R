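#' Write trio call records as one VCF 4.2 file per trio
#'
#' Samples are ordered child, father, mother with FORMAT `GT:DP:AD:GQ`.
#' Annotation travels in INFO (`FS`, `GENE`, `CLASS`, `DMG`, `CODING`); a
#' VQSR failure is encoded in the FILTER column.
#'
#' @param calls Trio call record data frame (see [simulate_raw_calls()]).
#' @param dir Output directory; files are named `<trio_id>.vcf`.
#' @return Invisibly, the paths written (named by trio).
#' @export
write_trio_vcfs <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias phred score\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene symbol\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=DMG,Number=1,Type=String,Description=\"Damaging prediction\">",
    "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"1 if within coding regions\">",
    "##FILTER=<ID=VQSR_FAIL,Description=\"Failed variant quality score recalibration\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  fmt_sample <- function(gt, dp, ad_alt, gq) {
    sprintf("%s:%d:%d,%d:%d", gt, dp, dp - ad_alt, ad_alt, round(gq))
  }
  paths <- character(0)
  for (trio in unique(calls$trio_id)) {
    x <- calls[calls$trio_id == trio, , drop = FALSE]
    info <- sprintf("FS=%g;GENE=%s;CLASS=%s;DMG=%s;CODING=%d",
                    x$fs, x$gene, x$class,
                    ifelse(is.na(x$damaging_pred), ".", x$damaging_pred),
                    as.integer(x$coding))
    body <- paste(
      x$chrom, x$pos, ".", x$ref, x$alt, ".",
      ifelse(x$vqsr_pass, "PASS", "VQSR_FAIL"), info, "GT:DP:AD:GQ",
      fmt_sample(x$child_gt, x$child_dp, x$child_alt_depth, x$gq),
      fmt_sample(x$father_gt, x$father_dp, x$father_alt_depth, x$gq),
      fmt_sample(x$mother_gt, x$mother_dp, x$mother_alt_depth, x$gq),
      sep = "\t"
    )
    col_line <- paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0(trio, "_child"),
                      paste0(trio, "_father"), paste0(trio, "_mother"),
                      sep = "\t")
    path <- file.path(dir, paste0(trio, ".vcf"))
    writeLines(c(header, col_line, body), path)
    paths[trio] <- path
  }
  invisible(paths)
}

#' Read one trio's candidate calls from a VCF file
#'
#' Expects FORMAT `GT`, `DP`, `AD`, `GQ` for three samples in the order
#' child, father, mother; strand bias, gene symbol, consequence class,
#' damaging prediction and coding status are taken from configurable INFO
#' keys. Multi-allelic ALT entries are decomposed into bi-allelic records
#' (allele depths beyond the first alternate are collapsed onto it).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param trio_id Trio identifier to stamp on the records; defaults to the
#'   file name without extension.
#' @param info_keys Named list mapping the `fs`, `gene`, `class`, `damaging`
#'   and `coding` fields to INFO keys.
#' @return A trio call record data frame as produced by
#'   [simulate_raw_calls()].
#' @export
read_trio_vcf <- function(path, trio_id = NULL,
                          info_keys = list(fs = "FS", gene = "GENE",
                                           class = "CLASS", damaging = "DMG",
                                           coding = "CODING")) {
  if (is.null(trio_id)) {
    trio_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(empty_calls())
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (ncol(gt) < 3L) stop("trio VCF must carry three samples", call. = FALSE)
  alt_depth <- function(j) {
    parts <- strsplit(ad[, j], ",", fixed = TRUE)
    vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (length(p) < 2L || all(is.na(p[-1]))) return(NA_real_)
      sum(p[-1], na.rm = TRUE)  # collapse multi-allelic alt depths
    }, numeric(1))
  }
  info_num <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info_chr <- function(key) as.character(vcfR::extract.info(v, element = key))
  alt <- fix[, "ALT"]
  first_alt <- vapply(strsplit(alt, ",", fixed = TRUE), `[`, character(1), 1L)
  dmg <- info_chr(info_keys$damaging)
  dmg[dmg %in% c(".", "")] <- NA_character_
  out <- data.frame(
    trio_id = trio_id,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = first_alt,
    gene = info_chr(info_keys$gene),
    class = info_chr(info_keys$class),
    damaging_pred = dmg,
    coding = info_num(info_keys$coding) == 1,
    child_gt = unname(gt[, 1L]),
    father_gt = unname(gt[, 2L]),
    mother_gt = unname(gt[, 3L]),
    child_dp = unname(dp[, 1L]),
    father_dp = unname(dp[, 2L]),
    mother_dp = unname(dp[, 3L]),
    child_alt_depth = alt_depth(1L),
    father_alt_depth = alt_depth(2L),
    mother_alt_depth = alt_depth(3L),
    gq = unname(gq[, 1L]),
    fs = info_num(info_keys$fs),
    vqsr_pass = fix[, "FILTER"] %in% c("PASS", "."),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read every trio VCF in a directory
#' @param dir Directory containing `<trio_id>.vcf` files.
#' @inheritParams read_trio_vcf
#' @return A single combined trio call record data frame.
#' @export
read_trio_vcf_dir <- function(dir, info_keys = list(fs = "FS", gene = "GENE",
                                                    class = "CLASS",
                                                    damaging = "DMG",
                                                    coding = "CODING")) {
  files <- list.files(dir, pattern = "\\.vcf(\\.gz)?$", full.names = TRUE)
  if (!length(files)) stop("no VCF files found in ", dir, call. = FALSE)
  do.call(rbind, lapply(files, read_trio_vcf, info_keys = info_keys))
}

empty_calls <- function() {
  data.frame(trio_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             class = character(), damaging_pred = character(),
             coding = logical(), child_gt = character(),
             father_gt = character(), mother_gt = character(),
             child_dp = numeric(), father_dp = numeric(),
             mother_dp = numeric(), child_alt_depth = numeric(),
             father_alt_depth = numeric(), mother_alt_depth = numeric(),
             gq = numeric(), fs = numeric(), vqsr_pass = logical(),
             stringsAsFactors = FALSE)
}

#' Read a PED pedigree file
#'
#' Standard six-column PED (family, individual, father, mother, sex,
#' phenotype). Returns one row per child with both parents present.
#'
#' @param path PED file path.
#' @return Data frame with columns `family`, `child`, `father`, `mother`.
#' @export
read_ped <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(p) < 6L) stop("PED file needs 6 columns", call. = FALSE)
  names(p)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  kids <- p[p$father != "0" & p$mother != "0", , drop = FALSE]
  data.frame(family = kids$family, child = kids$id,
             father = kids$father, mother = kids$mother,
             stringsAsFactors = FALSE)
}

#' Read a pairwise IBD table (sample1, sample2, pi_hat)
#' @param path TSV path with a header row.
#' @return Data frame with columns `sample1`, `sample2`, `pi_hat`.
#' @export
read_ibd_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample1", "sample2", "pi_hat")
  if (!all(need %in% names(d))) {
    stop("IBD table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Build per-trio IBD profiles from a pedigree and a pairwise IBD table
#'
#' Looks up the child-father and child-mother IBD proportions for every trio
#' in the pedigree (pair order in the IBD table does not matter).
#'
#' @param ped Pedigree data frame from [read_ped()].
#' @param ibd Pairwise IBD data frame from [read_ibd_table()].
#' @return Data frame with columns `trio_id`, `ibd_child_father`,
#'   `ibd_child_mother`.
#' @export
trio_ibd_profiles <- function(ped, ibd) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lookup <- stats::setNames(ibd$pi_hat, key(ibd$sample1, ibd$sample2))
  data.frame(
    trio_id = ped$family,
    ibd_child_father = unname(lookup[key(ped$child, ped$father)]),
    ibd_child_mother = unname(lookup[key(ped$child, ped$mother)]),
    stringsAsFactors = FALSE
  )
}

#' Read a BED region mask (0-based, half-open)
#' @param path BED file path (first three columns chrom, start, end).
#' @param name Mask name used in the filtering audit.
#' @return A region-mask data frame with columns `name`, `chrom`, `start`,
#'   `end`.
#' @export
read_bed_mask <- function(path, name = basename(path)) {
  b <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  region_mask(name, b[[1]], b[[2]], b[[3]])
}

#' Construct a region mask from interval vectors
#' @param name Mask name.
#' @param chrom,start,end Interval vectors; `start`/`end` are 0-based
#'   half-open as in BED.
#' @return A normalised region-mask data frame.
#' @export
region_mask <- function(name, chrom, start, end) {
  if (any(start >= end)) {
    stop("malformed mask interval: start >= end", call. = FALSE)
  }
  m <- data.frame(name = name, chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  m[order(m$chrom, m$start), , drop = FALSE]
}
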