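#' Genotype quality-control thresholds
#'
#' Default thresholds follow routine practice for medium-density bovine SNP
#' panels: sample call rate >= 0.90, sample heterozygosity within +/- 3 SD of
#' the panel mean, SNP call rate > 0.98, MAF > 0.03, Hardy-Weinberg
#' equilibrium p > 1e-7, and removal of duplicate / highly correlated
#' (|r| > 0.98) markers keeping the higher-MAF member.
#'
#' @param sample_cr_min minimum sample call rate.
#' @param het_sd_window heterozygosity window in panel SDs.
#' @param snp_cr_min minimum SNP call rate (exclusive).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param hwe_p_floor minimum HWE p-value (exclusive).
#' @param dup_r_max maximum absolute dosage correlation between retained
#'   neighbouring markers.
#' @return A list of thresholds of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_cr_min = 0.90, het_sd_window = 3,
                          snp_cr_min = 0.98, maf_min = 0.03,
                          hwe_p_floor = 1e-7, dup_r_max = 0.98) {
  rates <- c(sample_cr_min, snp_cr_min, maf_min, dup_r_max)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (het_sd_window <= 0) stop("het_sd_window must be > 0")
  if (hwe_p_floor < 0 || hwe_p_floor > 1) stop("hwe_p_floor must be in [0, 1]")
  structure(list(sample_cr_min = sample_cr_min, het_sd_window = het_sd_window,
                 snp_cr_min = snp_cr_min, maf_min = maf_min,
                 hwe_p_floor = hwe_p_floor, dup_r_max = dup_r_max),
            class = "qc_thresholds")
}

#' Sample-level genotype QC
#'
#' Applies, in order: (1) call-rate filter; (2) heterozygosity-rate filter,
#' the het rate being the proportion of heterozygous genotypes among an
#' animal's non-missing autosomal calls, with mean and SD computed over the
#' samples surviving rule 1; (3) exact-duplicate removal (identical
#' non-missing dosage vectors), keeping the first sample in id order.
#' Each sample is attributed to the first rule that removes it.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return List: `keep` (retained sample ids), `report` (rule, n_removed),
#'   `removed` (id, rule).
#' @export
sample_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (nrow(d) < 1L) stop("panel has no samples")
  ids <- panel$samples$id
  cr <- rowMeans(!is.na(d))
  fail_cr <- cr < thresholds$sample_cr_min

  het <- rowMeans(d == 1L, na.rm = TRUE)
  het[is.nan(het)] <- NA
  pool <- het[!fail_cr]
  mu <- mean(pool, na.rm = TRUE)
  sdv <- stats::sd(pool, na.rm = TRUE)
  fail_het <- rep(FALSE, length(ids))
  if (is.finite(sdv) && sdv > 0)
    fail_het <- !fail_cr & abs(het - mu) > thresholds$het_sd_window * sdv

  alive <- which(!fail_cr & !fail_het)
  fail_dup <- rep(FALSE, length(ids))
  if (length(alive) > 1L) {
    ord <- alive[order(ids[alive])]
    sig <- apply(d[ord, , drop = FALSE], 1L, function(g) {
      g[is.na(g)] <- 9L
      paste(g, collapse = "")
    })
    fail_dup[ord[duplicated(sig)]] <- TRUE
  }
  keep <- ids[!fail_cr & !fail_het & !fail_dup]
  if (length(keep) == 0L) stop("sample QC removed every sample")
  rule <- rep(NA_character_, length(ids))
  rule[fail_cr] <- "call_rate"
  rule[fail_het] <- "heterozygosity"
  rule[fail_dup] <- "duplicate"
  list(keep = keep,
       report = data.frame(rule = c("call_rate", "heterozygosity", "duplicate"),
                           n_removed = c(sum(fail_cr), sum(fail_het), sum(fail_dup))),
       removed = data.frame(id = ids[!is.na(rule)], rule = rule[!is.na(rule)]))
}

#' Marker-level genotype QC
#'
#' Keeps autosomal SNPs with call rate above threshold, MAF above threshold
#' and Hardy-Weinberg p-value above the floor.  Rules are applied in the
#' fixed order autosome, call rate, MAF, HWE; each marker is attributed to
#' the first rule that removes it, so per-rule counts sum to the total
#' removed.  MAF and HWE are computed on non-missing calls.
#'
#' @param panel a [genotype_panel()] (after sample QC).
#' @param thresholds a [qc_thresholds()].
#' @param autosomes integer chromosome codes considered autosomal
#'   (default `1:29`, the bovine autosomes).
#' @return List: `keep` (retained marker ids), `report` (rule, n_removed),
#'   `removed` (id, rule).
#' @export
snp_qc <- function(panel, thresholds = qc_thresholds(), autosomes = 1:29) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  m <- ncol(d)
  fail <- rep(NA_character_, m)

  fail[!(panel$map$chr %in% autosomes)] <- "autosome"

  cr <- colMeans(!is.na(d))
  fail[is.na(fail) & cr <= thresholds$snp_cr_min] <- "call_rate"

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  fail[is.na(fail) & maf <= thresholds$maf_min] <- "maf"

  todo <- which(is.na(fail))
  if (length(todo)) {
    hwep <- vapply(todo, function(j) {
      g <- d[, j]
      hwe_test(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 0L, na.rm = TRUE))
    }, numeric(1))
    fail[todo[hwep <= thresholds$hwe_p_floor]] <- "hwe"
  }
  keep <- panel$map$id[is.na(fail)]
  rules <- c("autosome", "call_rate", "maf", "hwe")
  list(keep = keep,
       report = data.frame(rule = rules,
                           n_removed = as.integer(table(factor(fail, rules)))),
       removed = data.frame(id = panel$map$id[!is.na(fail)],
                            rule = fail[!is.na(fail)]))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' the expected frequencies implied by the sample allele frequency.
#' Monomorphic markers carry no segregation information and return p = 1 by
#' convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The p-value in \[0, 1\].
#' @examples
#' hwe_test(25, 50, 25)  # exact HWE proportions: p = 1
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Remove duplicate-position and highly correlated neighbouring SNPs
#'
#' For markers at an identical (chromosome, position), and for pairs of
#' retained markers within a sliding window of `window` adjacent markers
#' whose dosage correlation exceeds `r_max` in absolute value, only the
#' member with the highest MAF is kept (ties broken by marker id order).
#' The scan runs left to right over the map so membership does not depend
#' on input labelling.
#'
#' @param panel a [genotype_panel()] with markers sorted by (chr, position).
#' @param r_max absolute correlation threshold (exclusive).
#' @param window how many preceding retained markers to test (default 1,
#'   i.e. adjacent pairs only).
#' @return List: `keep` (retained marker ids), `report`, `removed`.
#' @export
dedupe_snps <- function(panel, r_max = 0.98, window = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  map <- panel$map
  m <- ncol(d)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  pos <- if ("bp" %in% names(map) && !anyNA(map$bp)) map$bp else map$cm
  rule <- rep(NA_character_, m)

  # same-position groups: keep highest MAF, ties by id order
  key <- paste(map$chr, pos, sep = ":")
  for (grp in split(seq_len(m), key)) {
    if (length(grp) < 2L) next
    best <- grp[order(-maf[grp], map$id[grp])][1L]
    rule[setdiff(grp, best)] <- "same_position"
  }

  # correlated neighbours among retained markers, within chromosome
  if (window >= 1L) {
    kept <- which(is.na(rule))
    for (k in seq_along(kept)) {
      j <- kept[k]
      if (!is.na(rule[j])) next
      back <- kept[seq_len(k - 1L)]
      back <- back[is.na(rule[back])]
      back <- utils::tail(back[map$chr[back] == map$chr[j]], window)
      for (i in back) {
        r <- suppressWarnings(stats::cor(d[, i], d[, j],
                                         use = "pairwise.complete.obs"))
        if (is.finite(r) && abs(r) > r_max) {
          pair <- c(i, j)
          best <- pair[order(-maf[pair], map$id[pair])][1L]
          rule[setdiff(pair, best)] <- "correlated"
          if (!is.na(rule[j])) break
        }
      }
    }
  }
  keep <- map$id[is.na(rule)]
  rules <- c("same_position", "correlated")
  list(keep = keep,
       report = data.frame(rule = rules,
                           n_removed = as.integer(table(factor(rule, rules)))),
       removed = data.frame(id = map$id[!is.na(rule)], rule = rule[!is.na(rule)]))
}

#' Run full genotype QC
#'
#' Convenience wrapper: sample QC, then marker QC, then duplicate-marker
#' removal, returning the filtered panel and a combined report.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param autosomes autosomal chromosome codes.
#' @param window neighbour window for [dedupe_snps()].
#' @return List: `panel` (filtered), `report` (step, rule, n_removed).
#' @export
run_genotype_qc <- function(panel, thresholds = qc_thresholds(),
                            autosomes = 1:29, window = 1L) {
  sq <- sample_qc(panel, thresholds)
  panel <- subset_panel(panel, samples = sq$keep)
  mq <- snp_qc(panel, thresholds, autosomes)
  if (length(mq$keep) == 0L) stop("marker QC removed every marker")
  panel <- subset_panel(panel, markers = mq$keep)
  dq <- dedupe_snps(panel, thresholds$dup_r_max, window)
  if (length(dq$keep) == 0L) stop("duplicate-marker removal removed every marker")
  panel <- subset_panel(panel, markers = dq$keep)
  report <- rbind(cbind(step = "sample", sq$report),
                  cbind(step = "snp", mq$report),
                  cbind(step = "dedupe", dq$report))
  list(panel = panel, report = report)
}
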