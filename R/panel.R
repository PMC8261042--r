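#' Genotype panel
#'
#' Container for a set of biallelic autosomal SNP genotypes: a marker map,
#' per-sample allele-1 dosages (0/1/2, `NA` = missing) and, optionally, the
#' phased haplotypes the dosages derive from.  The dosage counts the first
#' (`a1`) allele of each marker; haplotype rows come in pairs, rows
#' `2i - 1` and `2i` belonging to sample `i`.
#'
#' @param dosage integer matrix, samples x markers, values in \{0, 1, 2, NA\}.
#' @param map data frame with columns `chr` (integer chromosome code),
#'   `id` (marker id), `cm` (map position, centimorgan) and optionally
#'   `bp`, `a1`, `a2`.  Markers must be ordered by (`chr`, position).
#' @param samples data frame with columns `id` and `breed`.
#' @param haplo optional 0/1 integer matrix with `2 * nrow(dosage)` rows
#'   whose paired row sums reproduce `dosage`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, map, samples, haplo = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.data.frame(map) || !all(c("chr", "id", "cm") %in% names(map)))
    stop("`map` needs columns chr, id, cm")
  if (nrow(map) != ncol(dosage))
    stop("map rows (", nrow(map), ") != dosage columns (", ncol(dosage), ")")
  if (!is.data.frame(samples) || !all(c("id", "breed") %in% names(samples)))
    stop("`samples` needs columns id, breed")
  if (nrow(samples) != nrow(dosage))
    stop("sample rows (", nrow(samples), ") != dosage rows (", nrow(dosage), ")")
  if (anyDuplicated(samples$id)) stop("duplicated sample ids")
  if (anyDuplicated(map$id)) stop("duplicated marker ids")
  ord <- order(map$chr, map$cm)
  if (!identical(ord, seq_len(nrow(map))))
    stop("markers must be sorted by (chr, position)")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(haplo)) {
    haplo <- as.matrix(haplo)
    if (nrow(haplo) != 2L * nrow(dosage) || ncol(haplo) != ncol(dosage))
      stop("haplo must be 2*n_samples x n_markers")
    if (!all(haplo %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  }
  rownames(dosage) <- samples$id
  colnames(dosage) <- map$id
  structure(
    list(dosage = dosage, map = map, samples = samples,
         haplo = haplo, phased = !is.null(haplo)),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "markers;", length(unique(x$samples$breed)), "breed(s);",
      if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param samples sample ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param markers marker ids (or logical/integer index) to keep; `NULL` keeps all.
#' @return The subsetted `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, markers = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- seq_len(nrow(panel$dosage))
  mi <- seq_len(ncol(panel$dosage))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$samples$id) else si[samples]
    if (anyNA(si)) stop("unknown sample id(s): ",
                        paste(samples[is.na(match(samples, panel$samples$id))], collapse = ", "))
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, panel$map$id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id(s)")
  }
  haplo <- NULL
  if (panel$phased) {
    hrows <- as.vector(rbind(2L * si - 1L, 2L * si))
    haplo <- panel$haplo[hrows, mi, drop = FALSE]
  }
  genotype_panel(panel$dosage[si, mi, drop = FALSE],
                 panel$map[mi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE],
                 haplo = haplo)
}

#' Allele frequencies of the counted (a1) allele
#'
#' @param panel a [genotype_panel()].
#' @param by_breed if `TRUE`, return a markers x breeds matrix of within-breed
#'   frequencies; otherwise a single pooled frequency vector.
#' @return Numeric vector (pooled) or matrix (per breed), computed on
#'   non-missing calls.
#' @export
allele_freqs <- function(panel, by_breed = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!by_breed) return(colMeans(panel$dosage, na.rm = TRUE) / 2)
  breeds <- sort(unique(panel$samples$breed))
  out <- vapply(breeds, function(b) {
    colMeans(panel$dosage[panel$samples$breed == b, , drop = FALSE],
             na.rm = TRUE) / 2
  }, numeric(ncol(panel$dosage)))
  dimnames(out) <- list(panel$map$id, breeds)
  out
}

#' Mean-impute missing dosages within breed
#'
#' Replaces missing dosages by the within-breed marker mean (falling back to
#' the pooled mean for breeds with no calls at a marker).  Imputation within
#' breed preserves the breed allele-frequency structure that the genomic
#' relationship matrix depends on.
#'
#' @param panel a [genotype_panel()].
#' @return The panel with a complete (numeric) dosage matrix; phase, if any,
#'   is dropped since imputed dosages are no longer haplotype sums.
#' @export
impute_dosages <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  if (!anyNA(d)) return(panel)
  pooled <- colMeans(d, na.rm = TRUE)
  pooled[is.nan(pooled)] <- 1 # marker with zero calls anywhere: freq 0.5
  for (b in unique(panel$samples$breed)) {
    rows <- which(panel$samples$breed == b)
    sub <- d[rows, , drop = FALSE]
    mu <- colMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- pooled[is.nan(mu)]
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx)) sub[idx] <- mu[idx[, 2]]
    d[rows, ] <- sub
  }
  out <- panel
  out$dosage <- d
  out$haplo <- NULL
  out$phased <- FALSE
  out
}

# split one integer seed into named reproducible sub-seeds (documented
# stream-splitting rule: set.seed(seed) then draw k integers below 2^31).
split_seed <- function(seed, n, names = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max, n)
  if (!is.null(names)) names(s) <- names
  s
}
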