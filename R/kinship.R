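#' Relationship matrix container
#'
#' Light wrapper pairing a (possibly sparse) symmetric matrix with the
#' animal ids it is indexed by and a flavor tag recording what it is.
#'
#' @param mat matrix or `Matrix`.
#' @param ids animal ids (row/column order).
#' @param flavor one of `"A"`, `"A_inv"`, `"A22"`, `"G"`, `"G_blend"`, `"H_inv"`.
#' @param meta optional list of provenance (allele-frequency policy, blend
#'   weights, scaling denominator, ...).
#' @return Object of class `relmat`.
#' @export
relmat <- function(mat, ids, flavor, meta = list()) {
  flavor <- match.arg(flavor, c("A", "A_inv", "A22", "G", "G_blend", "H_inv"))
  if (nrow(mat) != ncol(mat) || nrow(mat) != length(ids))
    stop("matrix dimension must equal id-list length")
  asym <- max(abs(mat - Matrix::t(mat)))
  if (asym > 1e-8 * max(1, max(abs(mat))))
    stop("matrix not symmetric (max asymmetry ", format(asym), ")")
  dimnames(mat) <- list(ids, ids)
  structure(list(mat = mat, ids = as.character(ids), flavor = flavor,
                 meta = meta), class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat("relmat [", x$flavor, "] ", length(x$ids), " x ", length(x$ids), "\n",
      sep = "")
  invisible(x)
}

ped_indices <- function(pedigree) {
  ids <- as.character(pedigree$id)
  si <- match(as.character(pedigree$sire), ids)
  di <- match(as.character(pedigree$dam), ids)
  unk <- function(p) is.na(p) | p %in% c("0", "")
  si[unk(as.character(pedigree$sire))] <- 0L
  di[unk(as.character(pedigree$dam))] <- 0L
  if (anyNA(si) || anyNA(di))
    stop("parent id(s) absent from pedigree: ",
         paste(unique(c(as.character(pedigree$sire)[is.na(si)],
                        as.character(pedigree$dam)[is.na(di)])), collapse = ", "))
  list(ids = ids, sire = as.integer(si), dam = as.integer(di))
}

#' Numerator relationship matrix (tabular method)
#'
#' Computes additive relationships by the tabular method, including
#' inbreeding, over a topologically sorted pedigree.  With `subset` the
#' corresponding block (e.g. A22 for the genotyped animals) is returned.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam` (0, `""` or
#'   `NA` = unknown), parents listed before offspring.
#' @param subset optional ids whose block to extract.
#' @return A dense [relmat()] of flavor `"A"` (or `"A22"` when `subset` is
#'   given).
#' @export
build_A <- function(pedigree, subset = NULL) {
  px <- ped_indices(pedigree)
  A <- .tabular_A(px$sire, px$dam)
  if (is.null(subset))
    return(relmat(A, px$ids, "A"))
  idx <- match(as.character(subset), px$ids)
  if (anyNA(idx))
    stop("subset id(s) absent from pedigree: ",
         paste(as.character(subset)[is.na(idx)], collapse = ", "))
  relmat(A[idx, idx, drop = FALSE], as.character(subset), "A22")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `alpha = 1/d` to the inverse, `d` being its Mendelian-sampling variance
#' `0.5 - 0.25 (F_s + F_d)` (0.75 - 0.25 F of the known parent when one is
#' missing, 1 when both are), with inbreeding coefficients from the
#' ancestor-tracing recursion.  Equals the dense inverse of [build_A()].
#'
#' @param pedigree as in [build_A()].
#' @return Sparse symmetric [relmat()] of flavor `"A_inv"`.
#' @export
build_A_inverse <- function(pedigree) {
  px <- ped_indices(pedigree)
  n <- length(px$ids)
  F <- .inbreeding_recursive(px$sire, px$dam)
  Fp <- function(p) ifelse(p > 0L, F[pmax(p, 1L)], 0)
  ks <- px$sire > 0L
  kd <- px$dam > 0L
  d <- ifelse(ks & kd, 0.5 - 0.25 * (Fp(px$sire) + Fp(px$dam)),
       ifelse(ks, 0.75 - 0.25 * Fp(px$sire),
       ifelse(kd, 0.75 - 0.25 * Fp(px$dam), 1)))
  alpha <- 1 / d
  i <- seq_len(n)
  ii <- c(i, i[ks], i[kd], px$sire[ks], px$dam[kd], px$sire[ks & kd],
          px$sire[ks], px$dam[kd])
  jj <- c(i, px$sire[ks], px$dam[kd], i[ks], i[kd], px$dam[ks & kd],
          px$sire[ks], px$dam[kd])
  xx <- c(alpha,
          -0.5 * alpha[ks], -0.5 * alpha[kd],
          -0.5 * alpha[ks], -0.5 * alpha[kd],
          0.25 * alpha[ks & kd],
          0.25 * alpha[ks], 0.25 * alpha[kd])
  # the sire-dam cross term appears in both (s,d) and (d,s)
  ii <- c(ii, px$dam[ks & kd]); jj <- c(jj, px$sire[ks & kd])
  xx <- c(xx, 0.25 * alpha[ks & kd])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  relmat(M, px$ids, "A_inv", meta = list(inbreeding = F))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p_k (1 - p_k))` with `Z = M - 2p`, `M` the dosage
#' matrix.  The centering/scaling frequencies are either the pooled sample
#' frequencies or the unweighted mean of per-breed frequencies ("current
#' allele frequencies averaged across breeds"); the latter is the default
#' for multi-breed panels.
#'
#' @param panel a [genotype_panel()]; missing dosages are mean-imputed
#'   within breed first.
#' @param freq_policy `"mean_of_breeds"` or `"pooled"`.
#' @return Dense [relmat()] of flavor `"G"`; `meta` records the frequencies
#'   and the scaling denominator.
#' @export
build_G <- function(panel, freq_policy = c("mean_of_breeds", "pooled")) {
  stopifnot(inherits(panel, "genotype_panel"))
  freq_policy <- match.arg(freq_policy)
  panel <- impute_dosages(panel)
  p <- if (freq_policy == "pooled" || length(unique(panel$samples$breed)) == 1L)
    allele_freqs(panel) else rowMeans(allele_freqs(panel, by_breed = TRUE))
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers fixed: zero VanRaden denominator")
  Z <- sweep(panel$dosage, 2L, 2 * p)
  G <- tcrossprod(Z) / denom
  relmat(G, panel$samples$id, "G",
         meta = list(freq_policy = freq_policy, freqs = p, denom = denom))
}

#' Inverse of the blended single-step relationship matrix
#'
#' `H^-1 = A^-1 + [0 0; 0 (w_G G + w_A A22)^-1 - A22^-1]` on the genotyped
#' block, with the default blend `(0.95, 0.05)`.  The blend keeps the
#' genomic matrix invertible and acknowledges that markers do not capture
#' all pedigree relationships.
#'
#' @param A_inv [build_A_inverse()] output covering the full pedigree.
#' @param A22 pedigree relationships among the genotyped animals
#'   ([build_A()] with `subset`).
#' @param G [build_G()] output on the identical id ordering as `A22`.
#' @param blend weights `c(w_G, w_A)`, summing to 1.
#' @return Sparse [relmat()] of flavor `"H_inv"` over the full pedigree.
#' @export
build_H_inverse <- function(A_inv, A22, G, blend = c(0.95, 0.05)) {
  stopifnot(inherits(A_inv, "relmat"), A_inv$flavor == "A_inv")
  if (abs(sum(blend) - 1) > 1e-12) stop("blend weights must sum to 1")
  if (inherits(A22, "relmat")) { a22_ids <- A22$ids; A22 <- as.matrix(A22$mat) }
  else a22_ids <- rownames(A22)
  if (inherits(G, "relmat")) { g_ids <- G$ids; G <- as.matrix(G$mat) }
  else g_ids <- rownames(G)
  if (!identical(as.character(a22_ids), as.character(g_ids)))
    stop("A22 and G must share an identical id ordering")
  idx <- match(a22_ids, A_inv$ids)
  if (anyNA(idx))
    stop("genotyped id(s) absent from pedigree: ",
         paste(a22_ids[is.na(idx)], collapse = ", "))
  Gb <- blend[1] * G + blend[2] * A22
  ch <- tryCatch(chol(Gb), error = function(e) NULL)
  if (is.null(ch))
    stop("blended matrix singular (condition number ",
         format(kappa(Gb), digits = 3), ")")
  corr <- chol2inv(ch) - chol2inv(chol(A22))
  n <- length(A_inv$ids)
  H <- A_inv$mat +
    Matrix::sparseMatrix(i = rep(idx, length(idx)),
                         j = rep(idx, each = length(idx)),
                         x = as.vector(corr), dims = c(n, n))
  relmat(H, A_inv$ids, "H_inv",
         meta = list(blend = blend, genotyped = as.character(a22_ids)))
}

#' Write a relationship matrix as id-indexed triplets
#'
#' @param rm a [relmat()].
#' @param path output CSV path (columns i, j, value over the lower
#'   triangle); an id-list sidecar `<path>.ids` is written alongside.
#' @return `path`, invisibly.
#' @export
write_relmat <- function(rm, path) {
  stopifnot(inherits(rm, "relmat"))
  M <- methods::as(methods::as(Matrix::Matrix(rm$mat, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  keep <- M@i >= M@j
  df <- data.frame(i = M@i[keep] + 1L, j = M@j[keep] + 1L, value = M@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE)
  writeLines(rm$ids, paste0(path, ".ids"))
  invisible(path)
}
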