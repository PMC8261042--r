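#' Linkage disequilibrium between adjacent markers
#'
#' For every within-chromosome adjacent marker pair, estimates the four
#' haplotype frequencies and the signed LD correlation
#' \deqn{r = (\rho_{AB}\rho_{ab} - \rho_{Ab}\rho_{aB}) /
#'       \sqrt{\rho_A \rho_a \rho_B \rho_b},}
#' where A/B denote the dosage-counted allele at each marker.  With phased
#' input the haplotype frequencies are plug-in haplotype counts (and r is
#' exactly the Pearson correlation of the allele indicators across
#' haplotypes); with unphased input they are estimated by a two-locus EM
#' over genotype counts.  Pairs with a monomorphic member are emitted with
#' `defined = FALSE` and are excluded from summaries downstream.
#'
#' @param panel a [genotype_panel()], typically restricted to one breed.
#' @param breed optional breed label to subset to before computing.
#' @param use_phase use phased haplotypes when present (default).
#' @param em_iter,em_tol EM iteration cap and convergence tolerance.
#' @return Data frame of class `ld_result`: chr, i, j, id_i, id_j, pA, pB,
#'   pAB, pAb, paB, pab, r, r2, defined.
#' @export
adjacent_ld <- function(panel, breed = NULL, use_phase = TRUE,
                        em_iter = 50L, em_tol = 1e-8) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(breed))
    panel <- subset_panel(panel, samples = panel$samples$breed == breed)
  m <- ncol(panel$dosage)
  if (m < 2L) stop("need at least 2 markers")
  phased <- use_phase && panel$phased
  if (!phased && nrow(panel$dosage) < 2L)
    stop("unphased LD needs at least 2 samples")
  idx <- which(diff(panel$map$chr) == 0L) # pair (k, k+1) within chromosome
  out <- data.frame(chr = panel$map$chr[idx], i = idx, j = idx + 1L,
                    id_i = panel$map$id[idx], id_j = panel$map$id[idx + 1L],
                    pA = NA_real_, pB = NA_real_, pAB = NA_real_,
                    pAb = NA_real_, paB = NA_real_, pab = NA_real_,
                    r = NA_real_, r2 = NA_real_, defined = FALSE)
  if (phased) {
    H <- panel$haplo
    pa <- colMeans(H)
    for (k in seq_along(idx)) {
      i <- idx[k]
      pAB <- mean(H[, i] == 1L & H[, i + 1L] == 1L)
      out[k, c("pA", "pB", "pAB")] <- c(pa[i], pa[i + 1L], pAB)
    }
  } else {
    d <- panel$dosage
    for (k in seq_along(idx)) {
      i <- idx[k]
      est <- em_haplotype_freqs(d[, i], d[, i + 1L], em_iter, em_tol)
      out[k, c("pA", "pB", "pAB")] <- est
    }
  }
  out$pAb <- out$pA - out$pAB
  out$paB <- out$pB - out$pAB
  out$pab <- 1 - out$pAB - out$pAb - out$paB
  den <- out$pA * (1 - out$pA) * out$pB * (1 - out$pB)
  ok <- is.finite(den) & den > 0
  out$r[ok] <- (out$pAB[ok] * out$pab[ok] - out$pAb[ok] * out$paB[ok]) /
    sqrt(den[ok])
  out$r2 <- out$r^2
  out$defined <- ok
  class(out) <- c("ld_result", "data.frame")
  out
}

# two-locus EM for the AB haplotype frequency from unphased dosages;
# returns c(pA, pB, pAB).  Only double heterozygotes have ambiguous phase.
em_haplotype_freqs <- function(gi, gj, max_iter = 50L, tol = 1e-8) {
  keep <- !is.na(gi) & !is.na(gj)
  gi <- gi[keep]; gj <- gj[keep]
  n <- length(gi)
  if (n == 0L) return(c(NA_real_, NA_real_, NA_real_))
  pA <- mean(gi) / 2
  pB <- mean(gj) / 2
  # known AB-haplotype contributions outside the double-het class
  base <- sum(ifelse(gi == 2L, gj, ifelse(gi == 1L, pmax(gj - 1L, 0L), 0L)))
  ndh <- sum(gi == 1L & gj == 1L)
  pAB <- pA * pB
  for (it in seq_len(max_iter)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    cis <- pAB * pab
    tot <- cis + pAb * paB
    frac <- if (tot > 0) cis / tot else 0.5
    new <- (base + ndh * frac) / (2 * n)
    new <- min(max(new, max(0, pA + pB - 1)), min(pA, pB))
    if (abs(new - pAB) < tol) { pAB <- new; break }
    pAB <- new
  }
  c(pA, pB, pAB)
}

#' Persistence of LD phase between two breeds
#'
#' Pearson correlation, across a common set of adjacent marker pairs, of the
#' signed LD values r computed within each of two breeds.  High positive
#' values mean the two populations share both LD and its phase, the
#' condition for marker effects to transfer across populations.  Reported
#' per chromosome and pooled over all shared pairs.
#'
#' @param ld_a,ld_b [adjacent_ld()] results computed on the identical marker
#'   list and allele coding.
#' @param labels length-2 character vector naming the two breeds.
#' @return List of class `phase_persistence`: `overall` (pooled R), `n_pairs`,
#'   `per_chr` (data frame chr, R, n), `labels`.
#' @export
phase_persistence <- function(ld_a, ld_b, labels = c("A", "B")) {
  if (nrow(ld_a) != nrow(ld_b) ||
      !all(ld_a$id_i == ld_b$id_i & ld_a$id_j == ld_b$id_j))
    stop("LD results must cover an identical marker-pair list")
  ok <- ld_a$defined & ld_b$defined
  if (sum(ok) < 2L) stop("fewer than 2 shared defined pairs")
  ra <- ld_a$r[ok]; rb <- ld_b$r[ok]
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("zero variance of r over the shared pair set: persistence undefined")
  per_chr <- do.call(rbind, lapply(split(seq_along(ra), ld_a$chr[ok]), function(s) {
    R <- if (length(s) > 1L && stats::sd(ra[s]) > 0 && stats::sd(rb[s]) > 0)
      stats::cor(ra[s], rb[s]) else NA_real_
    data.frame(R = R, n = length(s))
  }))
  per_chr <- cbind(chr = as.integer(rownames(per_chr)), per_chr)
  rownames(per_chr) <- NULL
  structure(list(overall = stats::cor(ra, rb), n_pairs = sum(ok),
                 per_chr = per_chr, labels = labels),
            class = "phase_persistence")
}

#' @export
print.phase_persistence <- function(x, ...) {
  cat(sprintf("persistence of phase %s vs %s: R = %.3f over %d adjacent pairs\n",
              x$labels[1], x$labels[2], x$overall, x$n_pairs))
  invisible(x)
}

#' Correlation of allele frequencies between two populations
#'
#' @param freq_a,freq_b frequency vectors of the identical counted allele on
#'   the identical marker list.
#' @return Pearson correlation in \[-1, 1\].
#' @export
allele_freq_correlation <- function(freq_a, freq_b) {
  if (length(freq_a) != length(freq_b)) stop("frequency vectors differ in length")
  ok <- is.finite(freq_a) & is.finite(freq_b)
  if (sum(ok) < 2L) stop("fewer than 2 usable markers")
  if (stats::sd(freq_a[ok]) == 0 || stats::sd(freq_b[ok]) == 0)
    stop("zero frequency variance: correlation undefined")
  stats::cor(freq_a[ok], freq_b[ok])
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of a symmetric relationship matrix; component scores
#' are the eigenvectors scaled by the square root of their eigenvalues, the
#' variance fraction of each component is eigenvalue / trace, and each
#' component's sign is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param G symmetric relationship matrix (or [build_G()] output).
#' @param n_comp number of leading components to return.
#' @param tol asymmetry tolerance.
#' @return List of class `grm_pca`: `scores` (n x n_comp), `values`
#'   (all eigenvalues, descending), `var_frac`.
#' @export
grm_pca <- function(G, n_comp = 2L, tol = 1e-8) {
  if (inherits(G, "relmat")) G <- as.matrix(G$mat)
  G <- as.matrix(G)
  if (nrow(G) < 2L || nrow(G) != ncol(G)) stop("G must be square, dim >= 2")
  if (max(abs(G - t(G))) > tol * max(1, max(abs(G))))
    stop("G is not symmetric within tolerance")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  n_comp <- min(n_comp, ncol(e$vectors))
  V <- e$vectors[, seq_len(n_comp), drop = FALSE]
  for (k in seq_len(n_comp)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  scores <- sweep(V, 2, sqrt(pmax(e$values[seq_len(n_comp)], 0)), `*`)
  rownames(scores) <- rownames(G)
  structure(list(scores = scores, values = e$values,
                 var_frac = e$values / sum(diag(G))),
            class = "grm_pca")
}

#' Pairwise phase-persistence / allele-frequency-correlation matrix
#'
#' Computes, for every breed pair in a panel, the persistence of phase
#' (upper triangle) and the allele-frequency correlation (lower triangle),
#' the customary square summary of cross-breed genomic correspondence.
#'
#' @param panel a multi-breed [genotype_panel()].
#' @param use_phase passed to [adjacent_ld()].
#' @return List: `matrix` (breeds x breeds; persistence above, frequency
#'   correlation below the diagonal), `ld` (per-breed `ld_result`s).
#' @export
breed_pair_summary <- function(panel, use_phase = TRUE) {
  breeds <- sort(unique(panel$samples$breed))
  if (length(breeds) < 2L) stop("need at least two breeds")
  ld <- lapply(breeds, function(b) adjacent_ld(panel, breed = b,
                                               use_phase = use_phase))
  names(ld) <- breeds
  fr <- allele_freqs(panel, by_breed = TRUE)
  M <- matrix(NA_real_, length(breeds), length(breeds),
              dimnames = list(breeds, breeds))
  for (a in seq_along(breeds)) for (b in seq_along(breeds)) {
    if (a >= b) next
    M[a, b] <- phase_persistence(ld[[a]], ld[[b]], breeds[c(a, b)])$overall
    M[b, a] <- allele_freq_correlation(fr[, a], fr[, b])
  }
  list(matrix = M, ld = ld)
}
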