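#' Default priors for the Gibbs sampler
#'
#' Weakly informative proper priors: inverse-Wishart for the genetic
#' covariance with degrees of freedom `t + 2` and scale `0.1 * diag(v_y)`
#' (so its prior mean is 10% of the per-trait phenotypic variance), and
#' scaled inverse chi-square with 3 degrees of freedom for the
#' permanent-environment (scale `0.1 v_y`) and residual (scale `0.5 v_y`)
#' variances.
#'
#' @param phen_var named per-trait phenotypic variances (e.g. record
#'   variances per breed).
#' @return List with `S0`, `nu0`, `nu_e`, `s2e0`, `nu_p`, `s2p0`.
#' @export
default_priors <- function(phen_var) {
  t <- length(phen_var)
  list(S0 = diag(0.1 * phen_var, t), nu0 = t + 2,
       nu_e = rep(3, t), s2e0 = 0.5 * phen_var,
       nu_p = rep(3, t), s2p0 = 0.1 * phen_var)
}

#' Gibbs sampling of the multi-breed covariance components
#'
#' Single-chain Gibbs sampler for the breed-as-trait single-step animal
#' model.  Each cycle (i) samples every location parameter from its full
#' conditional in a single-site Gauss-Seidel sweep over the mixed-model
#' equations, (ii) samples the genetic covariance matrix from its
#' inverse-Wishart full conditional with scale `S0 + U' H^-1 U` and degrees
#' of freedom `nu0 + n_animals`, and (iii) samples each
#' permanent-environment and residual variance from its scaled inverse
#' chi-square full conditional.  The chain is reproducible given `seed`;
#' animals are processed in the canonical order of the relationship matrix
#' ids, so record order does not affect the chain.
#'
#' @param records,spec,H_inv as in [assemble_mme()].
#' @param priors as [default_priors()]; `NULL` derives defaults from the
#'   per-trait record variances.
#' @param chain list: `cycles`, `burnin`, `thin`.  The study-scale protocol
#'   (1,000,000 / 100,000 / 50) is available by configuration; the default
#'   desk-scale chain is 20,000 / 4,000 / 10.
#' @param seed integer seed.
#' @param start optional list with `Sigma`, `s2e`, `s2p` starting values.
#' @return Object of class `gibbs_chain`: `draws` (stored cycles x
#'   parameters), `params`, `config`, `x_mean` (posterior-mean location
#'   solutions), `spec`, `traits`.
#' @export
gibbs_sample <- function(records, spec, H_inv, priors = NULL,
                         chain = list(cycles = 20000L, burnin = 4000L,
                                      thin = 10L),
                         seed = 1L, start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(H_inv, "relmat"))
  cycles <- as.integer(chain$cycles); burnin <- as.integer(chain$burnin)
  thin <- as.integer(chain$thin)
  if (!(cycles > burnin && burnin >= 0L && thin >= 1L))
    stop("need cycles > burnin >= 0 and thin >= 1")
  T <- length(spec$traits)
  # canonical record order: the chain is then invariant to input row order
  records <- records[order(match(records$breed, spec$traits),
                           as.character(records$animal), records$value), ,
                     drop = FALSE]
  nrec_t <- table(factor(records$breed, spec$traits))
  if (any(nrec_t == 0))
    stop("trait(s) with zero records under a default (improper for them) ",
         "prior: ", paste(spec$traits[nrec_t == 0], collapse = ", "))
  phen_var <- tapply(records$value, factor(records$breed, spec$traits),
                     stats::var)
  phen_var[!is.finite(phen_var) | phen_var <= 0] <- 1
  if (is.null(priors)) priors <- default_priors(as.numeric(phen_var))
  ds <- build_design(records, spec, H_inv$ids)
  C0 <- methods::as(Matrix::crossprod(ds$W), "generalMatrix")
  rhs0 <- as.numeric(Matrix::crossprod(ds$W, ds$y))
  if (is.null(start))
    start <- list(Sigma = diag(0.25 * as.numeric(phen_var), T) +
                    0.01 * mean(phen_var) * (matrix(1, T, T) - diag(T)),
                  s2e = 0.65 * as.numeric(phen_var),
                  s2p = 0.10 * as.numeric(phen_var))
  set.seed(as.integer(seed))
  res <- .gibbs_mme(
    C0, rhs0, methods::as(ds$W, "CsparseMatrix"), ds$y,
    as.integer(ds$rec_trait - 1L),
    methods::as(methods::as(H_inv$mat, "generalMatrix"), "CsparseMatrix"),
    ds$n_fix, T, ds$n_anim,
    as.integer(ds$eq_trait - 1L), as.integer(ds$eq_type),
    priors$S0, priors$nu0, priors$nu_e, priors$s2e0, priors$nu_p,
    priors$s2p0, cycles, burnin, thin,
    as.matrix(start$Sigma), start$s2e, start$s2p)
  ut <- which(upper.tri(diag(T), diag = TRUE), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  params <- c(sprintf("sigma_u[%s,%s]", spec$traits[ut[, 1]],
                      spec$traits[ut[, 2]]),
              sprintf("sigma2_p[%s]", spec$traits),
              sprintf("sigma2_e[%s]", spec$traits))
  draws <- res$draws
  colnames(draws) <- params
  # PE columns of traits without a PE term are not model parameters
  drop <- sprintf("sigma2_p[%s]", setdiff(spec$traits, spec$pe_traits))
  draws <- draws[, setdiff(params, drop), drop = FALSE]
  structure(list(draws = draws, params = colnames(draws),
                 config = list(cycles = cycles, burnin = burnin,
                               thin = thin, seed = seed),
                 x_mean = res$x_mean, jitters = res$jitters,
                 traits = spec$traits, pe_traits = spec$pe_traits,
                 index = ds$index),
            class = "gibbs_chain")
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat("gibbs_chain:", nrow(x$draws), "stored draws of", length(x$params),
      "parameters (cycles", x$config$cycles, "burnin", x$config$burnin,
      "thin", x$config$thin, ")\n")
  invisible(x)
}

# time-series (spectral) variance by Geyer's initial positive sequence:
# sum adjacent-lag autocovariance pairs while the pair sums stay positive.
ips_tsvar <- function(z) {
  n <- length(z)
  z <- z - mean(z)
  g0 <- sum(z^2) / n
  if (g0 == 0) return(0)
  acov <- function(k) sum(z[seq_len(n - k)] * z[(k + 1):n]) / n
  tsv <- g0
  k <- 1L
  while (k + 1L < n) {
    pair <- acov(k) + acov(k + 1L)
    if (pair <= 0) break
    tsv <- tsv + 2 * pair
    k <- k + 2L
  }
  tsv
}

#' Posterior summary with convergence diagnostics
#'
#' Per parameter: posterior mean, time-series standard error (spectral
#' variance by the initial-positive-sequence estimator), effective sample
#' size `n * var / tsvar`, and the Geweke z comparing the means of the first
#' 10% and last 50% of the chain.  A constant chain reports SE 0, ESS equal
#' to the chain length and z = 0 by convention.
#'
#' @param chain a [gibbs_sample()] chain, or a numeric matrix/vector of draws.
#' @return Data frame: param, mean, ts_se, ess, geweke_z.
#' @export
posterior_summary <- function(chain) {
  draws <- if (inherits(chain, "gibbs_chain")) chain$draws else chain
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                           dimnames = list(NULL, "param"))
  if (nrow(draws) < 10L) stop("need at least 10 stored draws")
  n <- nrow(draws)
  out <- lapply(colnames(draws), function(p) {
    z <- draws[, p]
    v <- stats::var(z)
    if (v == 0)
      return(data.frame(param = p, mean = z[1], ts_se = 0, ess = n,
                        geweke_z = 0))
    tsv <- ips_tsvar(z)
    a <- z[seq_len(max(2L, floor(0.1 * n)))]
    b <- z[(n - floor(0.5 * n) + 1L):n]
    den <- ips_tsvar(a) / length(a) + ips_tsvar(b) / length(b)
    data.frame(param = p, mean = mean(z), ts_se = sqrt(tsv / n),
               ess = n * v / tsv,
               geweke_z = if (den > 0) (mean(a) - mean(b)) / sqrt(den) else 0)
  })
  do.call(rbind, out)
}

#' Genetic parameters from covariance components
#'
#' Heritability `h2 = s2_u / (s2_u + s2_p + s2_e)` (PE variance 0 when the
#' breed has none), genetic correlations
#' `r_g = cov_u(b,c) / sqrt(s2_u(b) s2_u(c))` and repeatability
#' `(s2_u + s2_p) / total`.  Applied to a chain, the parameters are derived
#' per stored draw and then summarised as posterior mean with time-series
#' SE; applied to a single [covariance_components()], they are returned
#' directly.
#'
#' @param x a `gibbs_chain` or a [covariance_components()].
#' @return For components: list `h2`, `rg`, `repeatability`.  For a chain:
#'   list with the same elements as posterior summaries plus `draws`, the
#'   per-draw derived parameters.
#' @export
derive_parameters <- function(x) {
  if (inherits(x, "covariance_components")) {
    t <- length(x$traits)
    s2u <- diag(x$Sigma_u)
    s2p <- stats::setNames(numeric(t), x$traits)
    s2p[names(x$s2p)] <- x$s2p
    tot <- s2u + s2p + x$s2e
    h2 <- s2u / tot
    D <- sqrt(s2u %o% s2u)
    if (any(diag(D) == 0)) stop("zero genetic variance: correlation undefined")
    rg <- x$Sigma_u / D
    rep_ <- (s2u + s2p) / tot
    return(list(h2 = stats::setNames(h2, x$traits), rg = rg,
                repeatability = rep_[names(x$s2p)]))
  }
  stopifnot(inherits(x, "gibbs_chain"))
  traits <- x$traits
  T <- length(traits)
  derive1 <- function(d) {
    S <- matrix(0, T, T, dimnames = list(traits, traits))
    S[upper.tri(S, diag = TRUE)] <- d[seq_len(T * (T + 1) / 2)]
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    s2p <- stats::setNames(numeric(T), traits)
    for (b in x$pe_traits) s2p[b] <- d[sprintf("sigma2_p[%s]", b)]
    s2e <- d[sprintf("sigma2_e[%s]", traits)]
    tot <- diag(S) + s2p + s2e
    h2 <- diag(S) / tot
    rep_ <- (diag(S) + s2p) / tot
    rg <- (S / sqrt(diag(S) %o% diag(S)))[upper.tri(S)]
    c(stats::setNames(h2, sprintf("h2[%s]", traits)),
      stats::setNames(rg, sprintf("rg[%s,%s]",
                                  traits[row(S)[upper.tri(S)]],
                                  traits[col(S)[upper.tri(S)]])),
      stats::setNames(rep_[x$pe_traits],
                      sprintf("repeatability[%s]", x$pe_traits)))
  }
  first <- derive1(x$draws[1L, ])
  res <- vapply(seq_len(nrow(x$draws)),
                function(i) derive1(x$draws[i, ]), first)
  der <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
  colnames(der) <- names(first)
  list(summary = posterior_summary(der), draws = der)
}
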