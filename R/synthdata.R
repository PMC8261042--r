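#' Breed specification for simulation
#'
#' Describes one breed group: a pure founder population (taurine or
#' indicine) drifted away from its ancestral pool, or a composite formed by
#' crossing previously defined breeds in stated admixture fractions (e.g. a
#' 3/8-zebu composite).
#'
#' @param label short breed label.
#' @param role `"founder-taurine"`, `"founder-indicine"` or `"composite"`.
#' @param parents for composites, labels of previously defined breeds.
#' @param fractions admixture fractions over `parents`, dyadic (denominator
#'   a power of 2), summing to 1.
#' @param divergence Fst-like drift of a founder breed from its ancestral
#'   pool, in \[0, 1).
#' @param ancestry ancestral-pool label; founder breeds sharing a label are
#'   drifted from one common pool (shared LD phase), different labels mean
#'   independent pools.
#' @param n_founders number of founder animals (founder breeds).
#' @param n_generations descendant generations of random mating after
#'   founding / after composite formation.
#' @return Object of class `breed_spec`.
#' @export
breed_spec <- function(label, role = c("founder-taurine", "founder-indicine",
                                       "composite"),
                       parents = NULL, fractions = NULL, divergence = 0,
                       ancestry = "anc1", n_founders = 200L,
                       n_generations = 2L) {
  role <- match.arg(role)
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (role == "composite") {
    if (is.null(parents) || is.null(fractions) ||
        length(parents) != length(fractions))
      stop("composite needs matching parents and fractions")
    if (abs(sum(fractions) - 1) > 1e-12) stop("fractions must sum to 1")
    dyadic <- vapply(2^(0:4), function(den)
      all(abs(fractions * den - round(fractions * den)) < 1e-9), TRUE)
    if (!any(dyadic))
      stop("fractions must be dyadic with denominator <= 16")
  }
  structure(list(label = label, role = role, parents = parents,
                 fractions = fractions, divergence = divergence,
                 ancestry = ancestry, n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations)),
            class = "breed_spec")
}

#' Trait specification for the tick-resistance phenotype
#'
#' Per-breed heritabilities, cross-breed genetic correlations, optional
#' repeatabilities (breeds with repeated records), phenotype mode and
#' record design.  Per-breed phenotypic variance defaults to 1, so
#' heritabilities are variances directly.
#'
#' @param breeds breed labels (= traits).
#' @param h2 named per-breed heritabilities in (0, 1\].
#' @param rg t x t genetic correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite); a scalar is accepted for t = 2.
#' @param repeatability named repeatabilities for repeated-record breeds
#'   (`h2 <= repeatability < 1`); omit breeds without a PE term.
#' @param phen_var named per-breed phenotypic variances (default 1).
#' @param mode named per-breed phenotype mode: `"log-count"` (latent
#'   Gaussian on the log10(count+1) scale, emitted directly), `"score"`
#'   (back-transformed to a count and binned to the 0-5 scale) or
#'   `"averaged-count"` (records averaged to one value per animal).
#' @param n_records named per-breed records per animal.
#' @param mean named per-breed trait means on the latent scale.
#' @return Object of class `trait_spec`.
#' @export
trait_spec <- function(breeds, h2, rg = NULL, repeatability = NULL,
                       phen_var = NULL, mode = NULL, n_records = NULL,
                       mean = NULL) {
  t <- length(breeds)
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, t), breeds)
    if (!is.null(x)) {
      if (is.null(names(x))) { stopifnot(length(x) %in% c(1L, t)); out[] <- x }
      else out[names(x)] <- x
    }
    out
  }
  h2 <- fill(h2, NA_real_)
  if (any(!is.finite(h2)) || any(h2 < 0) || any(h2 > 1))
    stop("heritabilities must be in [0, 1]")
  if (is.null(rg)) rg <- diag(t)
  if (length(rg) == 1L && t == 2L) rg <- matrix(c(1, rg, rg, 1), 2)
  rg <- as.matrix(rg)
  if (!isTRUE(all.equal(rg, t(rg))) || any(abs(diag(rg) - 1) > 1e-12))
    stop("rg must be symmetric with unit diagonal")
  if (min(eigen(rg, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("rg is not positive semi-definite")
  dimnames(rg) <- list(breeds, breeds)
  if (!is.null(repeatability)) {
    if (is.null(names(repeatability))) stop("repeatability must be named")
    bad <- repeatability < h2[names(repeatability)] - 1e-12 |
      repeatability >= 1
    if (any(bad)) stop("need h2 <= repeatability < 1")
  }
  structure(list(breeds = breeds, h2 = h2, rg = rg,
                 repeatability = repeatability,
                 phen_var = fill(phen_var, 1),
                 mode = fill(mode, "log-count"),
                 n_records = fill(n_records, 1L),
                 mean = fill(mean, 1.5)),
            class = "trait_spec")
}

# variance components implied by a trait spec (truth bookkeeping)
trait_spec_components <- function(spec) {
  s2u <- spec$h2 * spec$phen_var
  s2p <- stats::setNames(rep(NA_real_, length(spec$breeds)), spec$breeds)
  if (!is.null(spec$repeatability))
    s2p[names(spec$repeatability)] <-
      (spec$repeatability - spec$h2[names(spec$repeatability)]) *
      spec$phen_var[names(spec$repeatability)]
  s2e <- spec$phen_var - s2u - ifelse(is.na(s2p), 0, s2p)
  Sigma_u <- sqrt(s2u %o% s2u) * spec$rg
  list(Sigma_u = Sigma_u, s2u = s2u, s2p = s2p, s2e = s2e)
}

# allele correlation achievable between two binary indicators through a
# Gaussian copula is bounded; these defaults put the adjacent-marker r^2
# regime around 0.3 with a wide spread (many near-zero, some near-complete
# pairs), the level seen on dense bovine panels.
ld_profile_default <- function() list(shape1 = 2, shape2 = 0.35, max = 0.995)

#' Simulate founder haplotypes for one or more breeds
#'
#' Per-breed allele frequencies are drawn from a common ancestral frequency
#' by a Balding-Nichols drift model, `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' `F` the breed's divergence.  Within-breed LD is induced by a signed
#' first-order Gaussian copula along each chromosome: every adjacent marker
#' interval carries a latent correlation (random sign, random magnitude)
#' drawn at the ancestral-pool level; breeds inherit their pool's interval
#' parameters, each redrawn independently with probability equal to the
#' breed's divergence, so LD phase is shared in proportion to shared
#' ancestry.  Haplotypes are independent draws given the breed parameters.
#'
#' @param n_markers total marker count (split evenly over chromosomes).
#' @param breed_specs list of [breed_spec()]s; only founder breeds receive
#'   haplotypes here.
#' @param seed integer seed.
#' @param n_chr number of chromosomes.
#' @param cm_spacing marker spacing in centimorgan (uniform map).
#' @param ld ld profile: Beta shape parameters and cap for the latent
#'   interval correlation magnitudes.
#' @return A phased [genotype_panel()] of all founder animals, markers
#'   ordered by (chromosome, position); attribute `breed_fracs` records the
#'   unit breed-fraction vector of each founder.
#' @export
simulate_founder_haplotypes <- function(n_markers, breed_specs, seed,
                                        n_chr = 5L, cm_spacing = 1,
                                        ld = ld_profile_default()) {
  if (n_markers < 2L) stop("need n_markers >= 2")
  if (inherits(breed_specs, "breed_spec")) breed_specs <- list(breed_specs)
  founders <- Filter(function(b) b$role != "composite", breed_specs)
  if (!length(founders)) stop("need at least one founder breed")
  seeds <- split_seed(seed, 2L + length(founders))
  per_chr <- rep(n_markers %/% n_chr, n_chr)
  per_chr[seq_len(n_markers %% n_chr)] <- per_chr[seq_len(n_markers %% n_chr)] + 1L
  chr <- rep(seq_len(n_chr), per_chr)
  cm <- unlist(lapply(per_chr, function(k) seq_len(k) * cm_spacing))
  map <- data.frame(chr = chr, id = sprintf("snp%06d", seq_len(n_markers)),
                    cm = cm, a1 = "A", a2 = "B")
  within <- diff(chr) == 0L # interval k couples markers k, k+1

  set.seed(seeds[1])
  pools <- unique(vapply(founders, `[[`, "", "ancestry"))
  anc <- lapply(pools, function(pl) {
    list(p = stats::runif(n_markers, 0.1, 0.9),
         sign = sample(c(-1, 1), n_markers - 1L, replace = TRUE),
         mag = pmin(stats::rbeta(n_markers - 1L, ld$shape1, ld$shape2), ld$max))
  })
  names(anc) <- pools

  hap_list <- list(); samp <- NULL
  for (k in seq_along(founders)) {
    b <- founders[[k]]
    set.seed(seeds[2L + k])
    a <- anc[[b$ancestry]]
    Fst <- b$divergence
    p <- if (Fst > 0) {
      stats::rbeta(n_markers, a$p * (1 - Fst) / Fst,
                   (1 - a$p) * (1 - Fst) / Fst)
    } else a$p
    p <- pmin(pmax(p, 0.005), 0.995)
    sgn <- a$sign; mag <- a$mag
    if (Fst > 0) {
      redo <- stats::runif(n_markers - 1L) < Fst
      sgn[redo] <- sample(c(-1, 1), sum(redo), replace = TRUE)
      mag[redo] <- pmin(stats::rbeta(sum(redo), ld$shape1, ld$shape2), ld$max)
    }
    cc <- ifelse(within, sgn * mag, 0)
    nh <- 2L * b$n_founders
    Z <- matrix(0, nh, n_markers)
    Z[, 1] <- stats::rnorm(nh)
    for (j in 2:n_markers)
      Z[, j] <- cc[j - 1L] * Z[, j - 1L] +
        sqrt(1 - cc[j - 1L]^2) * stats::rnorm(nh)
    H <- matrix(0L, nh, n_markers)
    H[Z < rep(stats::qnorm(p), each = nh)] <- 1L
    hap_list[[k]] <- H
    samp <- rbind(samp, data.frame(
      id = sprintf("%s_F%04d", b$label, seq_len(b$n_founders)),
      breed = b$label))
  }
  H <- do.call(rbind, hap_list)
  dos <- H[seq(1, nrow(H), 2), , drop = FALSE] +
    H[seq(2, nrow(H), 2), , drop = FALSE]
  panel <- genotype_panel(dos, map, samp, haplo = H)
  fr <- diag(length(founders))
  labs <- vapply(founders, `[[`, "", "label")
  dimnames(fr) <- list(labs, labs)
  attr(panel, "breed_fracs") <- fr[samp$breed, , drop = FALSE]
  rownames(attr(panel, "breed_fracs")) <- samp$id
  panel
}

# dyadic decomposition: split a target founder-fraction vector (integer
# numerators over 2^k) into two parent targets over 2^(k-1)
split_fracs <- function(num, den) {
  half <- den %/% 2L
  a <- pmax(num - half, 0L) # so that b = num - a stays within 0..half
  rem <- half - sum(a)
  for (i in seq_along(num)) {
    if (rem <= 0L) break
    give <- min(min(num[i], half) - a[i], rem)
    a[i] <- a[i] + give
    rem <- rem - give
  }
  list(a = as.integer(a), b = as.integer(num - a), den = half)
}

#' Simulate pedigree, descent and composite crossing
#'
#' Random-mating descent from the founder panel with recombination (one
#' expected crossover per Morgan, Haldane map), composite breeds formed by
#' the dyadic crossing ladder implied by their admixture fractions (e.g.
#' 3/8 zebu = (1/2 x 1/4) with 1/4 = (1/2 x 0)), and per-animal
#' pedigree-expected zebu fraction and heterozygosity coefficients from the
#' parental breed fractions.
#'
#' @param panel founder [genotype_panel()] from
#'   [simulate_founder_haplotypes()].
#' @param breed_specs list of [breed_spec()]s (founders and composites).
#' @param n_per_gen cohort size per breed per generation.
#' @param seed integer seed.
#' @return List: `pedigree` (id, sire, dam, birthdate, breed, sex, zebu,
#'   het, generation; topologically ordered) and `panel` extended to all
#'   simulated animals (phased).
#' @export
simulate_pedigree_and_crosses <- function(panel, breed_specs, n_per_gen = 150L,
                                          seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), panel$phased)
  if (inherits(breed_specs, "breed_spec")) breed_specs <- list(breed_specs)
  labs <- vapply(breed_specs, `[[`, "", "label")
  founders <- labs[vapply(breed_specs, `[[`, "", "role") != "composite"]
  for (b in breed_specs)
    if (b$role == "composite" && !all(b$parents %in% labs[seq_len(match(b$label, labs) - 1L)]))
      stop("composite '", b$label, "' references undefined breed(s)")
  indicine <- labs[vapply(breed_specs, `[[`, "", "role") == "founder-indicine"]
  set.seed(split_seed(seed, 1L))

  map <- panel$map
  d_cm <- diff(map$cm)
  rf <- ifelse(diff(map$chr) == 0L, 0.5 * (1 - exp(-2 * d_cm / 100)), 0.5)

  n0 <- nrow(panel$dosage)
  fr0 <- attr(panel, "breed_fracs")
  if (is.null(fr0)) {
    fr0 <- diag(length(founders))[match(panel$samples$breed, founders), ,
                                  drop = FALSE]
    colnames(fr0) <- founders
  }
  ped <- data.frame(id = panel$samples$id, sire = "0", dam = "0",
                    birthdate = as.Date("2000-01-01") +
                      sample.int(365L, n0, replace = TRUE) - 1L,
                    breed = panel$samples$breed,
                    sex = sample(c("M", "F"), n0, replace = TRUE),
                    zebu = as.numeric(fr0[, intersect(indicine, colnames(fr0)),
                                          drop = FALSE] %*%
                                        rep(1, length(intersect(indicine, colnames(fr0))))),
                    het = 0, generation = 0L)
  H <- panel$haplo
  fracs <- fr0
  rownames(fracs) <- ped$id
  counter <- 0L

  make_cohort <- function(sire_pool, dam_pool, n, breed, gen) {
    males <- sire_pool[ped$sex[match(sire_pool, ped$id)] == "M"]
    females <- dam_pool[ped$sex[match(dam_pool, ped$id)] == "F"]
    if (!length(males) || !length(females))
      stop("parent cohort lacks one sex; increase cohort sizes")
    sires <- sample(males, n, replace = TRUE)
    dams <- sample(females, n, replace = TRUE)
    ids <- sprintf("%s_G%d_%05d", breed, gen, counter + seq_len(n))
    counter <<- counter + n
    si <- match(sires, ped$id); di <- match(dams, ped$id)
    g1 <- .drop_gametes(H, si - 1L, rf)
    g2 <- .drop_gametes(H, di - 1L, rf)
    hh <- matrix(0L, 2L * n, ncol(H))
    hh[seq(1, 2 * n, 2), ] <- g1
    hh[seq(2, 2 * n, 2), ] <- g2
    H <<- rbind(H, hh)
    fs <- fracs[sires, , drop = FALSE]; fd <- fracs[dams, , drop = FALSE]
    fr <- (fs + fd) / 2
    rownames(fr) <- ids
    fracs <<- rbind(fracs, fr)
    zcols <- intersect(indicine, colnames(fr))
    ped <<- rbind(ped, data.frame(
      id = ids, sire = sires, dam = dams,
      birthdate = as.Date("2000-01-01") + 730L * gen +
        sample.int(365L, n, replace = TRUE) - 1L,
      breed = breed, sex = sample(c("M", "F"), n, replace = TRUE),
      zebu = as.numeric(fr[, zcols, drop = FALSE] %*% rep(1, length(zcols))),
      het = 1 - rowSums(fs * fd),
      generation = gen))
    ids
  }

  cohorts <- lapply(stats::setNames(founders, founders),
                    function(b) ped$id[ped$breed == b])
  gen_clock <- 1L
  for (b in breed_specs) {
    if (b$role != "composite") {
      cur <- cohorts[[b$label]]
      for (g in seq_len(b$n_generations)) {
        cur <- make_cohort(cur, cur, n_per_gen, b$label, gen_clock + g - 1L)
        cohorts[[b$label]] <- cur
      }
      next
    }
    # composite: build the dyadic crossing ladder bottom-up
    den <- 2L
    while (any(abs(b$fractions * den - round(b$fractions * den)) > 1e-9))
      den <- den * 2L
    target <- as.integer(round(b$fractions * den))
    ladder <- list()
    build <- function(num, den) {
      key <- paste(c(num, den), collapse = "/")
      if (!is.null(ladder[[key]])) return(ladder[[key]])
      if (any(num == den)) { # a pure parent breed
        out <- cohorts[[b$parents[which(num == den)]]]
      } else {
        sp <- split_fracs(num, den)
        p1 <- build(sp$a, sp$den)
        p2 <- build(sp$b, sp$den)
        gen_clock <<- gen_clock + 1L
        out <- make_cohort(p1, p2, n_per_gen, b$label, gen_clock)
      }
      ladder[[key]] <<- out
      out
    }
    cur <- build(target, den)
    for (g in seq_len(b$n_generations)) {
      gen_clock <- gen_clock + 1L
      cur <- make_cohort(cur, cur, n_per_gen, b$label, gen_clock)
    }
    cohorts[[b$label]] <- cur
  }
  dos <- H[seq(1, nrow(H), 2), , drop = FALSE] +
    H[seq(2, nrow(H), 2), , drop = FALSE]
  out_panel <- genotype_panel(dos, map,
                              data.frame(id = ped$id, breed = ped$breed),
                              haplo = H)
  attr(out_panel, "breed_fracs") <- fracs
  list(pedigree = ped, panel = out_panel)
}

#' Simulate true breeding values
#'
#' QTL mode (default): a random marker subset receives per-trait effects
#' drawn from a multivariate normal with the target genetic correlation;
#' per-animal breeding values are dosage-weighted effect sums, centered
#' within each trait's own breed and rescaled so the realized within-breed
#' genetic variance matches the trait specification.  Pedigree mode: a
#' multi-trait infinitesimal gene-drop down the pedigree (founders
#' `N(0, Sigma_u)`, offspring = parent average + Mendelian sampling with
#' inbreeding-adjusted variance), for studies whose fitted covariance is
#' the pedigree relationship matrix.
#'
#' @param panel [genotype_panel()] over all animals (QTL mode).
#' @param spec a [trait_spec()].
#' @param n_qtl number of QTL (QTL mode).
#' @param seed integer seed.
#' @param mode `"qtl"` or `"pedigree"`.
#' @param pedigree required for pedigree mode.
#' @param breeds_of named breed label per animal (defaults to panel sample
#'   breeds / pedigree breeds); the scaling reference of each trait is its
#'   own breed's cohort.
#' @return Matrix animals x traits of true breeding values; attribute
#'   `qtl` records the QTL marker ids (QTL mode).
#' @export
simulate_breeding_values <- function(panel = NULL, spec, n_qtl = 300L,
                                     seed = 1L, mode = c("qtl", "pedigree"),
                                     pedigree = NULL, breeds_of = NULL) {
  mode <- match.arg(mode)
  cmp <- trait_spec_components(spec)
  t <- length(spec$breeds)
  set.seed(split_seed(seed, 1L))
  if (mode == "pedigree") {
    if (is.null(pedigree)) stop("pedigree mode needs a pedigree")
    px <- ped_indices(pedigree)
    n <- length(px$ids)
    F <- .inbreeding_recursive(px$sire, px$dam)
    L <- t(chol(cmp$Sigma_u + 1e-12 * diag(t)))
    U <- matrix(0, n, t)
    for (i in seq_len(n)) {
      s <- px$sire[i]; d <- px$dam[i]
      base <- numeric(t); v <- 1
      if (s > 0L && d > 0L) { base <- 0.5 * (U[s, ] + U[d, ])
        v <- 0.5 - 0.25 * (F[s] + F[d]) }
      else if (s > 0L) { base <- 0.5 * U[s, ]; v <- 0.75 - 0.25 * F[s] }
      else if (d > 0L) { base <- 0.5 * U[d, ]; v <- 0.75 - 0.25 * F[d] }
      U[i, ] <- base + sqrt(v) * as.numeric(L %*% stats::rnorm(t))
    }
    dimnames(U) <- list(px$ids, spec$breeds)
    zero <- cmp$s2u == 0
    U[, zero] <- 0
    return(U)
  }
  stopifnot(inherits(panel, "genotype_panel"))
  m <- ncol(panel$dosage)
  if (n_qtl > m) stop("n_qtl exceeds the marker count")
  if (is.null(breeds_of)) breeds_of <- stats::setNames(panel$samples$breed,
                                                       panel$samples$id)
  qtl <- sort(sample.int(m, n_qtl))
  Rh <- chol(spec$rg + 1e-10 * diag(t))
  alpha <- matrix(stats::rnorm(n_qtl * t), n_qtl, t) %*% Rh
  U <- panel$dosage[, qtl, drop = FALSE] %*% alpha
  dimnames(U) <- list(panel$samples$id, spec$breeds)
  for (j in seq_len(t)) {
    b <- spec$breeds[j]
    own <- which(breeds_of[panel$samples$id] == b)
    if (!length(own)) own <- seq_len(nrow(U))
    mu <- mean(U[own, j])
    sdv <- stats::sd(U[own, j])
    s <- if (cmp$s2u[j] == 0) 0 else if (sdv > 0) sqrt(cmp$s2u[j]) / sdv else 0
    U[, j] <- (U[, j] - mu) * s
  }
  attr(U, "qtl") <- panel$map$id[qtl]
  attr(U, "effects") <- alpha
  U
}

#' Simulate tick phenotype records
#'
#' One record = contemporary-group effect + covariate terms (zebu fraction,
#' expected heterozygosity, age linear and quadratic) + breeding value +
#' permanent-environment deviation (repeated-record breeds) + residual, on
#' the latent log-count scale.  Mode `"log-count"` emits the latent value,
#' `"score"` back-transforms it to a count (`round(10^y - 1)` floored at 0)
#' and bins it with [bin_tick_score()], `"averaged-count"` averages each
#' animal's records to a single value.
#'
#' @param bv breeding-value matrix from [simulate_breeding_values()].
#' @param spec a [trait_spec()].
#' @param pedigree pedigree with breed, birthdate and (optionally) zebu and
#'   het columns; phenotyped animals default to the rows whose breed is a
#'   trait.
#' @param seed integer seed.
#' @param cg contemporary-group design: `n_groups` per breed and effect
#'   `sd`.
#' @param coefs covariate coefficients (age in days, centered internally).
#' @param animals optional character vector restricting which animals are
#'   phenotyped.
#' @return List: `records` (animal, breed, value, cg, zebu, het, age,
#'   record_date), `pe` (true PE deviations), `cg_effects`.
#' @export
simulate_phenotypes <- function(bv, spec, pedigree, seed = 1L,
                                cg = list(n_groups = 10L, sd = 0.3),
                                coefs = c(zebu = -0.3, het = -0.1,
                                          age = 0, age2 = 0),
                                animals = NULL) {
  cmp <- trait_spec_components(spec)
  set.seed(split_seed(seed, 1L))
  recs <- list(); pe_all <- c(); cg_all <- c()
  for (b in spec$breeds) {
    rows <- pedigree[pedigree$breed == b, , drop = FALSE]
    if (!is.null(animals)) rows <- rows[rows$id %in% animals, , drop = FALSE]
    if (!nrow(rows)) next
    miss <- setdiff(rows$id, rownames(bv))
    if (length(miss))
      stop("animal(s) without a breeding value: ",
           paste(utils::head(miss, 5), collapse = ", "))
    n <- nrow(rows)
    nr <- spec$n_records[b]
    s2p <- cmp$s2p[b]
    pe <- if (!is.na(s2p)) stats::rnorm(n, 0, sqrt(s2p)) else numeric(n)
    names(pe) <- rows$id
    pe_all <- c(pe_all, pe)
    cg_lab <- sprintf("%s_cg%02d", b,
                      sample.int(cg$n_groups, n * nr, replace = TRUE))
    cge <- stats::rnorm(cg$n_groups, 0, cg$sd)
    names(cge) <- sprintf("%s_cg%02d", b, seq_len(cg$n_groups))
    cg_all <- c(cg_all, cge)
    age <- sample(365:1460, n * nr, replace = TRUE)
    zf <- if ("zebu" %in% names(rows)) rep(rows$zebu, each = nr) else 0
    ht <- if ("het" %in% names(rows)) rep(rows$het, each = nr) else 0
    ac <- age - mean(age)
    y <- spec$mean[b] + cge[cg_lab] +
      coefs["zebu"] * zf + coefs["het"] * ht +
      coefs["age"] * ac + coefs["age2"] * ac^2 +
      rep(bv[rows$id, b], each = nr) + rep(pe, each = nr) +
      stats::rnorm(n * nr, 0, sqrt(cmp$s2e[b]))
    df <- data.frame(animal = rep(rows$id, each = nr), breed = b,
                     value = as.numeric(y), cg = cg_lab,
                     zebu = zf, het = ht, age = age,
                     record_date = rep(rows$birthdate, each = nr) + age)
    if (spec$mode[b] == "score") {
      df$value <- bin_tick_score(pmax(0, round(10^df$value - 1)))
    } else if (spec$mode[b] == "averaged-count") {
      agg <- stats::aggregate(df[c("value", "age")],
                              by = df[c("animal", "breed")], FUN = mean)
      agg$cg <- df$cg[match(agg$animal, df$animal)]
      agg$zebu <- df$zebu[match(agg$animal, df$animal)]
      agg$het <- df$het[match(agg$animal, df$animal)]
      agg$record_date <- df$record_date[match(agg$animal, df$animal)]
      df <- agg[c("animal", "breed", "value", "cg", "zebu", "het", "age",
                  "record_date")]
    }
    recs[[b]] <- df
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  list(records = out, pe = pe_all, cg_effects = cg_all)
}

#' Simulate a complete multi-breed study
#'
#' Runs the four generator stages (founder haplotypes, pedigree and
#' crosses, breeding values, phenotypes) under one seed, with complete
#' truth bookkeeping for validation against simulation truth.
#'
#' @param breed_specs list of [breed_spec()]s.
#' @param spec a [trait_spec()] over (a subset of) the breed labels.
#' @param n_markers marker count.
#' @param n_qtl QTL count (QTL mode).
#' @param n_per_gen cohort size per breed generation.
#' @param seed integer seed driving all stages (documented stream split).
#' @param bv_mode `"qtl"` or `"pedigree"` (see
#'   [simulate_breeding_values()]).
#' @param phenotype_generation restrict phenotyping to animals of
#'   generation >= this value (founders are generation 0); `NULL`
#'   phenotypes every animal of a phenotyped breed.
#' @param ... passed to [simulate_phenotypes()].
#' @return List of class `sim_output`: `panel`, `pedigree`, `phenotypes`,
#'   `true_bv`, `true_components` (a [covariance_components()]), `pe`,
#'   `seed`.
#' @export
simulate_population <- function(breed_specs, spec, n_markers = 1000L,
                                n_qtl = 300L, n_per_gen = 150L, seed = 1L,
                                bv_mode = c("qtl", "pedigree"),
                                phenotype_generation = 1L, ...) {
  bv_mode <- match.arg(bv_mode)
  seeds <- split_seed(seed, 4L)
  founder <- simulate_founder_haplotypes(n_markers, breed_specs, seeds[1])
  desc <- simulate_pedigree_and_crosses(founder, breed_specs, n_per_gen,
                                        seeds[2])
  bv <- simulate_breeding_values(desc$panel, spec, n_qtl, seeds[3],
                                 mode = bv_mode, pedigree = desc$pedigree)
  animals <- if (is.null(phenotype_generation)) NULL else
    desc$pedigree$id[desc$pedigree$generation >= phenotype_generation]
  ph <- simulate_phenotypes(bv, spec, desc$pedigree, seeds[4],
                            animals = animals, ...)
  cmp <- trait_spec_components(spec)
  pos <- cmp$Sigma_u
  if (any(diag(pos) == 0)) diag(pos)[diag(pos) == 0] <- 1e-8
  truth <- covariance_components(pos, s2e = pmax(cmp$s2e, 1e-8),
                                 s2p = cmp$s2p[!is.na(cmp$s2p)])
  structure(list(panel = desc$panel, pedigree = desc$pedigree,
                 phenotypes = ph$records, true_bv = bv,
                 true_components = truth, pe = ph$pe, seed = seed),
            class = "sim_output")
}
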