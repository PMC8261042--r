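small_chain <- function(cycles = 400L, burnin = 100L, thin = 3L, seed = 81) {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  gibbs_sample(sim$phenotypes, two_breed_spec(), Ainv,
               chain = list(cycles = cycles, burnin = burnin, thin = thin),
               seed = seed)
}

test_that("the Gibbs chain is reproducible and stores the contracted draw count", {
  ch1 <- small_chain()
  ch2 <- small_chain()
  expect_identical(ch1$draws, ch2$draws)
  expect_equal(nrow(ch1$draws), (400 - 100) / 3)
  expect_true(all(c("sigma_u[P1,P1]", "sigma_u[P1,P2]", "sigma2_p[P1]",
                    "sigma2_e[P2]") %in% ch1$params))
  expect_false("sigma2_p[P2]" %in% ch1$params) # P2 has no PE term
})

test_that("the chain is invariant to phenotype row order", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  cfg <- list(cycles = 200L, burnin = 50L, thin = 2L)
  ch1 <- gibbs_sample(sim$phenotypes, two_breed_spec(), Ainv, chain = cfg,
                      seed = 82)
  set.seed(99)
  shuf <- sim$phenotypes[sample(nrow(sim$phenotypes)), ]
  ch2 <- gibbs_sample(shuf, two_breed_spec(), Ainv, chain = cfg, seed = 82)
  expect_identical(ch1$draws, ch2$draws)
})

test_that("every stored draw yields admissible genetic parameters", {
  ch <- small_chain()
  der <- derive_parameters(ch)
  h2 <- der$draws[, grep("^h2", colnames(der$draws)), drop = FALSE]
  rg <- der$draws[, grep("^rg", colnames(der$draws)), drop = FALSE]
  rp <- der$draws[, "repeatability[P1]"]
  expect_true(all(h2 > 0 & h2 < 1))
  expect_true(all(rg >= -1 & rg <= 1))
  expect_true(all(rp > 0 & rp < 1))
  expect_true(all(rp >= h2[, "h2[P1]"] - 1e-12)) # bounds its trait's h2
})

test_that("a trait with zero records is rejected before sampling", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  only1 <- sim$phenotypes[sim$phenotypes$breed == "P1", ]
  expect_error(gibbs_sample(only1, two_breed_spec(), Ainv,
                            chain = list(cycles = 100, burnin = 10,
                                         thin = 1), seed = 1),
               "zero records")
})

test_that("posterior summaries match closed-form behaviour of known chains", {
  const <- matrix(5, 50, 1, dimnames = list(NULL, "c"))
  s <- posterior_summary(const)
  expect_equal(s$mean, 5)
  expect_equal(s$ts_se, 0)
  expect_equal(s$ess, 50)
  expect_equal(s$geweke_z, 0)
  expect_equal(posterior_summary(matrix(1:12, ncol = 1,
                                        dimnames = list(NULL, "m")))$mean,
               6.5)
  expect_error(posterior_summary(matrix(1:5, ncol = 1)), "10")
  set.seed(83)
  wn <- matrix(rnorm(4000), ncol = 1, dimnames = list(NULL, "wn"))
  expect_equal(posterior_summary(wn)$ess, 4000, tolerance = 0.2)
  # AR(1): ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.9
  n <- 20000
  ar <- matrix(as.numeric(arima.sim(list(ar = phi), n)), ncol = 1,
               dimnames = list(NULL, "ar"))
  expect_equal(posterior_summary(ar)$ess, n * (1 - phi) / (1 + phi),
               tolerance = 0.3)
})

test_that("derived parameters follow their defining ratios", {
  cmp <- covariance_components(
    matrix(c(0.3, 0.5 * sqrt(0.3 * 1), 0.5 * sqrt(0.3 * 1), 1), 2,
           dimnames = list(c("A", "B"), c("A", "B"))),
    s2e = c(A = 0.6, B = 1), s2p = c(A = 0.1))
  der <- derive_parameters(cmp)
  expect_equal(der$h2[["A"]], 0.3)
  expect_equal(der$h2[["B"]], 0.5)
  expect_equal(der$rg["A", "B"], 0.5)
  expect_equal(der$repeatability[["A"]], 0.4)
})

test_that("a heritability-free trait concentrates posterior h2 near zero", {
  bs <- breed_spec("N0", "founder-taurine", n_founders = 200,
                   n_generations = 3)
  ts <- trait_spec("N0", h2 = 0)
  sim <- simulate_population(list(bs), ts, n_markers = 40, n_qtl = 10,
                             n_per_gen = 500, seed = 84)
  Ainv <- build_A_inverse(sim$pedigree)
  ch <- gibbs_sample(sim$phenotypes, model_spec("N0", use_cg = TRUE), Ainv,
                     chain = list(cycles = 10000, burnin = 4000, thin = 5),
                     seed = 85)
  der <- derive_parameters(ch)
  h2 <- der$summary$mean[der$summary$param == "h2[N0]"]
  s2e <- colMeans(ch$draws)[["sigma2_e[N0]"]]
  # realized residual variance of this replicate, via the generator's truth
  seeds <- tickblup:::split_seed(84, 4)
  ph <- simulate_phenotypes(sim$true_bv, ts, sim$pedigree, seeds[4],
    animals = sim$pedigree$id[sim$pedigree$generation >= 1])
  realized <- var(ph$records$value - 1.5 - ph$cg_effects[ph$records$cg])
  expect_lt(h2, 0.08)
  expect_equal(s2e, realized, tolerance = 0.05)
})

test_that("exact-model two-breed truth is recovered by the sampler", {
  # breeding values drawn from N(0, Sigma (x) H) itself: a pure oracle for
  # the Gibbs machinery, free of generator-model mismatch
  bs <- list(breed_spec("R1", "founder-taurine", n_founders = 120,
                        n_generations = 2),
             breed_spec("R2", "founder-indicine", n_founders = 120,
                        n_generations = 2))
  ts <- trait_spec(c("R1", "R2"), h2 = c(R1 = 0.3, R2 = 0.4), rg = 0.8)
  sim <- simulate_population(bs, ts, n_markers = 400, n_qtl = 100,
                             n_per_gen = 350, seed = 86)
  ped <- sim$pedigree
  set.seed(87)
  gids <- sort(unlist(lapply(c("R1", "R2"), function(b)
    sample(intersect(sim$phenotypes$animal, ped$id[ped$breed == b]), 120))))
  Hinv <- build_H_inverse(build_A_inverse(ped), build_A(ped, subset = gids),
                          build_G(subset_panel(sim$panel, samples = gids)))
  H <- solve(as.matrix(Hinv$mat))
  Sig <- matrix(c(0.3, 0.8 * sqrt(0.12), 0.8 * sqrt(0.12), 0.4), 2)
  L <- t(chol(kronecker(H, Sig) + 1e-10 * diag(2 * nrow(H))))
  u <- matrix(L %*% rnorm(2 * nrow(H)), ncol = 2, byrow = TRUE,
              dimnames = list(Hinv$ids, c("R1", "R2")))
  rec <- sim$phenotypes
  rec$value <- 1.5 + u[cbind(rec$animal, rec$breed)] +
    rnorm(nrow(rec), 0, sqrt(ifelse(rec$breed == "R1", 0.7, 0.6)))
  ch <- gibbs_sample(rec, model_spec(c("R1", "R2"), use_cg = FALSE), Hinv,
                     chain = list(cycles = 8000, burnin = 2000, thin = 5),
                     seed = 88)
  m <- derive_parameters(ch)$summary
  est <- setNames(m$mean, m$param)
  expect_equal(est[["h2[R1]"]], 0.3, tolerance = 0.12)
  expect_equal(est[["h2[R2]"]], 0.4, tolerance = 0.12)
  expect_equal(est[["rg[R1,R2]"]], 0.8, tolerance = 0.2)
})
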