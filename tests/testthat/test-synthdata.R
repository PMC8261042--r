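test_that("breed and trait specifications enforce their invariants", {
  expect_error(breed_spec("X", divergence = 1), "divergence")
  expect_error(breed_spec("C", "composite", parents = c("A", "B"),
                          fractions = c(0.5, 0.4)), "sum to 1")
  expect_error(breed_spec("C", "composite", parents = c("A", "B"),
                          fractions = c(1 / 3, 2 / 3)), "dyadic")
  expect_error(trait_spec("X", h2 = 1.2), "0, 1")
  expect_error(trait_spec(c("A", "B"), h2 = 0.3,
                          rg = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
  expect_error(trait_spec("A", h2 = 0.5, repeatability = c(A = 0.4)),
               "repeatability")
  expect_error(simulate_founder_haplotypes(1, list(breed_spec("X")), 1),
               "n_markers")
})

test_that("founder simulation is seed-deterministic and frequency-calibrated", {
  bs <- list(breed_spec("D1", "founder-taurine", n_founders = 40))
  p1 <- simulate_founder_haplotypes(100, bs, seed = 7)
  p2 <- simulate_founder_haplotypes(100, bs, seed = 7)
  expect_identical(p1$haplo, p2$haplo)
  expect_identical(p1$dosage, p2$dosage)
  f <- allele_freqs(p1)
  expect_true(all(f > 0 & f < 1))
  expect_identical(order(p1$map$chr, p1$map$cm), seq_len(100L))
})

test_that("zero divergence from one pool shrinks breed frequency differences", {
  mk <- function(nf) {
    bs <- list(breed_spec("Z1", "founder-taurine", n_founders = nf),
               breed_spec("Z2", "founder-indicine", n_founders = nf))
    fr <- allele_freqs(simulate_founder_haplotypes(800, bs, seed = 8),
                       by_breed = TRUE)
    c(mean(abs(fr[, 1] - fr[, 2])), cor(fr[, 1], fr[, 2]))
  }
  small <- mk(50); big <- mk(800)
  expect_lt(big[1], small[1])
  expect_gt(big[2], 0.98)
})

test_that("realized Fst tracks the Balding-Nichols divergence parameter", {
  bs <- list(breed_spec("F1", "founder-taurine", divergence = 0.2,
                        n_founders = 500),
             breed_spec("F2", "founder-indicine", divergence = 0.2,
                        n_founders = 500))
  p <- simulate_founder_haplotypes(5000, bs, seed = 9)
  fr <- allele_freqs(p, by_breed = TRUE)
  fst <- hudson_fst(fr[, 1], fr[, 2], 1000, 1000)
  expect_equal(fst, 0.2, tolerance = 0.05)
})

test_that("composite crossing reaches the target admixture exactly", {
  bs <- list(breed_spec("TT", "founder-taurine", n_founders = 40,
                        n_generations = 1),
             breed_spec("II", "founder-indicine", n_founders = 40,
                        n_generations = 1),
             breed_spec("CC", "composite", parents = c("TT", "II"),
                        fractions = c(5 / 8, 3 / 8), n_generations = 1))
  fp <- simulate_founder_haplotypes(60, bs, seed = 10, n_chr = 2)
  d <- simulate_pedigree_and_crosses(fp, bs, n_per_gen = 40, seed = 11)
  ped <- d$pedigree
  cc <- ped[ped$breed == "CC", ]
  expect_equal(mean(cc$zebu[cc$generation == max(cc$generation)]), 0.375,
               tolerance = 1e-12)
  # F1 of two pure breeds has heterosis coefficient exactly 1
  sz <- ped$zebu[match(ped$sire, ped$id)]
  dz <- ped$zebu[match(ped$dam, ped$id)]
  f1 <- which(!is.na(sz) & !is.na(dz) & sz + dz == 1 &
                (sz == 0 | sz == 1))
  expect_true(length(f1) > 0 && all(ped$het[f1] == 1))
  # topological order and acyclicity by construction
  pos <- setNames(seq_len(nrow(ped)), ped$id)
  expect_true(all((ped$sire == "0" | pos[ped$sire] < pos[ped$id]) &
                    (ped$dam == "0" | pos[ped$dam] < pos[ped$id])))
  # descendants' dosages remain consistent with their haplotypes
  expect_identical(unname(d$panel$dosage),
                   unname(d$panel$haplo[seq(1, nrow(d$panel$haplo), 2), ] +
                            d$panel$haplo[seq(2, nrow(d$panel$haplo), 2), ]))
  expect_error(
    simulate_pedigree_and_crosses(fp, list(bs[[1]], breed_spec(
      "BAD", "composite", parents = c("TT", "NOPE"),
      fractions = c(0.5, 0.5))), n_per_gen = 20, seed = 1),
    "undefined")
})

test_that("breeding values honour zero-variance traits, clones and effect correlations", {
  ts0 <- trait_spec(c("A", "B"), h2 = c(A = 0, B = 0.4), rg = 0)
  d <- matrix(rbinom(40 * 60, 2, 0.5), 40, 60)
  d[2, ] <- d[1, ] # clones
  pan <- panel_from_dosage(d, breed = "A")
  pan$samples$breed <- rep(c("A", "B"), 20)
  pan <- genotype_panel(pan$dosage, pan$map, pan$samples)
  u <- simulate_breeding_values(pan, ts0, n_qtl = 30, seed = 12)
  expect_true(all(u[, "A"] == 0))
  expect_false(all(u[, "B"] == 0))
  ts <- trait_spec(c("A", "B"), h2 = c(A = 0.3, B = 0.4), rg = 0.8)
  u2 <- simulate_breeding_values(pan, ts, n_qtl = 30, seed = 13)
  expect_equal(u2[1, ], u2[2, ], tolerance = 1e-12, ignore_attr = TRUE)
  # drawn QTL effect pairs carry the target correlation
  ts1 <- trait_spec(c("A", "B"), h2 = c(A = 0.3, B = 0.4), rg = 0.8)
  big <- panel_from_dosage(matrix(rbinom(20 * 1200, 2, 0.5), 20, 1200),
                           breed = "A")
  big$samples$breed <- rep(c("A", "B"), 10)
  big <- genotype_panel(big$dosage, big$map, big$samples)
  u3 <- simulate_breeding_values(big, ts1, n_qtl = 1000, seed = 14)
  al <- attr(u3, "effects")
  expect_equal(cor(al[, 1], al[, 2]), 0.8, tolerance = 0.05)
  expect_error(simulate_breeding_values(pan, ts, n_qtl = 1e5, seed = 1),
               "exceeds")
})

test_that("clone breeding values are identical because they are genotype functions", {
  ts <- trait_spec(c("A", "B"), h2 = c(A = 0.3, B = 0.4), rg = 0.5)
  d <- matrix(rbinom(30 * 80, 2, 0.4), 30, 80)
  d[5, ] <- d[9, ]
  pan <- panel_from_dosage(d, breed = "A")
  pan$samples$breed <- rep(c("A", "B"), 15)
  pan <- genotype_panel(pan$dosage, pan$map, pan$samples)
  u <- simulate_breeding_values(pan, ts, n_qtl = 40, seed = 15)
  expect_equal(u[5, ], u[9, ], ignore_attr = TRUE)
})

test_that("noise-free phenotypes reproduce breeding values exactly", {
  ped <- data.frame(id = sprintf("n%02d", 1:20), sire = "0", dam = "0",
                    breed = "X",
                    birthdate = as.Date("2015-01-01") + 1:20)
  u <- matrix(rnorm(20), dimnames = list(ped$id, "X"))
  ts <- trait_spec("X", h2 = 1, mean = 0)
  ph <- simulate_phenotypes(u, ts, ped, seed = 16,
                            cg = list(n_groups = 2, sd = 0),
                            coefs = c(zebu = 0, het = 0, age = 0, age2 = 0))
  expect_equal(ph$records$value, unname(u[ph$records$animal, 1]),
               tolerance = 1e-12)
  ph2 <- simulate_phenotypes(u, ts, ped, seed = 16,
                             cg = list(n_groups = 2, sd = 0),
                             coefs = c(zebu = 0, het = 0, age = 0, age2 = 0))
  expect_identical(ph$records, ph2$records)
  expect_error(simulate_phenotypes(u[1:3, , drop = FALSE], ts, ped,
                                   seed = 1), "without a breeding value")
})

test_that("score mode emits 0-5 integers and averaged mode one record per animal", {
  ped <- data.frame(id = sprintf("q%02d", 1:30), sire = "0", dam = "0",
                    breed = "S", birthdate = as.Date("2015-01-01") + 1:30)
  u <- matrix(rnorm(30, 0, 0.4), dimnames = list(ped$id, "S"))
  ts <- trait_spec("S", h2 = 0.3, mode = "score", mean = 1.3)
  ph <- simulate_phenotypes(u, ts, ped, seed = 17)
  expect_true(all(ph$records$value %in% 0:5))
  tsa <- trait_spec("S", h2 = 0.3, repeatability = c(S = 0.5),
                    mode = "averaged-count", n_records = 4)
  pha <- simulate_phenotypes(u, tsa, ped, seed = 18)
  expect_equal(nrow(pha$records), 30L)
  expect_false(anyDuplicated(pha$records$animal) > 0)
})

test_that("repeated-record variance components are recovered by moments", {
  n <- 10000
  ped <- data.frame(id = sprintf("r%05d", 1:n), sire = "0", dam = "0",
                    breed = "M", birthdate = as.Date("2015-01-01"))
  set.seed(19)
  u <- matrix(rnorm(n, 0, sqrt(0.3)), dimnames = list(ped$id, "M"))
  ts <- trait_spec("M", h2 = 0.3, repeatability = c(M = 0.5), n_records = 2,
                   mean = 0)
  ph <- simulate_phenotypes(u, ts, ped, seed = 20,
                            cg = list(n_groups = 1, sd = 0),
                            coefs = c(zebu = 0, het = 0, age = 0, age2 = 0))
  v <- ph$records$value
  a <- ph$records$animal
  within <- tapply(v, a, function(x) diff(x)^2 / 2)
  s2e_hat <- mean(unlist(within))          # within-animal: residual only
  s2total <- var(v)
  expect_equal(s2e_hat, 0.5, tolerance = 0.05)        # 1 - repeatability
  expect_equal(s2total - s2e_hat, 0.5, tolerance = 0.05) # u + pe variance
})

test_that("parent-offspring regression recovers the specified heritability", {
  bs <- breed_spec("H1", "founder-taurine", n_founders = 600,
                   n_generations = 1)
  ts <- trait_spec("H1", h2 = 0.4)
  sim <- simulate_population(list(bs), ts, n_markers = 400, n_qtl = 400,
                             n_per_gen = 5000, seed = 21,
                             phenotype_generation = 0L,
                             cg = list(n_groups = 1, sd = 0),
                             coefs = c(zebu = 0, het = 0, age = 0, age2 = 0))
  ph <- sim$phenotypes
  y <- setNames(ph$value, ph$animal)
  ped <- sim$pedigree
  off <- ped[ped$generation == 1, ]
  mid <- (y[off$sire] + y[off$dam]) / 2
  slope <- coef(lm(y[off$id] ~ mid))[2]
  expect_equal(unname(slope), 0.4, tolerance = 0.05)
})
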