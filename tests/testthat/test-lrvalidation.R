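toy_phenos <- function(n = 9, breed = "T") {
  data.frame(animal = sprintf("v%02d", seq_len(n)), breed = breed,
             value = seq_len(n) / 10)
}

toy_ped <- function(n = 9) {
  data.frame(id = sprintf("v%02d", seq_len(n)), sire = "0", dam = "0",
             breed = "T",
             birthdate = as.Date("2010-01-01") + seq_len(n) * 30)
}

test_that("old-young partitions keep the oldest two thirds as reference", {
  part <- make_partition(toy_phenos(), toy_ped(), "old-young", "T")
  expect_equal(length(part$reference), 6L)
  expect_equal(part$validation_ids, sprintf("v%02d", 7:9))
  # 10 animals: floor(20/3) = 6 reference, 4 validation (ceiling third)
  part10 <- make_partition(toy_phenos(10), toy_ped(10), "old-young", "T")
  expect_equal(length(part10$validation_ids), 4L)
  expect_error(make_partition(toy_phenos(2), toy_ped(2), "old-young", "T"),
               ">= 3")
})

test_that("birth-date ties resolve deterministically by id", {
  ped <- toy_ped()
  ped$birthdate <- as.Date("2010-01-01") # all tied
  p1 <- make_partition(toy_phenos(), ped, "old-young", "T")
  p2 <- make_partition(toy_phenos()[sample(9), ], ped, "old-young", "T")
  expect_identical(p1$validation_ids, sprintf("v%02d", 7:9))
  expect_identical(sort(p2$validation_ids), p1$validation_ids)
})

test_that("other-pops masks every target-breed phenotype", {
  ph <- rbind(toy_phenos(6, "T"), toy_phenos(8, "U"))
  part <- make_partition(ph, strategy = "other-pops", target = "T")
  expect_equal(sum(ph$breed[part$reference] == "T"), 0L)
  expect_equal(sum(ph$breed[part$reference] == "U"), 8L)
  expect_setequal(part$validation_ids, sprintf("v%02d", 1:6))
})

test_that("genotype restriction and missing birth dates are honoured", {
  ped <- toy_ped()
  part <- make_partition(toy_phenos(), ped, "old-young", "T",
                         genotyped = sprintf("v%02d", 1:6))
  expect_equal(length(part$validation_ids), 2L)
  ped$birthdate[3] <- NA
  expect_error(make_partition(toy_phenos(), ped, "old-young", "T"), "v03")
})

test_that("LR statistics follow their covariance definitions", {
  ids <- paste0("x", 1:4)
  u <- setNames(c(1, 2, 3, 4), ids)
  expect_equal(lr_statistics(u, u, u, ids)$rho_wp, 1)
  expect_equal(lr_statistics(u, u, u, ids)$beta_wp, 1)
  half <- u / 2
  r2 <- lr_statistics(u, half, u, ids) # u_w = 2 u_p: over-dispersion
  expect_equal(r2$rho_wp, 1)
  expect_equal(r2$beta_wp, 2)
  uw <- setNames(c(1, 2, 3, 4), ids)
  up <- setNames(c(1.1, 1.9, 3.2, 3.8), ids)
  ys <- setNames(c(0.8, 2.2, 2.9, 4.1), ids)
  out <- lr_statistics(uw, up, ys, ids)
  expect_equal(out$rho_wp, cov(uw, up) / sqrt(var(uw) * var(up)))
  expect_equal(out$beta_wp, cov(uw, up) / var(up))
  expect_equal(out$predictive_ability, cor(ys, up))
  # degenerate partial predictions report NA, never a silent zero
  flat <- setNames(rep(1, 4), ids)
  expect_true(is.na(lr_statistics(uw, flat, ys, ids)$rho_wp))
})

test_that("accuracy against truth is a plain correlation with guards", {
  ids <- paste0("y", 1:50)
  set.seed(91)
  tru <- setNames(rnorm(50), ids)
  expect_equal(accuracy_from_truth(tru, tru, ids), 1)
  noise <- setNames(rnorm(50), ids)
  expect_equal(accuracy_from_truth(noise, tru, ids), cor(noise, tru))
  expect_lt(abs(accuracy_from_truth(noise, tru, ids)), 0.4)
  expect_warning(acc <- accuracy_from_truth(setNames(rep(1, 50), ids), tru,
                                            ids), "zero variance")
  expect_true(is.na(acc))
})

test_that("whole vs partial fits give near-unbiased dispersion on clean data", {
  bs <- breed_spec("L1", "founder-taurine", n_founders = 100,
                   n_generations = 3)
  ts <- trait_spec("L1", h2 = 0.3)
  sim <- simulate_population(list(bs), ts, n_markers = 30, n_qtl = 8,
                             n_per_gen = 250, seed = 92, bv_mode = "pedigree")
  Ainv <- build_A_inverse(sim$pedigree)
  out <- lr_validate(sim$phenotypes, model_spec("L1", use_cg = TRUE),
                     sim$true_components, Ainv, sim$pedigree, "L1",
                     "old-young", true_bv = sim$true_bv)
  expect_gt(out$rho_wp, 0.3)
  expect_gt(out$beta_wp, 0.6)
  expect_lt(out$beta_wp, 1.4)
  expect_true(out$acc_w >= out$acc_p - 0.05) # whole data cannot lose accuracy
})

test_that("a correlated large breed lifts multi-trait over univariate prediction", {
  bs <- list(breed_spec("S", "founder-taurine", n_founders = 120,
                        n_generations = 2),
             breed_spec("Bg", "founder-taurine", n_founders = 120,
                        n_generations = 2))
  ts <- trait_spec(c("S", "Bg"), h2 = c(S = 0.3, Bg = 0.3), rg = 0.9)
  deltas <- sapply(1:3, function(k) {
    sim <- simulate_population(bs, ts, n_markers = 500, n_qtl = 500,
                               n_per_gen = 240, seed = 930 + k)
    ped <- sim$pedigree
    # small target cohort: keep few S phenotypes, all of the big breed
    ph <- sim$phenotypes
    set.seed(940 + k)
    keepS <- sample(ph$animal[ph$breed == "S"], 60)
    ph <- ph[ph$breed == "Bg" | ph$animal %in% keepS, ]
    gids <- sort(c(keepS, sample(ph$animal[ph$breed == "Bg"], 120)))
    Hinv <- build_H_inverse(build_A_inverse(ped),
                            build_A(ped, subset = gids),
                            build_G(subset_panel(sim$panel, samples = gids)))
    spec <- model_spec(c("S", "Bg"), use_cg = TRUE)
    multi <- lr_validate(ph, spec, sim$true_components, Hinv, ped, "S",
                         "old-young", genotyped = gids)
    uni <- lr_validate(ph, spec, sim$true_components, Hinv, ped, "S",
                       "old-young", genotyped = gids, univariate = TRUE)
    multi$rho_wp - uni$rho_wp
  })
  expect_gt(mean(deltas), -0.02)
})
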