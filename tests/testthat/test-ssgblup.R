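test_that("the assembled system solves the scalar animal model in closed form", {
  ped <- data.frame(id = "a1", sire = "0", dam = "0", breed = "X")
  Ainv <- build_A_inverse(ped)
  rec <- data.frame(animal = "a1", breed = "X", value = 3)
  comps <- covariance_components(matrix(1, dimnames = list("X", "X")),
                                 s2e = c(X = 2))
  sys <- assemble_mme(rec, model_spec("X", use_cg = FALSE), comps, Ainv)
  sol <- solve_mme(sys)
  # dense normal equations for (mu, u): [[.5,.5],[.5,1.5]] x = (1.5,1.5)
  xh <- solve(matrix(c(.5, .5, .5, 1.5), 2), c(1.5, 1.5))
  expect_lt(max(abs(sol$x - xh)), 1e-8)
  expect_equal(extract_ebv(sol, sys)["a1", "X"], xh[2], tolerance = 1e-8)
})

test_that("zero right-hand side gives identically zero solutions", {
  ped <- random_pedigree(12, seed = 71)
  Ainv <- build_A_inverse(ped)
  rec <- data.frame(animal = ped$id[5:12], breed = "X", value = 0)
  comps <- covariance_components(matrix(0.3, dimnames = list("X", "X")),
                                 s2e = c(X = 0.7))
  sol <- solve_mme(assemble_mme(rec, model_spec("X", use_cg = FALSE),
                                comps, Ainv))
  expect_equal(sol$x, rep(0, length(sol$x)))
  expect_equal(sol$iterations, 0L)
})

test_that("PCG solutions match a dense solve on a random multi-trait system", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  sys <- assemble_mme(sim$phenotypes, two_breed_spec(),
                      sim$true_components, Ainv)
  sol <- solve_mme(sys, tol = 1e-11)
  xd <- solve(as.matrix(sys$C), sys$rhs)
  expect_lt(max(abs(sol$x - xd)), 1e-6)
  expect_error(solve_mme(sys, tol = 1e-14, max_iter = 2L), "residuals")
})

test_that("zero genetic correlation reduces the multi-trait run to univariate runs", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  spec <- two_breed_spec()
  cmp0 <- sim$true_components
  Sig <- cmp0$Sigma_u; Sig[1, 2] <- Sig[2, 1] <- 0
  comps <- covariance_components(Sig, s2e = cmp0$s2e, s2p = cmp0$s2p)
  multi <- solve_mme(assemble_mme(sim$phenotypes, spec, comps, Ainv),
                     tol = 1e-11)
  sys <- assemble_mme(sim$phenotypes, spec, comps, Ainv)
  ebv <- extract_ebv(multi, sys)
  for (b in c("P1", "P2")) {
    uni <- predict_univariate(sim$phenotypes, spec, comps, Ainv, b,
                              tol = 1e-11)
    expect_lt(max(abs(ebv[, b] - extract_ebv(uni$solution, uni$sys)[, b])),
              1e-6)
  }
})

test_that("G = A22 blending reduces ssGBLUP to pedigree BLUP", {
  sim <- two_breed_sim()
  ped <- sim$pedigree
  Ainv <- build_A_inverse(ped)
  set.seed(72)
  gids <- sort(sample(ped$id[ped$generation >= 1], 30))
  A22 <- build_A(ped, subset = gids)
  Hinv <- build_H_inverse(Ainv, A22, relmat(as.matrix(A22$mat), gids, "G"))
  spec <- two_breed_spec()
  s1 <- solve_mme(assemble_mme(sim$phenotypes, spec, sim$true_components,
                               Ainv), tol = 1e-11)
  s2 <- solve_mme(assemble_mme(sim$phenotypes, spec, sim$true_components,
                               Hinv), tol = 1e-11)
  expect_lt(max(abs(s1$x - s2$x)), 1e-6)
})

test_that("pedigree BLUP equals a dense GLS oracle when no animals are genotyped", {
  ped <- random_pedigree(25, seed = 73)
  set.seed(74)
  rec_anim <- ped$id[10:25]
  rec <- data.frame(animal = rec_anim, breed = "X",
                    value = rnorm(length(rec_anim), 2))
  s2u <- 0.4; s2e <- 0.6
  comps <- covariance_components(matrix(s2u, dimnames = list("X", "X")),
                                 s2e = c(X = s2e))
  Ainv <- build_A_inverse(ped)
  sys <- assemble_mme(rec, model_spec("X", use_cg = FALSE), comps, Ainv)
  sol <- solve_mme(sys, tol = 1e-12)
  # GLS: V = Z A Z' s2u + I s2e; beta = (X'V-1X)-1 X'V-1 y; u = s2u A Z' V-1 e
  A <- as.matrix(build_A(ped)$mat)
  Z <- matrix(0, nrow(rec), nrow(ped))
  Z[cbind(seq_len(nrow(rec)), match(rec$animal, ped$id))] <- 1
  V <- Z %*% A %*% t(Z) * s2u + diag(nrow(rec)) * s2e
  X <- matrix(1, nrow(rec))
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, rec$value))
  u <- s2u * A %*% t(Z) %*% solve(V, rec$value - X %*% beta)
  expect_lt(abs(sol$x[1] - beta[1]), 1e-7)
  expect_lt(max(abs(extract_ebv(sol, sys)[ped$id, "X"] - u)), 1e-7)
  # animals with no records and no links to recorded animals predict zero
  lone <- setdiff(ped$id[ped$sire == "0" & ped$dam == "0"], rec$animal)
  kin <- A[lone, rec$animal, drop = FALSE]
  isolated <- lone[rowSums(abs(kin)) == 0]
  if (length(isolated))
    expect_equal(unname(extract_ebv(sol, sys)[isolated, "X"]),
                 rep(0, length(isolated)), tolerance = 1e-9)
})

test_that("near-zero genetic variance shrinks all breeding values to zero", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  Sig <- diag(c(1e-8, 1e-8)); dimnames(Sig) <- list(c("P1", "P2"),
                                                    c("P1", "P2"))
  comps <- covariance_components(Sig, s2e = sim$true_components$s2e,
                                 s2p = sim$true_components$s2p)
  sys <- assemble_mme(sim$phenotypes, two_breed_spec(), comps, Ainv)
  sol <- solve_mme(sys)
  expect_lt(max(abs(extract_ebv(sol, sys))), 1e-4)
})

test_that("solutions are invariant to trait ordering up to relabeling", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  cmp <- sim$true_components
  s12 <- solve_mme(assemble_mme(sim$phenotypes, two_breed_spec(), cmp, Ainv),
                   tol = 1e-11)
  sys12 <- assemble_mme(sim$phenotypes, two_breed_spec(), cmp, Ainv)
  spec21 <- model_spec(c("P2", "P1"), use_cg = TRUE, pe_traits = "P1")
  ord <- c("P2", "P1")
  cmp21 <- covariance_components(cmp$Sigma_u[ord, ord], s2e = cmp$s2e[ord],
                                 s2p = cmp$s2p)
  sys21 <- assemble_mme(sim$phenotypes, spec21, cmp21, Ainv)
  s21 <- solve_mme(sys21, tol = 1e-11)
  e12 <- extract_ebv(s12, sys12)
  e21 <- extract_ebv(s21, sys21)
  expect_lt(max(abs(e12[, c("P1", "P2")] - e21[, c("P1", "P2")])), 1e-6)
})

test_that("records referencing unknown breeds or animals are rejected", {
  sim <- two_breed_sim()
  Ainv <- build_A_inverse(sim$pedigree)
  bad <- sim$phenotypes
  bad$breed[1] <- "ZZ"
  expect_error(assemble_mme(bad, two_breed_spec(), sim$true_components, Ainv),
               "ZZ")
  bad2 <- sim$phenotypes
  bad2$animal[1] <- "ghost"
  expect_error(assemble_mme(bad2, two_breed_spec(), sim$true_components,
                            Ainv), "ghost")
})
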