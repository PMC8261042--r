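test_that("tabular A reproduces hand-computed relationships and inbreeding", {
  ped <- data.frame(id = c("s", "d", "o"), sire = c("0", "0", "s"),
                    dam = c("0", "0", "d"))
  A <- build_A(ped)
  expect_equal(diag(A$mat), rep(1, 3), ignore_attr = TRUE)
  expect_equal(A$mat["o", "s"], 0.5)
  expect_equal(A$mat["o", "d"], 0.5)
  # offspring of full sibs: F = 0.25, diagonal 1.25
  ped2 <- data.frame(id = c("s", "d", "a", "b", "x"),
                     sire = c("0", "0", "s", "s", "a"),
                     dam = c("0", "0", "d", "d", "b"))
  A2 <- build_A(ped2)
  expect_equal(A2$mat["x", "x"], 1.25)
  expect_equal(build_A(ped2, subset = c("a", "x"))$mat["a", "x"],
               A2$mat["a", "x"])
  expect_error(build_A(ped2, subset = "zz"), "zz")
})

test_that("Henderson A-inverse with inbreeding equals the dense inverse of A", {
  for (k in 1:20) {
    ped <- random_pedigree(sample(10:60, 1), seed = 600 + k)
    A <- as.matrix(build_A(ped)$mat)
    Ainv <- as.matrix(build_A_inverse(ped)$mat)
    expect_lt(max(abs(Ainv - solve(A))), 1e-8)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("VanRaden G handles clones, the two-sample anchor and HWE scaling", {
  pan <- panel_from_dosage(matrix(c(0L, 2L), 2, 1))
  G <- build_G(pan, "pooled")
  expect_equal(as.matrix(G$mat), matrix(c(2, -2, -2, 2), 2),
               ignore_attr = TRUE)
  set.seed(61)
  d <- sapply(runif(4000, 0.1, 0.9), function(p) rbinom(120, 2, p))
  d[2, ] <- d[1, ] # clone
  pan2 <- panel_from_dosage(d)
  G2 <- as.matrix(build_G(pan2, "pooled")$mat)
  expect_equal(G2[1, 1], G2[2, 2])
  expect_equal(G2[1, 1], G2[1, 2])
  expect_equal(mean(diag(G2)), 1, tolerance = 0.02)
  expect_error(build_G(panel_from_dosage(matrix(2L, 3, 2))), "fixed")
})

test_that("G is invariant to marker order and conformable under sample permutation", {
  set.seed(62)
  d <- sapply(runif(50, 0.2, 0.8), function(p) rbinom(30, 2, p))
  G <- as.matrix(build_G(panel_from_dosage(d), "pooled")$mat)
  mp <- sample(50)
  G2 <- as.matrix(build_G(panel_from_dosage(d[, mp]), "pooled")$mat)
  expect_equal(G, G2, tolerance = 1e-12)
  sp <- sample(30)
  G3 <- as.matrix(build_G(panel_from_dosage(d[sp, ]), "pooled")$mat)
  expect_equal(G3, G[sp, sp], ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mean-of-breed and pooled frequency policies differ as documented", {
  set.seed(63)
  d <- rbind(sapply(runif(80, 0.5, 0.9), function(p) rbinom(20, 2, p)),
             sapply(runif(80, 0.1, 0.5), function(p) rbinom(5, 2, p)))
  pan <- genotype_panel(d, data.frame(chr = 1L, id = sprintf("m%02d", 1:80),
                                      cm = 1:80),
                        data.frame(id = sprintf("s%02d", 1:25),
                                   breed = rep(c("A", "B"), c(20, 5))))
  Gm <- build_G(pan, "mean_of_breeds")
  Gp <- build_G(pan, "pooled")
  expect_equal(Gm$meta$freq_policy, "mean_of_breeds")
  fb <- allele_freqs(pan, by_breed = TRUE)
  expect_equal(Gm$meta$freqs, rowMeans(fb), ignore_attr = TRUE)
  expect_gt(max(abs(as.matrix(Gm$mat) - as.matrix(Gp$mat))), 1e-6)
})

test_that("H-inverse satisfies the blend identity and the assembled-H oracle", {
  sim <- two_breed_sim()
  ped <- sim$pedigree
  Ainv <- build_A_inverse(ped)
  set.seed(64)
  gids <- sort(sample(ped$id[ped$generation >= 1], 25))
  A22 <- build_A(ped, subset = gids)
  # G = A22 -> correction block vanishes
  H0 <- build_H_inverse(Ainv, A22, relmat(as.matrix(A22$mat), gids, "G"))
  expect_lt(max(abs(H0$mat - Ainv$mat)), 1e-8)
  # explicit-H assembly (joint-distribution form) + dense inversion
  G <- build_G(subset_panel(sim$panel, samples = gids))
  Hinv <- build_H_inverse(Ainv, A22, G)
  Af <- as.matrix(build_A(ped)$mat)
  gi <- match(gids, Ainv$ids); ni <- setdiff(seq_along(Ainv$ids), gi)
  Gt <- 0.95 * as.matrix(G$mat) + 0.05 * as.matrix(A22$mat)
  A22i <- solve(Af[gi, gi])
  H <- Af
  H[ni, ni] <- Af[ni, ni] +
    Af[ni, gi] %*% A22i %*% (Gt - Af[gi, gi]) %*% A22i %*% Af[gi, ni]
  H[ni, gi] <- Af[ni, gi] %*% A22i %*% Gt
  H[gi, ni] <- t(H[ni, gi])
  H[gi, gi] <- Gt
  expect_lt(max(abs(as.matrix(Hinv$mat) - solve(H))), 1e-6)
  expect_error(build_H_inverse(Ainv, A22, G, blend = c(0.9, 0.05)), "sum to 1")
})

test_that("relationship matrices round-trip through the triplet writer", {
  ped <- random_pedigree(15, seed = 65)
  Ainv <- build_A_inverse(ped)
  path <- tempfile(fileext = ".csv")
  write_relmat(Ainv, path)
  tri <- read.csv(path)
  ids <- readLines(paste0(path, ".ids"))
  M <- matrix(0, length(ids), length(ids))
  M[cbind(tri$i, tri$j)] <- tri$value
  M[cbind(tri$j, tri$i)] <- tri$value
  expect_equal(M, as.matrix(Ainv$mat), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(ids, Ainv$ids)
})
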