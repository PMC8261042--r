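# shared fixtures, built in code and memoised across tests in a file run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixtures)) assign(key, force(expr), .fixtures)
  get(key, .fixtures)
}

# small two-breed population with repeated records for one breed
two_breed_sim <- function() memo("two_breed_sim", {
  bs <- list(breed_spec("P1", "founder-taurine", n_founders = 60,
                        n_generations = 2),
             breed_spec("P2", "founder-indicine", divergence = 0.15,
                        n_founders = 60, n_generations = 2))
  ts <- trait_spec(c("P1", "P2"), h2 = c(P1 = 0.3, P2 = 0.4), rg = 0.5,
                   repeatability = c(P1 = 0.45), n_records = c(P1 = 2, P2 = 1))
  simulate_population(bs, ts, n_markers = 300, n_qtl = 120, n_per_gen = 80,
                      seed = 1201)
})

two_breed_spec <- function() model_spec(c("P1", "P2"), use_cg = TRUE,
                                        pe_traits = "P1")

# random valid pedigree: founders then random matings, topologically ordered
random_pedigree <- function(n, n_founders = max(3L, n %/% 4L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  for (i in (n_founders + 1L):n) {
    prev <- seq_len(i - 1L)
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (length(males) && stats::runif(1) < 0.9)
      sire[i] <- id[if (length(males) == 1L) males else sample(males, 1L)]
    if (length(females) && stats::runif(1) < 0.9)
      dam[i] <- id[if (length(females) == 1L) females else sample(females, 1L)]
  }
  data.frame(id = id, sire = sire, dam = dam, breed = "X",
             birthdate = as.Date("2000-01-01") + seq_len(n))
}

# panel built directly from a dosage matrix (markers on one chromosome)
panel_from_dosage <- function(d, breed = "X", chr = NULL) {
  m <- ncol(d)
  map <- data.frame(chr = if (is.null(chr)) rep(1L, m) else chr,
                    id = sprintf("m%04d", seq_len(m)), cm = seq_len(m))
  map <- map[order(map$chr, map$cm), ]
  map$cm <- stats::ave(map$cm, map$chr, FUN = seq_along)
  genotype_panel(d, map,
                 data.frame(id = sprintf("s%03d", seq_len(nrow(d))),
                            breed = breed))
}

# panel from explicit haplotypes (2n x m)
panel_from_haplo <- function(H, breed = "X", chr = NULL) {
  d <- H[seq(1, nrow(H), 2), , drop = FALSE] +
    H[seq(2, nrow(H), 2), , drop = FALSE]
  p <- panel_from_dosage(d, breed, chr)
  genotype_panel(p$dosage, p$map, p$samples, haplo = H)
}

hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num) / mean(den)
}
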