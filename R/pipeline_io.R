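#' Write a genotype panel as PLINK bed/bim/fam
#'
#' SNP-major bed with the standard magic bytes; the breed label is stored
#' in the family-id column of the fam file, which is the usual convention
#' for multi-population panels and saves a side table.  Dosages count the
#' `a1` allele (bed code 00 = hom a1, 10 = het, 11 = hom a2, 01 = missing).
#'
#' @param panel a [genotype_panel()].
#' @param prefix path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return The prefix, invisibly.
#' @export
write_genotypes <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosage
  n <- nrow(d); m <- ncol(d)
  code <- matrix(1L, n, m) # 01 = missing
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  pad <- (4L - n %% 4L) %% 4L
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  dim(code) <- c(4L, (n + pad) / 4L * m)
  bytes <- code[1, ] + 4L * code[2, ] + 16L * code[3, ] + 64L * code[4, ]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, bytes)), con)
  map <- panel$map
  bim <- data.frame(chr = map$chr, id = map$id, cm = map$cm,
                    bp = if ("bp" %in% names(map)) map$bp
                         else round(map$cm * 1e6),
                    a1 = if ("a1" %in% names(map)) map$a1 else "A",
                    a2 = if ("a2" %in% names(map)) map$a2 else "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$samples$breed, iid = panel$samples$id,
                    father = 0, mother = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triple
#'
#' @param prefix path prefix of the `.bed/.bim/.fam` files.
#' @return An unphased [genotype_panel()] (breed = family id).
#' @export
load_genotypes <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing file: ", f)
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "father", "mother",
                                         "sex", "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "character", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("bad PLINK bed magic bytes in ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed supported: ", bed)
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * m)
    stop("bed payload is ", length(raw) - 3L, " bytes but bim/fam imply ",
         bpm * m, " (", m, " markers x ", bpm, " bytes)")
  bytes <- as.integer(raw[-(1:3)])
  codes <- rbind(bytes %% 4L, (bytes %/% 4L) %% 4L,
                 (bytes %/% 16L) %% 4L, bytes %/% 64L)
  dim(codes) <- c(4L * bpm, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  d <- matrix(NA_integer_, n, m)
  d[codes == 0L] <- 2L
  d[codes == 2L] <- 1L
  d[codes == 3L] <- 0L
  genotype_panel(d, bim[c("chr", "id", "cm", "bp", "a1", "a2")],
                 data.frame(id = fam$iid, breed = fam$fid))
}

#' Read and topologically order a pedigree CSV
#'
#' Expects columns id, sire, dam, birthdate (ISO-8601), breed; unknown
#' parents coded 0 or empty.  Parents that are referenced but not listed
#' are added as unknown-parent founders; cycles are rejected with the
#' offending chain printed.
#'
#' @param path CSV path, or a data frame already in memory.
#' @return Topologically sorted pedigree data frame.
#' @export
load_pedigree <- function(path) {
  ped <- if (is.data.frame(path)) path else
    utils::read.csv(path, colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs columns id, sire, dam")
  ped$sire[is.na(ped$sire) | ped$sire == ""] <- "0"
  ped$dam[is.na(ped$dam) | ped$dam == ""] <- "0"
  if (anyDuplicated(ped$id)) stop("duplicated pedigree id(s)")
  parents <- setdiff(unique(c(ped$sire, ped$dam)), c("0", ped$id))
  if (length(parents)) {
    extra <- ped[rep(1L, length(parents)), , drop = FALSE]
    extra[] <- NA
    extra$id <- parents
    extra$sire <- "0"; extra$dam <- "0"
    if ("breed" %in% names(ped)) extra$breed <- "unknown"
    ped <- rbind(extra, ped)
  }
  if ("birthdate" %in% names(ped)) ped$birthdate <- as.Date(ped$birthdate)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  depth <- rep(NA_integer_, n)
  depth[si == 0L & di == 0L] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    prog <- FALSE
    for (i in todo) {
      ds <- if (si[i] == 0L) -1L else depth[si[i]]
      dd <- if (di[i] == 0L) -1L else depth[di[i]]
      if (!anyNA(c(ds, dd))) { depth[i] <- max(ds, dd) + 1L; prog <- TRUE }
    }
    if (!prog) {
      chain <- ped$id[utils::head(todo, 10)]
      stop("pedigree cycle involving: ", paste(chain, collapse = " -> "))
    }
  }
  ped <- ped[order(depth, seq_len(n)), , drop = FALSE]
  rownames(ped) <- NULL
  ped
}

#' Write a pedigree CSV
#'
#' @param pedigree pedigree data frame.
#' @param path output path (id, sire, dam, birthdate ISO-8601, breed).
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  cols <- intersect(c("id", "sire", "dam", "birthdate", "breed"),
                    names(pedigree))
  utils::write.csv(pedigree[cols], path, row.names = FALSE)
  invisible(path)
}

config_schema <- function() list(
  seed = NULL,
  stages = NULL,
  simulate = c("n_markers", "n_qtl", "n_per_gen", "bv_mode", "n_chr",
               "breeds", "traits", "cg", "phenotype_generation"),
  phenotypes = c("cg_columns", "covariates", "min_cg_size", "sd_limit"),
  qc = c("sample_cr_min", "het_sd_window", "snp_cr_min", "maf_min",
         "hwe_p_floor", "dup_r_max", "autosomes", "window"),
  popgen = c("use_phase", "n_components"),
  kinship = c("freq_policy", "blend", "genotyped_fraction"),
  model = c("use_cg", "covariates", "pe_traits"),
  mcmc = c("cycles", "burnin", "thin"),
  validate = c("strategies", "breeds"),
  paths = c("genotypes", "pedigree", "phenotypes"))

#' Load and validate a run configuration
#'
#' YAML with one block per stage; unknown keys are rejected (typo guard).
#'
#' @param path YAML file path, or an equivalent list.
#' @return The validated config list with a `seed` default of 1.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in names(cfg)) {
    if (is.null(schema[[blk]]) || !is.list(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(bad))
      stop("unknown key(s) in `", blk, "`: ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$stages))
    cfg$stages <- c("simulate", "qc", "popgen", "kinship", "varcomp",
                    "blup", "validate")
  cfg
}

specs_from_config <- function(sim) {
  breeds <- lapply(sim$breeds, function(b)
    do.call(breed_spec, b[intersect(names(b),
      names(formals(breed_spec)))]))
  tr <- sim$traits
  spec <- trait_spec(breeds = unlist(tr$breeds),
                     h2 = unlist(tr$h2), rg = if (!is.null(tr$rg))
                       do.call(rbind, tr$rg) else NULL,
                     repeatability = unlist(tr$repeatability),
                     mode = unlist(tr$mode),
                     n_records = unlist(tr$n_records),
                     mean = unlist(tr$mean))
  list(breeds = breeds, traits = spec)
}

write_manifest <- function(outdir, stage, params, seed, inputs, outputs) {
  mf <- list(stage = stage, seed = seed,
             package = as.character(utils::packageVersion("tickblup")),
             params = params,
             inputs = as.list(stats::setNames(tools::md5sum(inputs),
                                              basename(inputs))),
             outputs = as.list(stats::setNames(tools::md5sum(outputs),
                                               basename(outputs))))
  path <- file.path(outdir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(mf, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the evaluation pipeline
#'
#' Executes the enabled stages in dependency order (simulate, qc, popgen,
#' kinship, varcomp, blup, validate), writing each stage's outputs plus a
#' manifest (parameter values, input/output hashes, seed) into `outdir`.
#' Reruns with an identical config and seed reproduce all stochastic
#' stages bit-identically.
#'
#' @param config a [load_run_config()] list or YAML path.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  cfg <- load_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  say <- function(...) if (!quiet) message("[tickblup] ", ...)
  st <- cfg$stages
  env <- new.env()

  run_stage <- function(stage, fn) {
    if (!stage %in% st) return(invisible(NULL))
    say("stage: ", stage)
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  run_stage("simulate", function() {
    sim <- cfg$simulate
    sp <- specs_from_config(sim)
    env$sim <- do.call(simulate_population, c(
      list(breed_specs = sp$breeds, spec = sp$traits, seed = seed),
      sim[intersect(names(sim), c("n_markers", "n_qtl", "n_per_gen",
                                  "bv_mode", "phenotype_generation"))],
      if (!is.null(sim$cg)) list(cg = sim$cg)))
    env$spec <- sp$traits
    out <- file.path(outdir, "simulated")
    write_genotypes(env$sim$panel, out)
    write_pedigree(env$sim$pedigree, file.path(outdir, "pedigree.csv"))
    utils::write.csv(env$sim$phenotypes, file.path(outdir, "phenotypes.csv"),
                     row.names = FALSE)
    tb <- data.frame(animal = rownames(env$sim$true_bv), env$sim$true_bv,
                     check.names = FALSE)
    utils::write.csv(tb, file.path(outdir, "true_breeding_values.csv"),
                     row.names = FALSE)
    write_manifest(outdir, "simulate", cfg$simulate, seed, character(0),
                   c(paste0(out, c(".bed", ".bim", ".fam")),
                     file.path(outdir, c("pedigree.csv", "phenotypes.csv",
                                         "true_breeding_values.csv"))))
  })

  if (is.null(env$sim) && any(c("qc", "popgen", "kinship", "varcomp",
                                "blup", "validate") %in% st)) {
    p <- cfg$paths
    if (is.null(p)) stop("no simulate stage and no input paths configured")
    env$panel <- load_genotypes(p$genotypes)
    env$pedigree <- load_pedigree(p$pedigree)
    env$phenotypes <- utils::read.csv(p$phenotypes)
  } else if (!is.null(env$sim)) {
    env$panel <- env$sim$panel
    env$pedigree <- env$sim$pedigree
    env$phenotypes <- env$sim$phenotypes
  }

  run_stage("qc", function() {
    thr <- do.call(qc_thresholds, cfg$qc[intersect(names(cfg$qc),
      names(formals(qc_thresholds)))])
    res <- run_genotype_qc(env$panel, thr)
    env$panel <- res$panel
    utils::write.csv(res$report, file.path(outdir, "qc_report.csv"),
                     row.names = FALSE)
    writeLines(res$panel$samples$id, file.path(outdir, "qc_keep_samples.txt"))
    writeLines(res$panel$map$id, file.path(outdir, "qc_keep_markers.txt"))
    write_manifest(outdir, "qc", cfg$qc, seed, character(0),
                   file.path(outdir, c("qc_report.csv", "qc_keep_samples.txt",
                                       "qc_keep_markers.txt")))
  })

  run_stage("popgen", function() {
    bp <- breed_pair_summary(env$panel,
                             use_phase = !isFALSE(cfg$popgen$use_phase))
    ld_tab <- do.call(rbind, lapply(names(bp$ld), function(b)
      cbind(breed = b, bp$ld[[b]])))
    utils::write.csv(ld_tab, file.path(outdir, "ld_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(breed = rownames(bp$matrix), bp$matrix,
                                check.names = FALSE),
                     file.path(outdir, "phase_freq_matrix.csv"),
                     row.names = FALSE)
    G <- build_G(env$panel)
    pc <- grm_pca(G, n_comp = max(2L, cfg$popgen$n_components %||% 2L))
    utils::write.csv(data.frame(id = G$ids,
                                breed = env$panel$samples$breed,
                                pc$scores, check.names = FALSE),
                     file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    write_manifest(outdir, "popgen", cfg$popgen, seed, character(0),
                   file.path(outdir, c("ld_pairs.csv", "phase_freq_matrix.csv",
                                       "pca_scores.csv")))
  })

  run_stage("kinship", function() {
    ks <- cfg$kinship
    geno_ids <- env$panel$samples$id
    gf <- ks$genotyped_fraction %||% 1
    if (gf < 1) {
      set.seed(seed + 7L)
      geno_ids <- sort(sample(geno_ids, ceiling(gf * length(geno_ids))))
    }
    Ainv <- build_A_inverse(env$pedigree)
    A22 <- build_A(env$pedigree, subset = geno_ids)
    G <- build_G(subset_panel(env$panel, samples = geno_ids),
                 freq_policy = ks$freq_policy %||% "mean_of_breeds")
    env$Hinv <- build_H_inverse(Ainv, A22, G,
                                blend = unlist(ks$blend %||% c(0.95, 0.05)))
    write_relmat(env$Hinv, file.path(outdir, "H_inverse.csv"))
    write_manifest(outdir, "kinship", cfg$kinship, seed, character(0),
                   file.path(outdir, c("H_inverse.csv", "H_inverse.csv.ids")))
  })

  model_from_cfg <- function() {
    traits <- if (!is.null(env$spec)) env$spec$breeds else
      sort(unique(env$phenotypes$breed))
    model_spec(traits,
               use_cg = !isFALSE(cfg$model$use_cg),
               covariates = unlist(cfg$model$covariates) %||% character(),
               pe_traits = unlist(cfg$model$pe_traits) %||% character())
  }

  run_stage("varcomp", function() {
    if (is.null(env$Hinv)) stop("varcomp needs the kinship stage")
    ms <- model_from_cfg()
    chain_cfg <- list(cycles = cfg$mcmc$cycles %||% 20000L,
                      burnin = cfg$mcmc$burnin %||% 4000L,
                      thin = cfg$mcmc$thin %||% 10L)
    env$chain <- gibbs_sample(env$phenotypes, ms, env$Hinv,
                              chain = chain_cfg, seed = seed)
    utils::write.csv(data.frame(env$chain$draws, check.names = FALSE),
                     file.path(outdir, "chain_draws.csv"), row.names = FALSE)
    der <- derive_parameters(env$chain)
    utils::write.csv(der$summary, file.path(outdir, "parameter_summary.csv"),
                     row.names = FALSE)
    write_summary_table(render_parameter_matrix(der, ms$traits),
                        file.path(outdir, "parameter_matrix"))
    env$comps <- chain_posterior_components(env$chain)
    write_manifest(outdir, "varcomp", chain_cfg, seed, character(0),
                   file.path(outdir, c("chain_draws.csv",
                                       "parameter_summary.csv",
                                       "parameter_matrix.csv")))
  })

  run_stage("blup", function() {
    if (is.null(env$Hinv)) stop("blup needs the kinship stage")
    ms <- model_from_cfg()
    if (is.null(env$comps))
      env$comps <- if (!is.null(env$sim)) env$sim$true_components else
        stop("blup needs varcomp (or simulated truth) for components")
    sys <- assemble_mme(env$phenotypes, ms, env$comps, env$Hinv)
    sol <- solve_mme(sys)
    utils::write.csv(sol$solutions, file.path(outdir, "solutions.csv"),
                     row.names = FALSE)
    env$ebv <- extract_ebv(sol, sys)
    write_manifest(outdir, "blup", list(tol = 1e-10), seed, character(0),
                   file.path(outdir, "solutions.csv"))
  })

  run_stage("validate", function() {
    if (is.null(env$Hinv) || is.null(env$comps))
      stop("validate needs kinship and varcomp (or simulated truth)")
    ms <- model_from_cfg()
    breeds <- unlist(cfg$validate$breeds) %||% ms$traits
    strategies <- unlist(cfg$validate$strategies) %||%
      c("old-young", "other-pops")
    truth <- if (!is.null(env$sim)) env$sim$true_bv else NULL
    rows <- list()
    for (b in breeds) {
      if ("old-young" %in% strategies) {
        rows[[length(rows) + 1L]] <-
          lr_validate(env$phenotypes, ms, env$comps, env$Hinv,
                      env$pedigree, b, "old-young", true_bv = truth,
                      univariate = TRUE)
        rows[[length(rows) + 1L]] <-
          lr_validate(env$phenotypes, ms, env$comps, env$Hinv,
                      env$pedigree, b, "old-young", true_bv = truth)
      }
      if ("other-pops" %in% strategies && length(ms$traits) > 1L)
        rows[[length(rows) + 1L]] <-
          lr_validate(env$phenotypes, ms, env$comps, env$Hinv,
                      env$pedigree, b, "other-pops", true_bv = truth)
    }
    rep_tab <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(c("breed", "strategy", "model", "n", "rho_wp",
                  "predictive_ability", "beta_wp", "acc_w", "acc_p"),
                setdiff(c("acc_w", "acc_p"), names(r)))]
    }))
    utils::write.csv(rep_tab, file.path(outdir, "validation_reports.csv"),
                     row.names = FALSE)
    write_summary_table(render_validation_grid(rep_tab, breeds),
                        file.path(outdir, "validation_grid"))
    write_manifest(outdir, "validate", cfg$validate, seed, character(0),
                   file.path(outdir, c("validation_reports.csv",
                                       "validation_grid.csv")))
  })

  invisible(outdir)
}

#' Posterior-mean covariance components from a chain
#'
#' @param chain a [gibbs_sample()] chain.
#' @return A [covariance_components()] at the posterior means.
#' @export
chain_posterior_components <- function(chain) {
  stopifnot(inherits(chain, "gibbs_chain"))
  m <- colMeans(chain$draws)
  traits <- chain$traits
  T <- length(traits)
  S <- matrix(0, T, T, dimnames = list(traits, traits))
  S[upper.tri(S, diag = TRUE)] <- m[seq_len(T * (T + 1) / 2)]
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  s2p <- m[sprintf("sigma2_p[%s]", chain$pe_traits)]
  names(s2p) <- chain$pe_traits
  covariance_components(S, s2e = stats::setNames(
    m[sprintf("sigma2_e[%s]", traits)], traits),
    s2p = if (length(s2p)) s2p else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
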