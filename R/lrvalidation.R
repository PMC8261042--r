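#' Whole/partial data partition for LR-method validation
#'
#' Two strategies.  `old-young`: the target breed's phenotyped (and, when
#' supplied, genotyped) animals are sorted by birth date (ties broken by
#' id); the oldest 2/3 (floor) keep their phenotypes, the youngest third
#' become the validation group with phenotypes masked; other breeds are
#' fully retained.  `other-pops`: every phenotype of the target breed is
#' masked, so partial-data predictions for it flow exclusively through the
#' cross-breed genetic correlations.  Masked animals keep their genotypes
#' and pedigree links.
#'
#' @param phenotypes record data frame (`animal`, `breed`, ...).
#' @param pedigree pedigree with `id` and `birthdate` (old-young).
#' @param strategy `"old-young"` or `"other-pops"`.
#' @param target target breed label.
#' @param genotyped optional ids; old-young validation animals are drawn
#'   from the phenotyped-and-genotyped set.
#' @return Object of class `lr_partition`: `strategy`, `target`,
#'   `reference` (row indices of `phenotypes` forming the partial data),
#'   `validation_ids`, `cut_date` (old-young).
#' @export
make_partition <- function(phenotypes, pedigree = NULL,
                           strategy = c("old-young", "other-pops"),
                           target, genotyped = NULL) {
  strategy <- match.arg(strategy)
  in_target <- phenotypes$breed == target
  cand <- unique(as.character(phenotypes$animal[in_target]))
  if (!is.null(genotyped)) cand <- intersect(cand, as.character(genotyped))
  if (length(cand) < 3L) stop("need >= 3 phenotyped animals in the target breed")
  if (strategy == "other-pops") {
    return(structure(list(strategy = strategy, target = target,
                          reference = which(!in_target),
                          validation_ids = cand, cut_date = NULL),
                     class = "lr_partition"))
  }
  if (is.null(pedigree)) stop("old-young needs a pedigree with birth dates")
  bd <- pedigree$birthdate[match(cand, as.character(pedigree$id))]
  if (anyNA(bd)) stop("missing birth date(s) for: ",
                      paste(cand[is.na(bd)], collapse = ", "))
  ord <- order(bd, cand)
  n_ref <- floor(2 * length(cand) / 3)
  val <- cand[ord][(n_ref + 1L):length(cand)]
  keep <- !(in_target & as.character(phenotypes$animal) %in% val)
  structure(list(strategy = strategy, target = target,
                 reference = which(keep), validation_ids = val,
                 cut_date = sort(bd)[n_ref]),
            class = "lr_partition")
}

#' LR-method validation statistics
#'
#' Over the validation animals: `rho_wp`, the correlation of whole- and
#' partial-data breeding values (estimates the ratio of partial to whole
#' population accuracy, `E(rho_wp) ~ acc_p / acc_w`); the predictive
#' ability `r(y*, u_p)` against phenotypes adjusted for fixed and
#' permanent-environment effects; and the dispersion slope `beta_wp` of the
#' regression of whole on partial breeding values (1 = unbiased, < 1 =
#' over-dispersed partial predictions).  Animals with repeated records
#' contribute their mean adjusted phenotype.
#'
#' @param u_w,u_p named whole- and partial-data breeding values (target
#'   trait) covering the validation ids.
#' @param ystar named adjusted phenotypes from the whole-data fit (may omit
#'   animals without records).
#' @param validation_ids animals to evaluate over.
#' @return Data frame row: n, rho_wp, predictive_ability, beta_wp.
#' @export
lr_statistics <- function(u_w, u_p, ystar, validation_ids) {
  ids <- as.character(validation_ids)
  if (length(ids) < 2L) stop("need > 1 validation animal")
  if (!all(ids %in% names(u_w)) || !all(ids %in% names(u_p)))
    stop("breeding values missing for some validation animals")
  w <- u_w[ids]; p <- u_p[ids]
  vp <- stats::var(p)
  if (vp == 0 || stats::var(w) == 0)
    return(data.frame(n = length(ids), rho_wp = NA_real_,
                      predictive_ability = NA_real_, beta_wp = NA_real_))
  ok <- ids[ids %in% names(ystar)]
  pa <- if (length(ok) > 1L && stats::var(ystar[ok]) > 0 &&
            stats::var(u_p[ok]) > 0)
    stats::cor(ystar[ok], u_p[ok]) else NA_real_
  data.frame(n = length(ids),
             rho_wp = stats::cor(w, p),
             predictive_ability = pa,
             beta_wp = stats::cov(w, p) / vp)
}

#' Population accuracy against simulation truth
#'
#' Pearson correlation of estimated and true breeding values over the
#' validation animals (the "population accuracy" whose partial/whole ratio
#' the LR correlation estimates).
#'
#' @param u_hat named estimated breeding values.
#' @param u_true named true breeding values.
#' @param validation_ids animals to evaluate over.
#' @return The correlation, or `NA` (with a warning) when either side has
#'   zero variance.
#' @export
accuracy_from_truth <- function(u_hat, u_true, validation_ids) {
  ids <- as.character(validation_ids)
  if (!all(ids %in% names(u_hat)) || !all(ids %in% names(u_true)))
    stop("breeding values missing for some validation animals")
  a <- u_hat[ids]; b <- u_true[ids]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Run LR validation for one breed and strategy
#'
#' Fits the whole-data and partial-data evaluations with the same model and
#' covariance components, computes adjusted phenotypes from the whole fit,
#' and returns the LR statistics (plus true-value accuracies when
#' simulation truth is supplied).
#'
#' @param records full phenotype table.
#' @param spec,comps,H_inv as in [assemble_mme()].
#' @param pedigree pedigree (for old-young dates).
#' @param target target breed.
#' @param strategy `"old-young"` or `"other-pops"`.
#' @param genotyped optional genotyped ids (validation set restriction).
#' @param true_bv optional matrix of true breeding values (animals x traits).
#' @param univariate fit the single-breed marginal model instead of the
#'   multi-trait model.
#' @param tol,max_iter solver settings.
#' @return One-row data frame: breed, strategy, model, n, rho_wp,
#'   predictive_ability, beta_wp and (with truth) acc_w, acc_p.
#' @export
lr_validate <- function(records, spec, comps, H_inv, pedigree, target,
                        strategy = "old-young", genotyped = NULL,
                        true_bv = NULL, univariate = FALSE,
                        tol = 1e-9, max_iter = 20000L) {
  part <- make_partition(records, pedigree, strategy, target, genotyped)
  fit <- function(rec) {
    if (univariate) {
      r <- predict_univariate(rec, spec, comps, H_inv, target,
                              tol = tol, max_iter = max_iter)
      list(sol = r$solution, sys = r$sys)
    } else {
      sys <- assemble_mme(rec, spec, comps, H_inv)
      list(sol = solve_mme(sys, tol, max_iter), sys = sys)
    }
  }
  whole <- fit(records)
  partial <- fit(records[part$reference, , drop = FALSE])
  u_w <- extract_ebv(whole$sol, whole$sys)[, target]
  u_p <- extract_ebv(partial$sol, partial$sys)[, target]
  ystar <- adjusted_phenotypes(whole$sol, whole$sys)
  out <- lr_statistics(u_w, u_p, ystar, part$validation_ids)
  out <- cbind(data.frame(breed = target, strategy = strategy,
                          model = if (univariate) "uni" else "multi"), out)
  if (!is.null(true_bv)) {
    tv <- stats::setNames(true_bv[, target], rownames(true_bv))
    out$acc_w <- accuracy_from_truth(u_w, tv, part$validation_ids)
    out$acc_p <- accuracy_from_truth(u_p, tv, part$validation_ids)
  }
  out
}
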