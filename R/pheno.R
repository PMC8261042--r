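#' Log-transform tick counts
#'
#' Tick counts are strongly right-skewed; the standard normalising transform
#' for this trait is `log(count + 1)`, base 10 for count data and natural
#' log where a population's records were recorded that way.
#'
#' @param count non-negative integer vector of tick counts.
#' @param base 10 or `exp(1)`.
#' @return `log(count + 1)` in the requested base.
#' @examples
#' log_transform_counts(c(0, 9, 99))   # 0, 1, 2
#' @export
log_transform_counts <- function(count, base = 10) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and >= 0")
  if (any(count != round(count))) stop("counts must be integers")
  if (!isTRUE(all.equal(base, 10)) && !isTRUE(all.equal(base, exp(1))))
    stop("base must be 10 or e")
  log(count + 1, base = base)
}

#' Bin a tick count onto the 0-5 visual score scale
#'
#' Field scoring of tick burden uses a six-point scale: 0 = no ticks,
#' 1 = up to 10, 2 = 11-30, 3 = 31-80, 4 = 81-150, 5 = more than 150
#' engorged female ticks.
#'
#' @param count non-negative integer vector of tick counts.
#' @return Integer scores in 0..5.
#' @examples
#' bin_tick_score(c(0, 10, 11, 150, 151))  # 0 1 2 4 5
#' @export
bin_tick_score <- function(count) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be finite and >= 0")
  if (any(count != round(count))) stop("counts must be integers")
  as.integer(cut(count, breaks = c(-0.5, 0.5, 10.5, 30.5, 80.5, 150.5, Inf),
                 labels = FALSE)) - 1L
}

#' Build contemporary groups and trim outlying records
#'
#' Concatenates the contemporary-group (CG) key columns into a single factor,
#' removes records in CGs with fewer than `min_size` animals, then removes
#' records deviating more than `sd_limit` standard deviations from their CG
#' mean.  The SD is computed once, on the untrimmed CG (single pass), so the
#' result does not depend on record order.
#'
#' @param records data frame of phenotype records with a `value` column.
#' @param cg_cols character vector naming the CG key columns.
#' @param min_size minimum number of animals per CG (default 5).
#' @param sd_limit trim limit in CG standard deviations (default 3.5).
#' @param value_col name of the record value column.
#' @param animal_col name of the animal id column (used to count animals per
#'   CG; records of the same animal count once).
#' @return List with `records` (surviving rows, plus a `cg` factor column)
#'   and `report` (data frame: rule, n_removed).
#' @export
build_contemporary_groups <- function(records, cg_cols, min_size = 5,
                                      sd_limit = 3.5, value_col = "value",
                                      animal_col = "animal") {
  if (nrow(records) == 0L) {
    rec <- records
    rec$cg <- factor(character(0))
    return(list(records = rec,
                report = data.frame(rule = c("cg_size", "sd_trim"),
                                    n_removed = c(0L, 0L))))
  }
  miss <- setdiff(c(cg_cols, value_col, animal_col), names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(records[cg_cols], sep = ":"))
  if (anyNA(records[cg_cols])) stop("incomplete CG key")
  n_animals <- tapply(records[[animal_col]], key, function(a) length(unique(a)))
  small <- names(n_animals)[n_animals < min_size]
  drop_size <- key %in% small
  v <- records[[value_col]]
  mu <- ave(v, key, FUN = mean)
  sdv <- ave(v, key, FUN = stats::sd)
  dev <- ifelse(is.na(sdv) | sdv == 0, 0, abs(v - mu) / sdv)
  drop_sd <- !drop_size & dev > sd_limit
  keep <- !(drop_size | drop_sd)
  rec <- records[keep, , drop = FALSE]
  rec$cg <- factor(key[keep])
  list(records = rec,
       report = data.frame(rule = c("cg_size", "sd_trim"),
                           n_removed = c(sum(drop_size), sum(drop_sd))))
}

#' Pre-adjust repeated records to a single value per animal
#'
#' Fits the stated fixed effects by ordinary least squares and returns, per
#' animal, the mean of (record - fitted fixed part).  This condenses
#' repeated measurements into one fixed-effect-adjusted value per animal
#' (the treatment used for populations whose data arrive pre-summarised).
#'
#' @param records data frame with an animal id column and a value column.
#' @param fixed one-sided formula of fixed effects over columns of
#'   `records` (e.g. `~ farm + sex`); `~ 1` fits an overall mean only.
#' @param animal_col,value_col column names.
#' @return Named numeric vector, one adjusted value per animal.
#' @export
preadjust_repeated_records <- function(records, fixed = ~ 1,
                                       animal_col = "animal",
                                       value_col = "value") {
  stopifnot(nrow(records) >= 1L)
  X <- stats::model.matrix(fixed, records)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  y <- records[[value_col]]
  fit <- qr.fitted(qrX, y)
  resid <- y - fit
  out <- tapply(resid, records[[animal_col]], mean)
  stats::setNames(as.numeric(out), names(out))
}
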