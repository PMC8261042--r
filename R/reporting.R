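#' Parameter matrix in the customary breed x breed layout
#'
#' Builds the t x t summary table with heritabilities (posterior mean
#' +/- time-series SE) on the diagonal and genetic correlations above it;
#' the lower triangle is left blank.
#'
#' @param der a [derive_parameters()] result from a chain (its `summary`),
#'   or the summary data frame itself.
#' @param traits breed labels in display order.
#' @param digits rounding (half-even) for the formatted table.
#' @return List of class `summary_table`: `values` (numeric matrix, mean),
#'   `se` (matrix), `formatted` (character matrix "mean +/- se").
#' @export
render_parameter_matrix <- function(der, traits, digits = 2) {
  sm <- if (is.data.frame(der)) der else der$summary
  t <- length(traits)
  val <- se <- matrix(NA_real_, t, t, dimnames = list(traits, traits))
  fmt <- matrix("", t, t, dimnames = list(traits, traits))
  pick <- function(p) {
    row <- sm[sm$param == p, ]
    if (!nrow(row)) stop("missing parameter summary: ", p)
    row
  }
  for (i in seq_len(t)) {
    r <- pick(sprintf("h2[%s]", traits[i]))
    val[i, i] <- r$mean; se[i, i] <- r$ts_se
    for (j in seq_len(t)) {
      if (j <= i) next
      p1 <- sprintf("rg[%s,%s]", traits[i], traits[j])
      p2 <- sprintf("rg[%s,%s]", traits[j], traits[i])
      row <- sm[sm$param %in% c(p1, p2), ]
      if (!nrow(row)) stop("missing breed pair: ", traits[i], " x ", traits[j])
      val[i, j] <- row$mean[1]; se[i, j] <- row$ts_se[1]
    }
  }
  rnd <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  idx <- which(!is.na(val), arr.ind = TRUE)
  fmt[idx] <- paste0(rnd(val[idx]), " ± ", rnd(se[idx]))
  structure(list(values = val, se = se, formatted = fmt),
            class = "summary_table")
}

#' Validation grid in the customary breed x strategy layout
#'
#' Rows are breeds; columns are statistic-by-strategy blocks
#' (predictive ability, dispersion slope, whole/partial correlation for
#' each of: univariate old-young, multivariate old-young, multivariate
#' other-pops).  A missing breed x strategy cell is emitted as `NA` with a
#' warning rather than dropped.
#'
#' @param reports data frame rbind of [lr_validate()] rows.
#' @param breeds row order.
#' @param digits rounding for the formatted copy.
#' @return List of class `summary_table`: `values` (data frame), `formatted`.
#' @export
render_validation_grid <- function(reports, breeds = NULL, digits = 2) {
  if (is.null(breeds)) breeds <- unique(reports$breed)
  combos <- data.frame(
    model = c("uni", "multi", "multi"),
    strategy = c("old-young", "old-young", "other-pops"),
    tag = c("uni_oy", "multi_oy", "multi_op"))
  stats <- c("predictive_ability", "beta_wp", "rho_wp")
  out <- data.frame(breed = breeds)
  for (s in stats) for (k in seq_len(nrow(combos))) {
    col <- paste(s, combos$tag[k], sep = ".")
    out[[col]] <- vapply(breeds, function(b) {
      row <- reports[reports$breed == b & reports$model == combos$model[k] &
                       reports$strategy == combos$strategy[k], ]
      if (!nrow(row)) {
        warning("missing cell: ", b, " / ", combos$tag[k], " / ", s)
        return(NA_real_)
      }
      row[[s]][1]
    }, numeric(1))
  }
  fmt <- out
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x)
    ifelse(is.na(x), "NA", formatC(round(x, digits), format = "f",
                                   digits = digits)))
  structure(list(values = out, formatted = fmt), class = "summary_table")
}

#' Write a summary table as CSV (full precision) and Markdown (rounded)
#'
#' @param tab a `summary_table`.
#' @param path base path; writes `<path>.csv` and `<path>.md`.
#' @return Paths written, invisibly.
#' @export
write_summary_table <- function(tab, path) {
  stopifnot(inherits(tab, "summary_table"))
  val <- tab$values
  if (is.matrix(val)) val <- data.frame(label = rownames(val), val,
                                        check.names = FALSE)
  utils::write.csv(val, paste0(path, ".csv"), row.names = FALSE)
  fmt <- tab$formatted
  if (is.matrix(fmt)) fmt <- data.frame(label = rownames(fmt), fmt,
                                        check.names = FALSE)
  md <- c(paste0("| ", paste(names(fmt), collapse = " | "), " |"),
          paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|"),
          vapply(seq_len(nrow(fmt)), function(i)
            paste0("| ", paste(unlist(fmt[i, ]), collapse = " | "), " |"),
            character(1)))
  writeLines(md, paste0(path, ".md"))
  invisible(paste0(path, c(".csv", ".md")))
}
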