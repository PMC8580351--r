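#' Join driver-mutation catalogs with fitted stage numbers
#'
#' Builds the driver-decomposition table: for each cancer type, the mean
#' number of driver mutations per tumor from two published pan-cancer
#' catalogs is set against the fitted stage number k (pooled-sex fits for
#' non-reproductive cancers, sex-specific fits for reproductive ones,
#' which the caller supplies in `k_table`), and the non-driver stage count
#' is the difference.  Negative non-driver counts are possible and kept:
#' they flag cancers reporting more driver mutations than fitted stages.
#'
#' @param driver_catalog data frame with columns cancer_code,
#'   drivers_iranzo, drivers_bailey
#' @param k_table data frame with columns cancer_code and k (or k_stages)
#' @return data frame with the joined columns plus non_driver_iranzo and
#'   non_driver_bailey
#' @export
build_driver_table <- function(driver_catalog, k_table) {
  kcol <- if ("k_stages" %in% names(k_table)) "k_stages" else "k"
  m <- merge(driver_catalog[, c("cancer_code", "drivers_iranzo",
                                "drivers_bailey")],
             stats::setNames(k_table[, c("cancer_code", kcol)],
                             c("cancer_code", "k_stages")),
             by = "cancer_code")
  m$non_driver_iranzo <- m$k_stages - m$drivers_iranzo
  m$non_driver_bailey <- m$k_stages - m$drivers_bailey
  m
}

#' Regression of driver-mutation counts on the stage number
#'
#' Unweighted OLS of mean driver mutations per tumor against fitted k.
#' Records whose studentized (leave-one-out standardized) residual from a
#' preliminary all-points fit is at least `outlier_threshold` (default
#' 3.0) are removed before the final fit, and the Pearson correlation is
#' reported on the retained set.
#'
#' @param records driver table from [build_driver_table()]
#' @param catalog "iranzo" or "bailey": which driver column to regress
#' @param exclude_outliers apply the standardized-residual rule
#' @param outlier_threshold studentized-residual cutoff
#' @return list with slope, intercept, r, p, n, `outliers` (codes removed)
#'   and the final `lm` fit
#' @export
driver_stage_regression <- function(records, catalog = c("iranzo", "bailey"),
                                    exclude_outliers = TRUE,
                                    outlier_threshold = 3.0) {
  catalog <- match.arg(catalog)
  ycol <- paste0("drivers_", catalog)
  stopifnot(nrow(records) >= 4)
  dat <- data.frame(k = records$k_stages, y = records[[ycol]],
                    cancer_code = records$cancer_code)
  outliers <- character(0)
  if (exclude_outliers) {
    pre <- stats::lm(y ~ k, data = dat)
    # on an (essentially) exact fit the leave-one-out residual scale is
    # numerical noise and studentization is meaningless: nothing to remove
    sig <- suppressWarnings(summary(pre)$sigma)
    if (sig > 1e-8 * max(stats::sd(dat$y), .Machine$double.eps)) {
      rs <- stats::rstudent(pre)
      outliers <- dat$cancer_code[!is.na(rs) & abs(rs) >= outlier_threshold]
    }
    dat <- dat[!(dat$cancer_code %in% outliers), ]
  }
  fit <- stats::lm(y ~ k, data = dat)
  ct <- stats::cor.test(dat$k, dat$y, method = "pearson")
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = nrow(dat),
       outliers = outliers, fit = fit)
}

#' Summary of the driver contribution to carcinogenic stages
#'
#' Column means of driver mutations and fitted stages over a subset of
#' records, and the per-cancer percent contribution drivers/k * 100 with
#' its mean and a 95% population interval (mean +/- 1.96 SD of the
#' per-cancer percentages - an interval for the spread across cancer
#' types, not a standard error of the mean).
#'
#' @param records driver table
#' @param catalog "iranzo" or "bailey"
#' @param exclude optional cancer codes to drop (e.g. "UCEC")
#' @param non_reproductive_only restrict to non-reproductive cancers
#' @return list with mean_drivers, mean_k, mean_percent, percent_interval
#'   (length-2 vector) and n
#' @export
driver_fraction_summary <- function(records, catalog = c("iranzo", "bailey"),
                                    exclude = character(0),
                                    non_reproductive_only = FALSE) {
  catalog <- match.arg(catalog)
  ycol <- paste0("drivers_", catalog)
  rows <- records[!(records$cancer_code %in% exclude), ]
  if (non_reproductive_only)
    rows <- rows[!(rows$cancer_code %in% reproductive_codes()), ]
  if (nrow(rows) < 2) stop("subset resolves fewer than 2 records")
  pct <- rows[[ycol]] / rows$k_stages * 100
  list(mean_drivers = mean(rows[[ycol]]),
       mean_k = mean(rows$k_stages),
       mean_percent = mean(pct),
       percent_interval = mean(pct) + c(-1, 1) * 1.96 * stats::sd(pct),
       n = nrow(rows))
}
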