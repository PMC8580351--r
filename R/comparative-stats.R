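#' Named row subsets of a parameter table
#'
#' Every cross-cancer statistic depends on an exact inclusion set, so the
#' selections are encoded once, by name, rather than ad hoc:
#' \describe{
#'   \item{all}{every row}
#'   \item{non_reproductive}{rows with `reproductive == FALSE`}
#'   \item{reproductive}{rows with `reproductive == TRUE`}
#'   \item{non_repro_core}{non-reproductive minus the degenerate fits
#'     (LGG, PCPG) and minus the combined COADREAD row (COAD and READ
#'     enter separately); n = 21 on the pooled table}
#'   \item{non_repro_core_no_read}{`non_repro_core` additionally minus
#'     READ; n = 20, the paired male/female comparison set}
#'   \item{any_cancer_male}{male lifetime-risk set: all male rows minus
#'     LGG, PCPG and COADREAD}
#'   \item{any_cancer_female}{female lifetime-risk set: minus LGG, PCPG,
#'     COADREAD and READ}
#' }
#'
#' @param tbl a parameter table with columns cancer_code, reproductive
#' @param subset one of the names above
#' @return the selected rows
#' @export
select_subset <- function(tbl, subset = c("all", "non_reproductive",
                                          "reproductive", "non_repro_core",
                                          "non_repro_core_no_read",
                                          "any_cancer_male",
                                          "any_cancer_female")) {
  subset <- match.arg(subset)
  drop_codes <- switch(subset,
    all = character(0),
    non_reproductive = character(0),
    reproductive = character(0),
    non_repro_core = c("LGG", "PCPG", "COADREAD"),
    non_repro_core_no_read = c("LGG", "PCPG", "COADREAD", "READ"),
    any_cancer_male = c("LGG", "PCPG", "COADREAD"),
    any_cancer_female = c("LGG", "PCPG", "COADREAD", "READ"))
  keep <- !(tbl$cancer_code %in% drop_codes)
  if (subset %in% c("non_reproductive", "non_repro_core",
                    "non_repro_core_no_read"))
    keep <- keep & !tbl$reproductive
  if (subset == "reproductive") keep <- keep & tbl$reproductive
  tbl[keep, , drop = FALSE]
}

#' Mean and SD of a fitted parameter over a named subset
#'
#' @param tbl parameter table
#' @param parameter column name, e.g. "b" or "k"
#' @param subset a [select_subset()] name
#' @return list with `mean`, `sd` (n-1 denominator) and `n`
#' @export
summarize_parameter <- function(tbl, parameter = "b", subset = "non_repro_core") {
  rows <- select_subset(tbl, subset)
  x <- rows[[parameter]]
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("subset resolves fewer than 2 rows")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

#' Paired t-test of a parameter between two matched tables
#'
#' Classical paired t-test on per-cancer differences between, e.g., the
#' male and female tables, matching rows by cancer code.  When a family of
#' parameters is tested together, Holm step-down adjustment is applied
#' across the family.
#'
#' @param tbl_a,tbl_b parameter tables sharing cancer codes
#' @param parameters character vector of column names to test
#' @param subset a [select_subset()] name applied to both tables
#' @param correction "holm" (default) or "none"
#' @return data frame with parameter, n, t, df, p, p_adj
#' @export
paired_parameter_test <- function(tbl_a, tbl_b, parameters,
                                  subset = "non_repro_core_no_read",
                                  correction = c("holm", "none")) {
  correction <- match.arg(correction)
  a <- select_subset(tbl_a, subset)
  b <- select_subset(tbl_b, subset)
  common <- intersect(a$cancer_code, b$cancer_code)
  if (length(common) < 2) stop("fewer than 2 matched cancers")
  a <- a[match(common, a$cancer_code), ]
  b <- b[match(common, b$cancer_code), ]
  res <- do.call(rbind, lapply(parameters, function(p) {
    d <- a[[p]] - b[[p]]
    if (all(d == 0)) {
      data.frame(parameter = p, n = length(d), t = 0,
                 df = length(d) - 1, p = 1)
    } else {
      ht <- stats::t.test(a[[p]], b[[p]], paired = TRUE)
      data.frame(parameter = p, n = length(d),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
    }
  }))
  res$p_adj <- if (correction == "holm") stats::p.adjust(res$p, "holm") else res$p
  res
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, e.g. for
#' comparing the senescence slope of reproductive against non-reproductive
#' cancers.
#'
#' @param x,y numeric vectors (each of length >= 2)
#' @return list with t, df, p
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (isTRUE(all.equal(c(x, y), rep(mean(c(x, y)), length(x) + length(y)))))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Rank and linear correlation
#'
#' Spearman's rho (ties mid-ranked, P from the t approximation) and
#' Pearson's r with its t-based P-value.
#'
#' @param x,y paired numeric vectors, length >= 4
#' @return list with estimate, p, n (and `method`)
#' @export
rank_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stopifnot(sum(ok) >= 4)
  ht <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
  list(estimate = unname(ht$estimate), p = ht$p.value, n = sum(ok),
       method = "spearman")
}

#' @rdname rank_corr
#' @export
linear_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  stopifnot(sum(ok) >= 4)
  ht <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(estimate = unname(ht$estimate), p = ht$p.value, n = sum(ok),
       method = "pearson")
}

#' Regression of the stage-transition rate on the stage number
#'
#' Unweighted ordinary least squares of u on k across cancer types.  The
#' slope and the negated intercept are the constants (c, d) of the
#' two-variable model, u = c*k - d.
#'
#' @param tbl parameter table with columns u_mu and k
#' @param subset a [select_subset()] name
#' @return list with `c` (slope), `d` (negated intercept), `slope_se`,
#'   `slope_p`, `r_squared`, `n` and the underlying `lm` fit
#' @export
regress_u_on_k <- function(tbl, subset = "non_repro_core") {
  rows <- select_subset(tbl, subset)
  if (nrow(rows) < 3) stop("fewer than 3 rows for regression")
  fit <- stats::lm(u_mu ~ k, data = rows)
  sm <- summary(fit)
  list(c = unname(stats::coef(fit)[2]), d = -unname(stats::coef(fit)[1]),
       slope_se = sm$coefficients[2, 2], slope_p = sm$coefficients[2, 4],
       r_squared = sm$r.squared, n = nrow(rows), fit = fit)
}

#' ANCOVA comparison of two regression lines
#'
#' Tests equality of slopes (group-by-covariate interaction F-test) and,
#' given a common slope, equality of intercepts (group main effect) for
#' y ~ x fitted in two groups, e.g. the male and female u-versus-k trends.
#'
#' @param x_a,y_a data for group A
#' @param x_b,y_b data for group B
#' @return list with `p_slope` and `p_intercept`
#' @export
compare_slopes <- function(x_a, y_a, x_b, y_b) {
  dat <- data.frame(x = c(x_a, x_b), y = c(y_a, y_b),
                    g = factor(rep(c("A", "B"), c(length(x_a), length(x_b)))))
  if (identical(c(x_a, y_a), c(x_b, y_b)))
    return(list(p_slope = 1, p_intercept = 1))
  full <- stats::lm(y ~ x * g, data = dat)
  common_slope <- stats::lm(y ~ x + g, data = dat)
  common_line <- stats::lm(y ~ x, data = dat)
  p_slope <- stats::anova(common_slope, full)[2, "Pr(>F)"]
  p_intercept <- stats::anova(common_line, common_slope)[2, "Pr(>F)"]
  list(p_slope = p_slope, p_intercept = p_intercept)
}

#' Association of observed/expected lifetime risk with extrinsic risk
#'
#' Rank-correlates the SEER-to-two-variable cumulative-probability ratio
#' (a proxy for non-baseline risk) against a user-supplied table of
#' extrinsic-to-intrinsic risk ratios, joined on cancer code.
#'
#' @param ratio_tbl data frame with cancer_code and ratio_seer_twovar
#' @param extrinsic_tbl data frame with cancer_code and extrinsic_ratio
#' @return list as from [rank_corr()]
#' @export
extrinsic_association <- function(ratio_tbl, extrinsic_tbl) {
  m <- merge(ratio_tbl[, c("cancer_code", "ratio_seer_twovar")],
             extrinsic_tbl[, c("cancer_code", "extrinsic_ratio")],
             by = "cancer_code")
  rank_corr(m$ratio_seer_twovar, m$extrinsic_ratio)
}

#' Lifetime risk of at least one cancer from a parameter table
#'
#' Combines a table's per-cancer model-fitted lifetime cumulative
#' probabilities under independence, using the named lifetime-risk subset
#' for the given sex (degenerate fits and the double-counting colorectal
#' row removed).
#'
#' @param tbl parameter table with a `model_cum_prob` (or `cum_prob`) column
#' @param sex "male" or "female"
#' @return probability of at least one diagnosis
#' @export
lifetime_risk_from_table <- function(tbl, sex = c("male", "female")) {
  sex <- match.arg(sex)
  rows <- select_subset(tbl, paste0("any_cancer_", sex))
  col <- if ("model_cum_prob" %in% names(rows)) "model_cum_prob" else "cum_prob"
  lifetime_risk_any(rows[[col]], na.rm = TRUE)
}
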