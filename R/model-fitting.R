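#' Cancer types with a reproductive time origin
#'
#' For cancers of reproductive organs the stage clock is taken to start at
#' puberty, so model time is age minus 15 years; for all other cancers it
#' is age itself.
#'
#' @return character vector of cancer codes
#' @export
reproductive_codes <- function() {
  c("PRAD", "TGCT", "BRCA", "CESC", "OV", "UCEC", "UCS")
}

#' Default lower age limit of the fitting window
#'
#' Curves are fit from age 50 upward, where case counts begin to rise,
#' except for three early-peaking cancers: thyroid (THCA) and cervical
#' (CESC) cancer from 30 years, and testicular germ-cell tumors (TGCT)
#' from 20 years.
#'
#' @param cancer_code cancer type label
#' @return start age in years
#' @export
default_start_age <- function(cancer_code) {
  switch(as.character(cancer_code), THCA = 30, CESC = 30, TGCT = 20, 50)
}

#' Fit configuration
#'
#' @param start_age lower age limit of the fitting window, years
#' @param onset_offset 0 or 15 years, subtracted from age to get model time
#' @param p_threshold inclusion threshold for the u/k parameter P-values
#' @param max_peak_age upper limit for reported observed peaks, years
#' @param k_bounds allowed range for the stage number during optimization
#' @param k_start_spread multi-start offsets applied to the initial k guess
#' @param maxiter Levenberg-Marquardt iteration cap per start
#' @return an object of class `fit_config`
#' @export
fit_config <- function(start_age = 50, onset_offset = 0,
                       p_threshold = 0.1, max_peak_age = 105,
                       k_bounds = c(0.5, 20),
                       k_start_spread = c(-2, 0, 2),
                       maxiter = 200) {
  stopifnot(start_age >= onset_offset, p_threshold > 0, p_threshold < 1,
            length(k_bounds) == 2L, k_bounds[1] > 0,
            k_bounds[2] > k_bounds[1])
  structure(list(start_age = start_age, onset_offset = onset_offset,
                 p_threshold = p_threshold, max_peak_age = max_peak_age,
                 k_bounds = k_bounds, k_start_spread = k_start_spread,
                 maxiter = maxiter),
            class = "fit_config")
}

#' Per-cancer fit configuration
#'
#' Convenience wrapper applying the start-age exceptions and the
#' reproductive time origin for a given cancer type.
#'
#' @param cancer_code cancer type label
#' @param ... further arguments passed to [fit_config()]
#' @return a `fit_config`
#' @export
fit_config_for <- function(cancer_code, ...) {
  fit_config(start_age = default_start_age(cancer_code),
             onset_offset = if (cancer_code %in% reproductive_codes()) 15 else 0,
             ...)
}

# model rate per 1e5 person-years used by the optimizer; the (1-bt)
# suppression term is truncated at zero so bins beyond the support
# (t > 1/b) compare against a zero rate instead of a negative hazard —
# otherwise near-empty oldest bins, whose Poisson SEs are tiny, dominate
# the weighted objective with meaningless negative-rate residuals
.fit_model_rate <- function(theta, t) {
  1e5 * exp(theta[1] + (theta[2] - 1) * log(t)) * pmax(1 - theta[3] * t, 0)
}

#' Weighted nonlinear least-squares fit of the multistage-senescence model
#'
#' Minimizes \eqn{\sum_i w_i (rate_i - 10^5 ASR(t_i))^2} with
#' \eqn{w_i = 1/SE_i^2} over bins at or above the configured start age,
#' using the Levenberg-Marquardt algorithm.  The amplitude is fit on the
#' log scale (a > 0), the stage number k is bounded, and the senescence
#' slope b is unconstrained in sign.  The objective is multimodal in
#' (a, k), so the optimizer is restarted from a small deterministic grid
#' of k guesses around a log-log-slope estimate and the best deviance
#' kept.  Standard errors come from the Jacobian-based covariance;
#' the transition rate u and its standard error are derived from
#' (log a, k) by the delta method, and parameter P-values are two-sided
#' Wald tests against zero on n - 3 degrees of freedom.
#'
#' @param series an `age_binned_series` from [compute_crude_rates()]
#' @param config a [fit_config()]; default derives start age and onset
#'   offset from the series' cancer code
#' @return an object of class `fit_result`: fitted [model_params], their
#'   standard errors and P-values, residual summary, derived peak age /
#'   peak rate / cumulative probability, and the P-value inclusion flag
#' @export
fit_series <- function(series, config = NULL) {
  stopifnot(inherits(series, "age_binned_series"))
  if (is.null(config)) config <- fit_config_for(series$cancer_code[1])
  win <- series$valid & series$age_mid >= config$start_age
  dat <- series[win, , drop = FALSE]
  if (nrow(dat) < 6) stop("fewer than 6 valid bins at or above start age")
  if (all(dat$cases == 0)) stop("degenerate series: no cases in window")
  tt <- dat$age_mid - config$onset_offset
  y <- dat$rate
  sw <- 1 / dat$rate_se            # sqrt of inverse-variance weight

  # initial guesses: k from the log-log slope of the rising limb plus one,
  # b near the cross-cancer consensus, amplitude matched to the peak bin
  pos <- y > 0
  k0 <- if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ log(tt[pos])))[2]
    max(1.5, min(sl + 1, config$k_bounds[2] - 0.5))
  } else 5
  b0 <- 0.01
  ipk <- which.max(y)
  resid_fn <- function(theta) sw * (y - .fit_model_rate(theta, tt))

  best <- NULL
  for (dk in config$k_start_spread) {
    kk <- min(max(k0 + dk, config$k_bounds[1] + 0.1),
              config$k_bounds[2] - 0.1)
    sen <- 1 - b0 * tt[ipk]
    a0 <- max(y[ipk], 1e-6) / 1e5 / (tt[ipk]^(kk - 1) * max(sen, 0.05))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(loga = log(a0), k = kk, b = b0),
        fn = resid_fn,
        lower = c(-Inf, config$k_bounds[1], -Inf),
        upper = c(Inf, config$k_bounds[2], Inf),
        control = minpack.lm::nls.lm.control(maxiter = config$maxiter)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
      best <- fit
  }
  if (is.null(best)) stop("Levenberg-Marquardt failed to converge from all starts")

  theta <- best$par
  n <- length(y); p <- 3L; df <- n - p
  resvar <- stats::deviance(best) / df
  covm <- tryCatch(solve(best$hessian) * resvar,
                   error = function(e) matrix(NA_real_, 3, 3))
  params <- model_params(a = exp(theta[["loga"]]), k = theta[["k"]],
                         b = theta[["b"]],
                         onset_offset = config$onset_offset)
  se_loga <- sqrt(covm[1, 1]); se_k <- sqrt(covm[2, 2]); se_b <- sqrt(covm[3, 3])
  # delta method for u = exp((log a + lgamma(k)) / k)
  g <- c(params$u / params$k,
         params$u * (digamma(params$k) - log(params$u)) / params$k,
         0)
  se_u <- sqrt(drop(t(g) %*% covm %*% g))
  wald_p <- function(est, se) 2 * stats::pt(-abs(est / se), df)
  p_u <- wald_p(params$u, se_u)
  p_k <- wald_p(params$k, se_k)
  p_b <- wald_p(params$b, se_b)

  derived <- list(peak_age = NA_real_, peak_rate = NA_real_,
                  cum_prob = NA_real_)
  if (params$k > 1 && params$b > 0) {
    pk <- model_peak(params)
    derived$peak_age <- pk$age
    derived$peak_rate <- pk$rate
  }
  derived$cum_prob <- suppressWarnings(cumulative_probability(params))

  structure(list(
    cancer_code = series$cancer_code[1], sex = series$sex[1],
    params = params,
    se = c(a = params$a * se_loga, u = se_u, k = se_k, b = se_b),
    p_values = c(u = p_u, k = p_k, b = p_b),
    deviance = stats::deviance(best), df = df, n_bins = n,
    start_age = config$start_age,
    derived = derived,
    included = is.finite(p_u) && is.finite(p_k) &&
      p_u <= config$p_threshold && p_k <= config$p_threshold),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit: %s (%s), %d bins from age %g\n",
              x$cancer_code, x$sex, x$n_bins, x$start_age))
  cat(sprintf("  u = %.4g (P=%.3g)  k = %.3g (P=%.3g)  b = %.4g\n",
              x$params$u, x$p_values["u"], x$params$k, x$p_values["k"],
              x$params$b))
  cat(sprintf("  peak %.3g per 1e5 at %.1f yr; lifetime Pc = %.3g; %s\n",
              x$derived$peak_rate, x$derived$peak_age, x$derived$cum_prob,
              if (x$included) "included" else "EXCLUDED (P > threshold)"))
  invisible(x)
}

#' Tabulate a collection of fit results
#'
#' @param results list of `fit_result` objects
#' @return data frame with one row per fit: parameters, standard errors,
#'   P-values, derived statistics and the inclusion flag
#' @export
fit_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(cancer_code = r$cancer_code, sex = r$sex,
               u_mu = r$params$u, k = r$params$k, b = r$params$b,
               a = r$params$a,
               se_u = r$se[["u"]], se_k = r$se[["k"]], se_b = r$se[["b"]],
               p_u = r$p_values[["u"]], p_k = r$p_values[["k"]],
               peak_age = r$derived$peak_age,
               peak_rate = r$derived$peak_rate,
               cum_prob = r$derived$cum_prob,
               included = r$included,
               stringsAsFactors = FALSE)
  }))
}

#' Apply the parameter P-value inclusion rules
#'
#' Flags fits whose u or k P-value exceeds the threshold (default 0.1) for
#' exclusion from downstream comparisons, and optionally applies the
#' colorectal substitution rule: drop the combined COADREAD row whenever
#' COAD and READ enter separately, so colorectal cases are not counted
#' twice.
#'
#' @param tbl a data frame from [fit_results_table()] (or any table with
#'   columns cancer_code, p_u, p_k)
#' @param p_threshold exclusion threshold for P(u), P(k)
#' @param drop_coadread drop the COADREAD row in favor of COAD + READ
#' @return list with `included` (filtered table) and `excluded` (log with
#'   a `reason` column)
#' @export
apply_inclusion_rules <- function(tbl, p_threshold = 0.1,
                                  drop_coadread = FALSE) {
  if (nrow(tbl) == 0)
    return(list(included = tbl, excluded = cbind(tbl[0, ], reason = character(0))))
  reason <- rep(NA_character_, nrow(tbl))
  bad_p <- !is.finite(tbl$p_u) | !is.finite(tbl$p_k) |
    tbl$p_u > p_threshold | tbl$p_k > p_threshold
  reason[bad_p] <- sprintf("P(u) or P(k) > %g", p_threshold)
  if (drop_coadread) {
    cr <- tbl$cancer_code == "COADREAD" & is.na(reason)
    reason[cr] <- "COAD and READ included separately"
  }
  list(included = tbl[is.na(reason), , drop = FALSE],
       excluded = cbind(tbl[!is.na(reason), , drop = FALSE],
                        reason = reason[!is.na(reason)]))
}
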