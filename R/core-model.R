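#' Multistage-senescence model parameters
#'
#' Container for the parameters describing one cancer type's age-specific
#' incidence curve \eqn{ASR(t) = a t^{k-1} (1 - bt)}: the amplitude
#' \eqn{a = u^k/\Gamma(k)}, the geometric-mean stage-transition rate
#' \eqn{u} (1/year), the number of carcinogenic stages \eqn{k} (a positive
#' real, not restricted to integers), and the senescence tumor-suppression
#' slope \eqn{b} (1/year).  For cancers of reproductive organs the clock
#' starts at puberty, so \code{onset_offset = 15} years is subtracted from
#' age before evaluating \eqn{t}; for all other cancers it is 0.
#'
#' Exactly one of \code{u} or \code{a} must be supplied; the other is
#' derived through \eqn{a = u^k/\Gamma(k)}.  \code{b} may be negative or
#' zero (a degenerate fit without old-age decline); when \code{b > 0} the
#' model support is \eqn{0 \le t \le 1/b} and the curve is truncated to
#' zero beyond it.
#'
#' @param u stage-transition rate, 1/year (> 0), or NULL if `a` is given
#' @param k number of carcinogenic stages (> 0)
#' @param b senescence tumor suppressor, 1/year (any sign)
#' @param a amplitude of the power law, or NULL if `u` is given
#' @param onset_offset 0 (non-reproductive) or 15 (reproductive), years
#' @return an object of class `model_params`
#' @export
model_params <- function(u = NULL, k, b = 0, a = NULL, onset_offset = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (!onset_offset %in% c(0, 15))
    stop("onset_offset must be 0 (non-reproductive) or 15 (reproductive)")
  if (is.null(u) == is.null(a))
    stop("supply exactly one of 'u' or 'a'")
  if (is.null(a)) {
    stopifnot(is.finite(u), u > 0)
    a <- a_from_u(u, k)
  } else {
    stopifnot(is.finite(a), a > 0)
    u <- u_from_a(a, k)
  }
  structure(list(a = a, u = u, k = k, b = b, onset_offset = onset_offset),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "multistage-senescence parameters: u = %.4g /yr, k = %.3g stages, b = %.4g /yr\n",
    x$u, x$k, x$b))
  cat(sprintf("  amplitude a = %.4g, onset offset = %d yr", x$a, x$onset_offset))
  if (x$b > 0) cat(sprintf(", support ends at t = %.1f yr", 1 / x$b))
  cat("\n")
  invisible(x)
}

#' Constants of the two-variable (age, stage) incidence model
#'
#' The two-variable model replaces the per-cancer transition rate by the
#' cross-cancer linear trend \eqn{u = c k - d}, so that incidence depends
#' only on age and the number of stages.  Defaults are the pooled-sex
#' non-reproductive estimates: b = 0.0099/yr, c = 0.0046/yr per stage,
#' d = 0.0087/yr.
#'
#' @param b senescence tumor suppressor, 1/year
#' @param c slope of the transition rate against stage number, 1/year/stage
#' @param d negated intercept of that trend, 1/year
#' @return an object of class `two_variable_constants`
#' @export
two_variable_constants <- function(b = 0.0099, c = 0.0046, d = 0.0087) {
  stopifnot(is.finite(b), is.finite(c), is.finite(d), b > 0)
  structure(list(b = b, c = c, d = d), class = "two_variable_constants")
}

#' Armitage-Doll power-law incidence rate
#'
#' \eqn{ASR(t) = u^k t^{k-1} / \Gamma(k)}: the hazard of completing the
#' last of k sequential stages by age t when every stage proceeds at the
#' same small rate u per year.  Computed in log space so that large k and
#' small u do not underflow.
#'
#' @param t age (or age since onset), years; vectorized
#' @param u stage-transition rate, 1/year
#' @param k number of stages (> 0)
#' @return rate per person-year, same length as `t`
#' @export
asr_power_law <- function(t, u, k) {
  stopifnot(all(is.finite(t)), all(t >= 0),
            is.finite(u), u > 0, is.finite(k), k > 0)
  if (k < 1 && any(t == 0))
    stop("t = 0 with k < 1: rate diverges")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(k * log(u) - lgamma(k) + (k - 1) * log(t[pos]))
  if (any(!pos)) out[!pos] <- if (k == 1) u else 0
  out
}

#' Multistage-senescence incidence rate
#'
#' \eqn{ASR(t) = a t^{k-1} (1 - bt)}, the power law damped by a linear
#' senescence tumor-suppression term that is unity at the time origin and
#' reaches zero at t = 1/b.  Beyond the support (t > 1/b when b > 0) the
#' rate is returned as 0 rather than as a negative hazard.
#'
#' @param t age since onset, years; vectorized
#' @param params a [model_params] object
#' @return rate per person-year
#' @export
asr_senescence <- function(t, params) {
  stopifnot(inherits(params, "model_params"), all(is.finite(t)), all(t >= 0))
  k <- params$k
  if (k < 1 && any(t == 0)) stop("t = 0 with k < 1: rate diverges")
  out <- numeric(length(t))
  sup <- t > 0 & (params$b <= 0 | t <= 1 / params$b)
  out[sup] <- exp(log(params$a) + (k - 1) * log(t[sup])) *
    (1 - params$b * t[sup])
  if (any(t == 0) && k == 1) out[t == 0] <- params$a
  out
}

#' Factor decomposition of the multistage-senescence rate
#'
#' Splits the rate into its three factors: A = \eqn{u^k/\Gamma(k)}, the
#' age-independent stage-transition-rate term; B = \eqn{t^{k-1}}, the
#' power-law growth term; C = \eqn{1 - bt}, the senescence
#' tumor-suppression term (equal to unity at the time origin).
#'
#' @inheritParams asr_senescence
#' @return a list with vectors `A`, `B`, `C`; `A * B * C` equals
#'   [asr_senescence()] inside the model support
#' @export
asr_factors <- function(t, params) {
  stopifnot(inherits(params, "model_params"), all(is.finite(t)), all(t >= 0))
  list(A = rep(params$a, length(t)),
       B = t^(params$k - 1),
       C = 1 - params$b * t)
}

#' Two-variable (age, stage) incidence rate
#'
#' Evaluates the senescence model with the transition rate replaced by the
#' cross-cancer trend \eqn{u = ck - d}, so incidence is a function of age
#' and stage number only.
#'
#' @param t age, years
#' @param k number of stages
#' @param consts a [two_variable_constants] object
#' @return rate per person-year
#' @export
asr_two_variable <- function(t, k, consts = two_variable_constants()) {
  stopifnot(inherits(consts, "two_variable_constants"))
  u <- consts$c * k - consts$d
  if (u <= 0)
    stop(sprintf("c*k - d = %.4g <= 0: two-variable model undefined at k = %g",
                 u, k))
  asr_senescence(t, model_params(u = u, k = k, b = consts$b))
}

#' Age of peak incidence, k/(b(k+1)) closed form
#'
#' The widely quoted closed-form peak age \eqn{T_p = k / (b (k+1))}.  Note
#' this expression maximizes \eqn{t^k (1-bt)}, i.e. the curve with one more
#' power of t than the incidence rate itself; the true maximizer of
#' \eqn{t^{k-1}(1-bt)} is returned by [peak_age_argmax()].  Both are in
#' circulation for this model; table-style derived statistics here use the
#' argmax form, while illustrative stage-vs-peak-age sequences use this one.
#'
#' @param k number of stages (> 0)
#' @param b senescence tumor suppressor, 1/year (> 0)
#' @return age in years
#' @export
peak_age_formula <- function(k, b) {
  stopifnot(all(k > 0))
  if (any(b <= 0)) stop("b <= 0: incidence has no finite peak age")
  k / (b * (k + 1))
}

#' Age of peak incidence, exact maximizer of the incidence curve
#'
#' Analytic argmax of \eqn{t^{k-1}(1-bt)}: \eqn{T_p = (k-1)/(bk)}.
#' Requires k > 1 (for k <= 1 the curve is non-increasing times the
#' senescence term and has no interior maximum) and b > 0.
#'
#' @param params a [model_params] object with k > 1 and b > 0
#' @return age since onset, years
#' @export
peak_age_argmax <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$b <= 0) stop("b <= 0: incidence has no finite peak age")
  if (params$k <= 1) stop("k <= 1: incidence curve has no interior maximum")
  (params$k - 1) / (params$b * params$k)
}

#' Peak of the modeled incidence curve
#'
#' Age (in calendar years, onset offset added back) and rate (per 100,000
#' person-years) at the maximum of the fitted curve.
#'
#' @param params a [model_params] object with k > 1, b > 0
#' @return list with `age` (years) and `rate` (per 1e5 person-years)
#' @export
model_peak <- function(params) {
  tp <- peak_age_argmax(params)
  list(age = tp + params$onset_offset,
       rate = 1e5 * asr_senescence(tp, params))
}

#' Lifetime cumulative probability of one cancer
#'
#' Integral of the modeled rate over the full support [0, 1/b]:
#' \eqn{P_c = a b^{-k} (1/k - 1/(k+1))}.  Interpreted as the lifetime risk
#' of that cancer in the absence of competing mortality.  Undefined when
#' b <= 0 (infinite support); returns NaN with a warning in that case,
#' mirroring degenerate fits.
#'
#' @param params a [model_params] object
#' @return probability, or NaN when b <= 0
#' @export
cumulative_probability <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$b <= 0) {
    warning("b <= 0: cumulative probability undefined (infinite support)")
    return(NaN)
  }
  with(params, exp(log(a) - k * log(b) + log(1 / k - 1 / (k + 1))))
}

#' Fractional reduction of lifetime risk attributable to senescence
#'
#' Compares the cumulative probability with the senescence term in place
#' against the same power-law curve integrated over the same span [0, 1/b]
#' with the (1 - bt) factor removed.  The amplitude cancels and the
#' reduction is k/(k+1) for any b > 0; both integrals are evaluated and
#' the ratio returned, so the identity is checkable rather than assumed.
#'
#' @param k number of stages (> 0)
#' @param b senescence tumor suppressor used for the integration limit
#' @return fraction in (0, 1)
#' @export
senescence_reduction <- function(k, b = 0.0099) {
  stopifnot(all(is.finite(k)), all(k > 0), b > 0)
  tmax <- 1 / b
  log_with <- k * log(tmax) + log(1 / k - 1 / (k + 1))
  log_without <- k * log(tmax) - log(k)
  1 - exp(log_with - log_without)
}

#' Transition rate from amplitude and back
#'
#' Inverse pair linking the fitted amplitude \eqn{a} of the power law to
#' the geometric-mean stage-transition rate: \eqn{u = (a \Gamma(k))^{1/k}}
#' and \eqn{a = u^k / \Gamma(k)}.  Both are computed in log space.
#'
#' @param a amplitude (> 0)
#' @param u transition rate, 1/year (> 0)
#' @param k number of stages (> 0)
#' @return `u_from_a`: rate in 1/year; `a_from_u`: amplitude
#' @export
u_from_a <- function(a, k) {
  stopifnot(all(a > 0), all(k > 0))
  exp((log(a) + lgamma(k)) / k)
}

#' @rdname u_from_a
#' @export
a_from_u <- function(u, k) {
  stopifnot(all(u > 0), all(k > 0))
  exp(k * log(u) - lgamma(k))
}

#' Lifetime risk of at least one cancer
#'
#' Combines per-cancer lifetime cumulative probabilities under
#' independence: \eqn{1 - \prod_i (1 - P_{c,i})}.
#'
#' @param pcs vector of per-cancer probabilities, each in [0, 1)
#' @param na.rm drop missing entries before combining
#' @return probability of at least one diagnosis
#' @export
lifetime_risk_any <- function(pcs, na.rm = FALSE) {
  if (na.rm) pcs <- pcs[!is.na(pcs)]
  stopifnot(all(is.finite(pcs)), all(pcs >= 0))
  if (any(pcs >= 1)) stop("per-cancer probabilities must be < 1")
  1 - prod(1 - pcs)
}
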