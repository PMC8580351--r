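#' Census-like per-bin person-years template
#'
#' A smooth population pyramid for the 23 standard bins: flat through late
#' middle age, declining exponentially from age 60, with the 85-and-over
#' total split into 5-year bins by [oldage_fractions()] so the old-age
#' population-inference path is exercised end to end.
#'
#' @param py_scale person-years per bin below age 60
#' @param fractions an [oldage_fractions()] split of the 85+ total
#' @return numeric vector of 23 per-bin person-years
#' @export
population_template <- function(py_scale = 1e7,
                                fractions = oldage_fractions(
                                  c(0.62, 0.26, 0.09, 0.025, 0.004, 0.001))) {
  young <- rep(py_scale, 12)                      # 0-4 ... 55-59
  decline <- py_scale * exp(-0.25 * (1:5))        # 60-64 ... 80-84
  pop85 <- py_scale * exp(-0.25 * 5) * 1.2        # aggregate 85+
  unname(c(young, decline, infer_oldage_populations(pop85, fractions)))
}

#' Specification of a synthetic registry cohort
#'
#' Bundles the ground-truth model parameters per cancer type, the per-bin
#' person-years (shared by both sexes), and the random seed that makes the
#' simulated registry reproducible.
#'
#' @param cancers data frame with columns cancer_code, u, k, b and logical
#'   reproductive
#' @param person_years per-bin person-years for the 23 standard bins
#' @param sexes which sexes to tabulate
#' @param seed integer random seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(cancers, person_years = population_template(),
                        sexes = c("male", "female"), seed = 1L) {
  stopifnot(all(c("cancer_code", "u", "k", "b", "reproductive") %in%
                  names(cancers)),
            length(person_years) == 23L, all(person_years > 0))
  structure(list(cancers = cancers, person_years = person_years,
                 sexes = sexes, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a registry of Poisson case counts
#'
#' Per bin, cancer type and sex, case counts are drawn independently as
#' Poisson with mean ASR(t) * person-years, where t is the bin midpoint
#' minus the onset offset and the rate is zero outside the model support
#' (so bins beyond t = 1/b expect zero cases).  Output uses exactly the
#' CSV schemas the rate-computation readers consume.
#'
#' @param spec a [cohort_spec()]
#' @param dir if non-NULL, write `cases.csv` and `population.csv` there
#' @return list with data frames `cases` (cancer_code, sex, age_group,
#'   cases) and `population` (sex, age_group, person_years); file paths
#'   attached as attribute `paths` when written
#' @export
simulate_registry <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mids <- age_bin_midpoints()
  labels <- age_bin_labels()
  case_rows <- list()
  for (i in seq_len(nrow(spec$cancers))) {
    ci <- spec$cancers[i, ]
    off <- if (isTRUE(ci$reproductive)) 15 else 0
    pars <- model_params(u = ci$u, k = ci$k, b = ci$b, onset_offset = off)
    tt <- pmax(mids - off, 0)
    lam <- ifelse(tt > 0, asr_senescence(tt, pars), 0) * spec$person_years
    if (any(lam > 1e9))
      stop("expected count exceeds 1e9 in a bin; rescale person-years")
    for (sx in spec$sexes) {
      case_rows[[length(case_rows) + 1L]] <- data.frame(
        cancer_code = ci$cancer_code, sex = sx, age_group = labels,
        cases = stats::rpois(length(lam), lam), stringsAsFactors = FALSE)
    }
  }
  cases <- do.call(rbind, case_rows)
  population <- do.call(rbind, lapply(spec$sexes, function(sx)
    data.frame(sex = sx, age_group = labels,
               person_years = spec$person_years, stringsAsFactors = FALSE)))
  out <- list(cases = cases, population = population)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pc <- file.path(dir, "cases.csv"); pp <- file.path(dir, "population.csv")
    utils::write.csv(cases, pc, row.names = FALSE)
    utils::write.csv(population, pp, row.names = FALSE)
    attr(out, "paths") <- c(cases = pc, population = pp)
  }
  out
}

#' Parameter-recovery experiment
#'
#' For each ground-truth (u, k, b) cell and person-year level: simulate a
#' registry, recompute crude rates, refit the model, and tabulate the
#' fitted parameters.  Deterministic under `seed` (replicate r of cell i
#' uses seed + 1000*i + r).
#'
#' @param truth data frame with columns u, k, b (one row per cell)
#' @param py_levels per-bin person-years levels (flat across bins)
#' @param replicates Poisson replicates per cell and level
#' @param seed base integer seed
#' @param start_age lower fitting-window limit passed to the fit
#' @return data frame with one row per fit: truth, py, replicate, fitted
#'   u_hat/k_hat/b_hat and their errors
#' @export
recovery_experiment <- function(truth, py_levels = 1e7, replicates = 20,
                                seed = 1L, start_age = 50) {
  stopifnot(all(c("u", "k", "b") %in% names(truth)))
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (py in py_levels) {
      for (r in seq_len(replicates)) {
        spec <- cohort_spec(
          cancers = data.frame(cancer_code = "SYN", u = truth$u[i],
                               k = truth$k[i], b = truth$b[i],
                               reproductive = FALSE),
          person_years = rep(py, 23), sexes = "male",
          seed = seed + 1000L * i + r)
        reg <- simulate_registry(spec)
        series <- build_series(reg$cases, reg$population, "SYN", "male")
        fit <- tryCatch(
          fit_series(series, fit_config(start_age = start_age)),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          u = truth$u[i], k = truth$k[i], b = truth$b[i], py = py,
          replicate = r,
          u_hat = if (is.null(fit)) NA_real_ else fit$params$u,
          k_hat = if (is.null(fit)) NA_real_ else fit$params$k,
          b_hat = if (is.null(fit)) NA_real_ else fit$params$b)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$err_u <- res$u_hat - res$u
  res$err_k <- res$k_hat - res$k
  res$err_b <- res$b_hat - res$b
  res
}

#' Bias and RMSE summary of a recovery experiment
#'
#' @param res output of [recovery_experiment()]
#' @return data frame with per-cell median bias and RMSE of u, k, b
#' @export
recovery_summary <- function(res) {
  agg <- function(f) stats::aggregate(
    cbind(err_u, err_k, err_b) ~ u + k + b + py, data = res, FUN = f,
    na.action = stats::na.omit)
  med <- agg(stats::median)
  rmse <- agg(function(e) sqrt(mean(e^2)))
  names(med)[5:7] <- c("bias_u", "bias_k", "bias_b")
  names(rmse)[5:7] <- c("rmse_u", "rmse_k", "rmse_b")
  merge(med, rmse, by = c("u", "k", "b", "py"))
}
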