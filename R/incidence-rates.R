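#' Standard 5-year age bins
#'
#' Registry tabulations use 5-year age groups "0-4" through "105-109" plus
#' an open-ended "110+", giving bin midpoints 2.5, 7.5, ..., 112.5 years.
#'
#' @return `age_bin_labels()`: character vector of 23 labels;
#'   `age_bin_midpoints()`: numeric vector of 23 midpoints in years.
#' @export
age_bin_labels <- function() {
  lo <- seq(0, 110, by = 5)
  c(paste(lo[-23], lo[-23] + 4, sep = "-"), "110+")
}

#' @rdname age_bin_labels
#' @export
age_bin_midpoints <- function() seq(2.5, 112.5, by = 5)

#' Parse age-group labels to bin midpoints
#'
#' Accepts "lo-hi" ranges and the open-ended "110+" (any "x+" maps to
#' x + 2.5, the midpoint it would have as a closed 5-year bin).
#'
#' @param labels character vector of age-group labels
#' @return numeric midpoints in years
#' @export
parse_age_group <- function(labels) {
  labels <- trimws(as.character(labels))
  open <- grepl("^[0-9]+\\+$", labels)
  rng  <- grepl("^[0-9]+-[0-9]+$", labels)
  if (!all(open | rng))
    stop("unparseable age-group labels: ",
         paste(unique(labels[!(open | rng)]), collapse = ", "))
  out <- numeric(length(labels))
  out[open] <- as.numeric(sub("\\+$", "", labels[open])) + 2.5
  lo <- as.numeric(sub("-.*$", "", labels[rng]))
  hi <- as.numeric(sub("^.*-", "", labels[rng]))
  out[rng] <- (lo + hi + 1) / 2
  out
}

#' Crude age-specific incidence rates with Poisson standard errors
#'
#' Converts per-bin case counts and person-years into crude rates per
#' 100,000 person-years.  The standard error is Poisson,
#' SE = sqrt(cases)/PY * 1e5.  Zero-case bins get a weighting SE computed
#' as if one case had been observed, so inverse-variance weights stay
#' finite and such bins remain in fits with low weight; the reported
#' `rate_se` for those bins is that substitute value.  Bins with zero
#' person-years are flagged invalid and excluded from fitting.
#'
#' @param cases non-negative integer case counts per bin
#' @param person_years person-years at risk per bin
#' @param midpoints bin midpoints in years (default the standard 23 bins)
#' @param cancer_code,sex optional labels carried along
#' @return a data frame of class `age_binned_series` with columns
#'   cancer_code, sex, age_mid, cases, person_years, rate, rate_se, valid
#' @export
compute_crude_rates <- function(cases, person_years,
                                midpoints = age_bin_midpoints(),
                                cancer_code = NA_character_,
                                sex = NA_character_) {
  stopifnot(length(cases) == length(person_years),
            length(cases) == length(midpoints))
  if (any(cases < 0, na.rm = TRUE)) stop("negative case counts")
  if (any(diff(midpoints) <= 0)) stop("bin midpoints must be increasing")
  if (any(person_years <= 0 & cases > 0))
    stop("cases observed in a bin with no person-years")
  valid <- is.finite(person_years) & person_years > 0 & is.finite(cases)
  rate <- rate_se <- rep(NA_real_, length(cases))
  rate[valid] <- cases[valid] / person_years[valid] * 1e5
  rate_se[valid] <- sqrt(pmax(cases[valid], 1)) / person_years[valid] * 1e5
  structure(
    data.frame(cancer_code = cancer_code, sex = sex,
               age_mid = midpoints, cases = cases,
               person_years = person_years,
               rate = rate, rate_se = rate_se, valid = valid,
               stringsAsFactors = FALSE),
    class = c("age_binned_series", "data.frame"))
}

#' Old-age population fractions
#'
#' Census-derived fractions of the 85-and-over population falling in each
#' of the bins 85-89, 90-94, 95-99, 100-104, 105-109 and 110+, used to
#' split a registry's aggregate 85+ person-years into 5-year bins.
#'
#' @param fractions numeric vector of 6 non-negative fractions summing to 1
#' @return an object of class `oldage_fractions`
#' @export
oldage_fractions <- function(fractions) {
  stopifnot(is.numeric(fractions), length(fractions) == 6L,
            all(is.finite(fractions)), all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("old-age fractions must sum to 1")
  structure(as.numeric(fractions), class = "oldage_fractions",
            bins = c("85-89", "90-94", "95-99", "100-104", "105-109", "110+"))
}

#' Split an aggregate 85+ population into 5-year bins
#'
#' Registry population tables often stop at an open "85+" group while the
#' incidence curve extends well beyond it; census fractions of the 85+
#' population are assumed to hold for the registry, so the per-bin
#' person-years are total * fraction.  The split conserves the total
#' exactly.
#'
#' @param pop_85plus_total aggregate person-years at ages 85 and over
#' @param fractions an [oldage_fractions] object
#' @return named numeric vector of person-years for the six old-age bins
#' @export
infer_oldage_populations <- function(pop_85plus_total, fractions) {
  stopifnot(inherits(fractions, "oldage_fractions"),
            is.finite(pop_85plus_total), pop_85plus_total >= 0)
  out <- pop_85plus_total * as.numeric(fractions)
  names(out) <- attr(fractions, "bins")
  out
}

#' Observed peak of an age-binned rate series
#'
#' Midpoint and rate of the maximum-rate valid bin among bins younger than
#' `max_age` (default 105 years, excluding the noisiest oldest bins).
#' Ties are broken toward the younger bin.
#'
#' @param series an `age_binned_series`
#' @param max_age upper age limit (exclusive) for the search, years
#' @return list with `age` and `rate`
#' @export
observed_peak <- function(series, max_age = 105) {
  stopifnot(inherits(series, "age_binned_series"))
  ok <- series$valid & series$age_mid < max_age & is.finite(series$rate)
  if (!any(ok)) stop("no valid bins below the age limit")
  cand <- series[ok, ]
  i <- which.max(cand$rate)   # which.max returns the first (youngest) tie
  list(age = cand$age_mid[i], rate = cand$rate[i])
}

#' Read registry-style case and population tables
#'
#' Case CSVs carry columns (cancer_code, sex, age_group, cases); population
#' CSVs carry (sex, age_group, person_years) with an optional leading
#' `registry` column, in which case person-years are summed over
#' registries.  Age-group labels are parsed with [parse_age_group()].
#'
#' @param path CSV file path
#' @return a data frame with an added `age_mid` column
#' @export
read_case_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cancer_code", "sex", "age_group", "cases")
  if (!all(need %in% names(df)))
    stop("case CSV must have columns: ", paste(need, collapse = ", "))
  df$age_mid <- parse_age_group(df$age_group)
  df
}

#' @rdname read_case_csv
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_group", "person_years")
  if (!all(need %in% names(df)))
    stop("population CSV must have columns: ", paste(need, collapse = ", "))
  if ("registry" %in% names(df)) {
    df <- stats::aggregate(person_years ~ sex + age_group, data = df, FUN = sum)
  }
  df$age_mid <- parse_age_group(df$age_group)
  df
}

#' Assemble one cancer/sex stratum into a rate series
#'
#' Joins a case table and a population table on (sex, age bin) for one
#' cancer type and computes crude rates.  `sex = "pooled"` sums cases and
#' person-years over both sexes before rate computation (a re-tabulation
#' of the incidence data, not an average of the per-sex estimates).
#'
#' @param cases_df data frame from [read_case_csv()]
#' @param pop_df data frame from [read_population_csv()]
#' @param cancer_code cancer type to extract
#' @param sex "male", "female" or "pooled"
#' @return an `age_binned_series`
#' @export
build_series <- function(cases_df, pop_df, cancer_code, sex) {
  if (is.null(cases_df$age_mid)) cases_df$age_mid <- parse_age_group(cases_df$age_group)
  if (is.null(pop_df$age_mid)) pop_df$age_mid <- parse_age_group(pop_df$age_group)
  sexes <- if (sex == "pooled") c("male", "female") else sex
  cc <- cases_df[cases_df$cancer_code == cancer_code &
                   cases_df$sex %in% sexes, ]
  pp <- pop_df[pop_df$sex %in% sexes, ]
  if (nrow(cc) == 0) stop("no case rows for ", cancer_code, " / ", sex)
  mids <- sort(unique(pp$age_mid))
  cases <- vapply(mids, function(m) sum(cc$cases[cc$age_mid == m]), 0)
  py <- vapply(mids, function(m) sum(pp$person_years[pp$age_mid == m]), 0)
  compute_crude_rates(cases, py, midpoints = mids,
                      cancer_code = cancer_code, sex = sex)
}

#' Write a rate series to CSV
#'
#' @param series an `age_binned_series`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
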