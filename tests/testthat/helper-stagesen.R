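# shared helpers: noise-free series and quick single-cancer simulations

`%||%` <- function(a, b) if (is.null(a)) b else a

noise_free_series <- function(u, k, b, py = 1e7, onset_offset = 0,
                              code = "SYN", sex = "male") {
  mids <- age_bin_midpoints()
  pars <- model_params(u = u, k = k, b = b, onset_offset = onset_offset)
  tt <- pmax(mids - onset_offset, 0)
  lam <- ifelse(tt > 0, asr_senescence(tt, pars), 0) * py
  compute_crude_rates(round(lam), rep(py, 23),
                      cancer_code = code, sex = sex)
}

simulated_series <- function(u, k, b, py = 1e7, seed = 1, code = "SYN") {
  spec <- cohort_spec(
    cancers = data.frame(cancer_code = code, u = u, k = k, b = b,
                         reproductive = FALSE),
    person_years = rep(py, 23), sexes = "male", seed = seed)
  reg <- simulate_registry(spec)
  build_series(reg$cases, reg$population, code, "male")
}
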