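test_that("population preprocessing normalizes to DMSO and cuts late times", {
  raw <- data.frame(
    time_h = c(10, 10, 10, 56, 10, 10),
    nominal_dose_nM = c(1, 0, 0, 1, 1, 0),
    replicate = 1,
    reporter = c("GREB1", "GREB1", "GREB1", "GREB1", "PR", "TFF1"),
    value = c(200, 90, 110, 500, 50, 30),
    treatment = c("E2", "DMSO", "DMSO", "E2", "E2", "DMSO"))
  out <- preprocess_population(raw)
  ## 200 / mean(90, 110) = 2; the t = 56 h row is dropped
  expect_equal(out$value[out$reporter == "GREB1"], 2)
  expect_false(any(out$time_h > 55))
  ## the PR row has no matched control: excluded and counted
  expect_false("PR" %in% out$reporter)
  expect_equal(attr(out, "excluded")$missing_control, 1)
  expect_equal(attr(out, "excluded")$after_t_max, 1)
})

test_that("cell counts are normalized to the first timepoint", {
  raw <- data.frame(
    time_h = c(0, 24), nominal_dose_nM = 1, replicate = 1,
    reporter = "count", value = c(50, 100), treatment = "E2")
  out <- preprocess_population(raw)
  expect_equal(out$value, c(1, 2))
})

test_that("Latin hypercube starts stratify, respect fixed, and reproduce", {
  b <- data.frame(name = "x", lower = 0, upper = 1, log = FALSE)
  s <- latin_hypercube_init(4, b, seed = 2)
  ## exactly one point per quartile
  expect_equal(sort(findInterval(s[, "x"], c(0, 0.25, 0.5, 0.75, 1))),
               1:4)
  expect_identical(latin_hypercube_init(4, b, seed = 2), s)
  expect_false(identical(latin_hypercube_init(4, b, seed = 3), s))
  cfg <- fit_config(fixed = list(stim_PR = 1, GREB1_init = 0.5))
  bounds <- estrocycle:::.fit_bounds("III", c(0.001, 1), cfg)
  expect_false(any(c("stim_PR", "GREB1_init") %in% bounds$name))
  expect_true("eff_1" %in% bounds$name)
  expect_false("eff_0.001" %in% bounds$name)  # lowest dose pinned
})

test_that("candidate parameter vectors always satisfy derived synthesis", {
  cfg <- fit_config()
  doses <- c(0.001, 1)
  bounds <- estrocycle:::.fit_bounds("III", doses, cfg)
  set.seed(1)
  v <- stats::setNames(exp(stats::runif(nrow(bounds), -3, 0)), bounds$name)
  p <- estrocycle:::.vec_to_params(v, "III", doses, cfg, sig_params("III"))
  expect_equal(p$s_GREB1, p$d_GREB1 * p$GREB1_init)
  expect_equal(p$s_PR, p$d_PR * p$PR_init)
  expect_equal(p$s_TFF1, p$d_TFF1 * p$TFF1_init)
  expect_equal(p$s_ER, p$d_ER * p$ER_init)
  expect_equal(unname(p$dose_map[1]), 0.001)
})

test_that("degradation fitting recovers exact and noisy decay rates", {
  t <- seq(0, 24, 3)
  exact <- data.frame(time_h = t, reporter = "GREB1",
                      value = 10 * exp(-0.1 * t))
  f <- fit_degradation(exact)
  expect_equal(unname(coef(f)["d_GREB1"]), 0.1, tolerance = 1e-6)
  const <- data.frame(time_h = t, reporter = "PR", value = rep(5, length(t)))
  expect_equal(unname(coef(fit_degradation(const))["d_PR"]), 0)
  set.seed(8)
  tn <- rep(c(0, 12, 24), 3)
  noisy <- data.frame(time_h = tn, reporter = "TFF1",
                      value = 7 * exp(-0.08 * tn) *
                        rlnorm(length(tn), 0, 0.05))
  expect_equal(unname(coef(fit_degradation(noisy))["d_TFF1"]), 0.08,
               tolerance = 0.2)
  expect_error(fit_degradation(data.frame(time_h = 1, reporter = "PR",
                                          value = 0)), "positive")
})

test_that("small multi-start fit runs, clusters, and reports best = min", {
  cfg <- synth_config(seed = 21, noise_sd = 0, doses_nM = c(0.001, 1, 100),
                      times_h = seq(0, 55, 5), replicates = 1)
  gd <- gen_expression_data("I", config = cfg)
  fit <- suppressWarnings(
    fit_signaling("I", gd$data, fit_config(n_starts = 4, seed = 3,
                                           max_iter = 15)))
  expect_s3_class(fit, "sig_fit")
  expect_equal(fit$cost, min(fit$starts$cost))
  expect_true(all(!is.na(fit$starts$cluster[fit$starts$converged])))
  expect_equal(sort(unique(fit$starts$cluster)),
               seq_len(max(fit$starts$cluster)))
  ## predict returns observables on the data grid for every dose
  pr <- predict(fit)
  expect_setequal(unique(pr$nominal_dose_nM), c(0.001, 1, 100))
  expect_true(all(c("GREB1_total", "PR_total", "TFF1") %in% names(pr)))
  expect_error(fit_signaling("I", gd$data[gd$data$time_h < 20, ],
                             fit_config(n_starts = 2)), "5 timepoints")
})

test_that("fits require minimally informative data", {
  d <- data.frame(time_h = rep(0:9, 2), nominal_dose_nM = rep(c(1, 1), each = 10),
                  replicate = 1, reporter = "GREB1", value = 1)
  expect_error(fit_signaling("I", d, fit_config(n_starts = 1)),
               "at least 2 doses")
})
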