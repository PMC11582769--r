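test_that("extended oscillator reduces exactly to the base model", {
  base <- base_cycle_params()
  ext <- cycle_params(scale_div = 1, k_GREB1 = 0, r = 1)
  set.seed(4)
  for (i in 1:10) {
    st <- c(CDK1 = runif(1, 0, 1), APC = runif(1, 0, 1))
    ## r * E2_ER * PR == 1 and k_GREB1 = 0 must reproduce base rates exactly
    d_ext <- cycle_rhs(st, ext, GREB1 = runif(1, 0, 10), E2_ER = 2,
                       PR = 0.5)
    d_base <- cycle_rhs(st, base, GREB1 = 0, E2_ER = 1, PR = 1)
    expect_equal(d_ext, d_base)
  }
})

test_that("APC activation flux vanishes at APC = 1", {
  p <- cycle_params()
  d <- cycle_rhs(c(CDK1 = 0.5, APC = 1), p, GREB1 = 1, E2_ER = 0.1, PR = 0.5)
  expect_lte(d[["APC"]], 0)
})

test_that("APC stays within [0,1] and CDK1 non-negative along integrations", {
  p <- base_cycle_params()
  for (init in list(c(CDK1 = 0.9, APC = 0.05), c(CDK1 = 0.01, APC = 0.99))) {
    tr <- simulate_cycle(p, seq(0, 60, 0.05), init = init,
                         GREB1 = 0, E2_ER = 1, PR = 1)
    expect_true(all(tr$APC >= -1e-9 & tr$APC <= 1 + 1e-9))
    expect_true(all(tr$CDK1 >= -1e-9))
  }
})

test_that("oscillation detector handles constants and sinusoids", {
  t <- seq(0, 480, 1)
  expect_false(detect_oscillation(t, rep(0.3, length(t)))$oscillates)
  o <- detect_oscillation(t, sin(2 * pi * t / 48) + 1)
  expect_true(o$oscillates)
  expect_equal(o$period, 48, tolerance = 0.5 / 48)
  expect_error(detect_oscillation(t[1:4], t[1:4]), "too short")
})

test_that("rescaling the five rate constants rescales the period", {
  base <- base_cycle_params()
  tr1 <- simulate_cycle(base, seq(0, 400, 0.01), GREB1 = 0, E2_ER = 1, PR = 1)
  p1 <- detect_oscillation(tr1, t_tail = 200)
  expect_true(p1$oscillates)
  sc <- base_cycle_params(scale_div = 11)
  tr11 <- simulate_cycle(sc, seq(0, 4400, 0.1), GREB1 = 0, E2_ER = 1, PR = 1)
  p11 <- detect_oscillation(tr11, t_tail = 2200)
  expect_true(p11$oscillates)
  expect_equal(p11$period / p1$period, 11, tolerance = 0.01)
})

test_that("phase classifier applies the 5% threshold rule", {
  ## synthetic triangle waves with analytically known extrema and crossings
  t <- seq(0, 40, 0.5)
  tri <- function(t, per) {
    ph <- (t %% per) / per
    ifelse(ph < 0.5, 2 * ph, 2 - 2 * ph)
  }
  apc <- 0.2 + 0.8 * tri(t + 5, 20)   # min 0.2, max 1.0
  cdk <- 0.1 + 0.7 * tri(t, 20)
  seq_ <- classify_phases(t, cdk, apc)
  expect_false(seq_$arrested)
  expect_equal(seq_$apc_threshold, 0.2 + 0.05 * 0.8)  # min + 5% of range
  expect_setequal(as.character(unique(seq_$phases)), c("G1", "G1S", "SG2M"))
  ## transitions alternate legally
  ev <- seq_$transitions
  legal <- c(G1 = "G1S", G1S = "SG2M", SG2M = "G1")
  expect_true(all(legal[ev$from] == ev$to))
})

test_that("a trajectory without interior APC extrema is an arrest verdict", {
  t <- seq(0, 50, 0.5)
  seq_ <- classify_phases(t, exp(-t / 10), 1 - exp(-t / 10))
  expect_true(seq_$arrested)
  expect_true(all(seq_$phases == "G1"))
  expect_equal(nrow(phase_durations_insilico(seq_)), 0)
})

test_that("phase durations per cycle sum to the oscillation period", {
  p <- cycle_params()
  sp <- sig_params("III")
  st <- signaling_steady_state("III", sp, 0.156)$state
  tr <- simulate_cycle(p, seq(0, 700, 0.1), GREB1 = st[["GREB1"]],
                       E2_ER = st[["E2_ER"]], PR = st[["PR"]])
  osc <- detect_oscillation(tr, t_tail = 300)
  expect_true(osc$oscillates)
  expect_equal(osc$period, 48, tolerance = 0.02)
  tail_tr <- tr[tr$time >= 300, ]
  seq_ <- classify_phases(tail_tr)
  durs <- phase_durations_insilico(seq_)
  complete <- durs[durs$complete, ]
  expect_equal(nrow(complete[complete$phase == "G1", ]) > 2, TRUE)
  ## one full cycle: G1 + G1S + SG2M within one grid step of the period
  for (cyc in unique(complete$cycle_index)) {
    d <- complete[complete$cycle_index == cyc, ]
    if (nrow(d) == 3)
      expect_equal(sum(d$duration_h), osc$period, tolerance = 0.2 / 48)
  }
})

test_that("limit-cycle state sampling is seeded and on the cycle", {
  p <- base_cycle_params(scale_div = 11)
  tr <- simulate_cycle(p, seq(0, 2000, 0.25), GREB1 = 0, E2_ER = 1, PR = 1)
  s1 <- sample_initial_states(tr, 20, seed = 5)
  s2 <- sample_initial_states(tr, 20, seed = 5)
  s3 <- sample_initial_states(tr, 20, seed = 6)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(s1$CDK1, s3$CDK1)))
  ## sampled states lie on the trajectory (distance below grid tolerance)
  for (i in seq_len(5)) {
    d <- sqrt((tr$CDK1 - s1$CDK1[i])^2 + (tr$APC - s1$APC[i])^2)
    expect_lt(min(d), 0.02)
  }
  expect_error(sample_initial_states(
    data.frame(time = 1:20, CDK1 = rep(1, 20), APC = rep(0.5, 20)), 5),
    "no sustained limit cycle")
})

test_that("oscillations are lost outside the coupling bands", {
  sp <- sig_params("III")
  st <- signaling_steady_state("III", sp, 0.156)$state
  sim <- function(cp) {
    tr <- simulate_cycle(cp, seq(0, 1500, 0.25), GREB1 = st[["GREB1"]],
                         E2_ER = st[["E2_ER"]], PR = st[["PR"]])
    detect_oscillation(tr, t_tail = 500)$oscillates
  }
  expect_true(sim(cycle_params()))
  ## strong GREB1 drive pins CDK1 high
  expect_false(sim(cycle_params(k_GREB1 = 100 * cycle_params()$k_GREB1)))
  ## APC inactivation too weak or too strong
  expect_false(sim(cycle_params(r = cycle_params()$r / 50)))
  expect_false(sim(cycle_params(r = cycle_params()$r * 30)))
})

test_that("coupling is strictly one-way", {
  sp <- sig_params("III")
  cp <- cycle_params()
  tg <- seq(0, 40, 0.5)
  a <- simulate_coupled("III", sp, cp, e2_free(0.837), tg,
                        cyc_init = c(CDK1 = 0.1, APC = 0.1))
  b <- simulate_coupled("III", sp, cp, e2_free(0.837), tg,
                        cyc_init = c(CDK1 = 0.8, APC = 0.6))
  sig_cols <- signaling_states("III")
  expect_equal(a[, sig_cols], b[, sig_cols], tolerance = 1e-6)
})

test_that("signaling arrest suppresses oscillations in the coupled system", {
  sp <- sig_params("III")
  cp <- cycle_params()
  tr <- simulate_coupled("III", sp, cp, e2_clamp(0), seq(0, 300, 0.25))
  expect_false(detect_oscillation(tr, t_tail = 150)$oscillates)
})
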