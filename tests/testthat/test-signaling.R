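test_that("saturating rate matches its closed form and bounds", {
  expect_equal(saturating_rate(1, 0, 7), 0)
  expect_equal(saturating_rate(0.5, 2, 3), 0.5)
  v <- saturating_rate(0.3, 1e4, 1)
  expect_lt(v, 0.3)          # bounded by p * min(X, Y)
  expect_gt(v, 0.29)
  expect_error(saturating_rate(0.3, -1, 1), "non-negative")
})

test_that("synthesis derivation enforces the steady-state constraint", {
  p <- sig_params("I", d_GREB1 = 0.2, GREB1_init = 4)
  expect_equal(p$s_GREB1, 0.8)
  p0 <- sig_params("I", d_ER = 0, ER_init = 5)
  expect_equal(p0$s_ER, 0)
  ## rhs at the unexposed initial state is exactly zero for all models
  for (m in c("I", "II", "III")) {
    pm <- sig_params(m)
    st <- initial_state(m, pm, e2_free(0))
    expect_equal(unname(model_rhs(m, st, pm)),
                 rep(0, length(st)))
  }
})

test_that("72 h unexposed trajectories stay flat (steady-state closure)", {
  for (m in c("I", "II", "III")) {
    pm <- sig_params(m)
    tr <- simulate_signaling(m, pm, e2_clamp(0), seq(0, 72, by = 4))
    st <- initial_state(m, pm, e2_clamp(0))
    ref <- pmax(abs(st), 1e-3)
    drift <- max(abs(t(as.matrix(tr[, -1])) - st) / ref)
    expect_lt(drift, 1e-8)
  }
})

test_that("compiled integrator matches the reference R right-hand side", {
  for (m in c("I", "II", "III")) {
    p <- sig_params(m)
    tg <- seq(0, 30, 2)
    tr_c <- simulate_signaling(m, p, e2_free(0.5), tg)
    fn <- function(t, y, parms) {
      y[y < 0] <- 0
      list(model_rhs(m, y, parms))
    }
    tr_r <- deSolve::lsoda(initial_state(m, p, e2_free(0.5)), tg, fn, p,
                           rtol = 1e-8, atol = 1e-10)
    expect_equal(as.matrix(tr_c[, -1]),
                 unname(tr_r[, -1]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("zero-degradation Model I conserves E2-containing mass", {
  p <- sig_params("I", d_ER = 0, d_E2_ER = 0, d_E2_ER_GREB1 = 0,
                  d_GREB1 = 0, d_PR = 0, d_TFF1 = 0,
                  stim_GREB1 = 0, stim_PR = 0, stim_TFF1 = 0, ER_init = 0)
  # ER_init = 0 makes s_ER = 0; seed ER directly so binding still occurs
  st <- initial_state("I", p, e2_free(1))
  st["ER"] <- 2
  tr <- simulate_signaling("I", p, e2_free(1), seq(0, 100, 5), init = st)
  mass <- tr$E2 + tr$E2_ER + tr$E2_ER_GREB1
  expect_lt(max(abs(mass - mass[1])), 1e-7)
})

test_that("free E2 is strictly non-increasing (no synthesis term)", {
  p <- sig_params("I")
  tr <- simulate_signaling("I", p, e2_free(1), 0:50)
  expect_true(all(diff(tr$E2) <= 1e-12))
})

test_that("integration is non-negative and grid-converged", {
  p <- sig_params("III")
  tr <- simulate_signaling("III", p, e2_free(0.837), seq(0, 100, 1))
  expect_true(all(as.matrix(tr[, -1]) > -1e-9))
  tr2 <- simulate_signaling("III", p, e2_free(0.837), seq(0, 100, 0.5))
  end1 <- unlist(tr[nrow(tr), -1])
  end2 <- unlist(tr2[nrow(tr2), -1])
  expect_lt(max(abs(end1 - end2) / pmax(abs(end2), 1e-8)), 1e-6)
})

test_that("clamping holds E2 fixed and preserves the steady state", {
  p <- sig_params("III")
  tr <- simulate_signaling("III", p, e2_clamp(0.2), seq(0, 20, 2))
  expect_true(all(tr$E2 == 0.2))
})

test_that("knockdown removes only the target's sources", {
  p <- sig_params("III")
  ## PR knocked down from PR = 0 stays 0
  st <- initial_state("III", p, e2_free(0.837))
  st["PR"] <- 0
  tr <- simulate_signaling("III", p, e2_free(0.837), 0:48, knockdown = "PR",
                           init = st)
  expect_true(all(abs(tr$PR) < 1e-10))
  ## GREB1 knockdown: free GREB1 declines monotonically
  trg <- simulate_signaling("III", p, e2_free(0.837), 0:48,
                            knockdown = "GREB1")
  expect_true(all(diff(trg$GREB1) < 1e-10))
  ## empty target set is the identity
  st2 <- random_states("III", 1, seed = 3)[[1]]
  expect_identical(model_rhs("III", st2, p, knockdown = character()),
                   model_rhs("III", st2, p))
  rhs_kd <- apply_knockdown("III", "TFF1")
  d <- rhs_kd(st2, p)
  d0 <- model_rhs("III", st2, p)
  expect_equal(d[names(d) != "TFF1"], d0[names(d0) != "TFF1"])
  expect_error(apply_knockdown("III", "ESR1"), "unknown knockdown")
})

test_that("observable totals sum free and complexed forms", {
  p <- sig_params("III")
  df <- data.frame(time = 0, E2 = 0, ER = 1, E2_ER = 0, E2_ER_PR = 0.2,
                   E2_ER_PR_GREB1 = 0.5, GREB1 = 1, PR = 0.1, TFF1 = 0.3)
  ot <- observable_totals(df, "III")
  expect_equal(ot$GREB1_total, 1.5)
  expect_equal(ot$PR_total, 0.1 + 0.2 + 0.5)
  expect_equal(ot$TFF1, 0.3)
  ## all complexes zero: totals equal free forms
  df0 <- transform(df, E2_ER_PR = 0, E2_ER_PR_GREB1 = 0)
  ot0 <- observable_totals(df0, "III")
  expect_equal(ot0$GREB1_total, df0$GREB1)
  expect_equal(ot0$PR_total, df0$PR)
})

test_that("Model I/II printed-equation switch drops the consumption flux", {
  st <- random_states("I", 1, seed = 5)[[1]]
  p_cons <- sig_params("I", greb1_consumption = TRUE)
  p_print <- sig_params("I", greb1_consumption = FALSE)
  d1 <- model_rhs("I", st, p_cons)
  d2 <- model_rhs("I", st, p_print)
  fG <- saturating_rate(p_cons$b_E2_ER_GREB1, st[["E2_ER"]], st[["GREB1"]])
  expect_equal(d2[["GREB1"]] - d1[["GREB1"]], fG)
  same <- setdiff(names(d1), "GREB1")
  expect_equal(d1[same], d2[same])
})

test_that("steady-exposure observables are non-decreasing in effective dose", {
  p <- sig_params("III")
  effs <- vapply(c(0.001, 0.1, 10, 100), function(d) effective_dose(p, d),
                 numeric(1))
  tots <- sapply(effs, function(e) {
    st <- signaling_steady_state("III", p, e, tol = 1e-7)$state
    df <- as.data.frame(t(st)); df$time <- 0
    unlist(observable_totals(df, "III")[, c("GREB1_total", "PR_total",
                                            "TFF1")])
  })
  for (i in 1:3) expect_true(all(diff(tots[i, ]) > -1e-8))
})

test_that("dose map interpolates and validates", {
  p <- sig_params("III")
  expect_equal(effective_dose(p, 100), 0.837)
  expect_equal(effective_dose(p, 0.055), 0.104)
  expect_equal(effective_dose(p, 0), 0)
  mid <- effective_dose(p, 0.3)
  expect_true(mid > effective_dose(p, 0.1) && mid < effective_dose(p, 1))
  expect_error(effective_dose(p, 5000), "outside")
})

test_that("parameter constructor enforces bounds and knows its fields", {
  expect_error(sig_params("III", d_PR = 1.5), "lie in")
  expect_error(sig_params("III", nonsense = 1), "unknown signaling")
  expect_error(sig_params("III", stim_PR = 2e3), "lie in")
})
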