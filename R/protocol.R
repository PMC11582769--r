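#' Define an in-silico experimental protocol
#'
#' Mirrors the wet-lab flow: culture in complete medium (E2-equivalent
#' clamp), an optional 24 h siRNA knockdown phase (still in complete-medium
#' clamp), a 24 h starvation phase with E2 fixed at 0, and an exposure phase
#' in which E2 starts at the effective dose and is then depleted freely.
#' Knockdown targets persist through every later phase.
#'
#' @param dose_nM Nominal exposure dose in nM (0 = control, no E2).
#' @param knockdown Character vector of knockdown targets (GREB1/PR/TFF1),
#'   or NULL for mock.
#' @param e2_culture Clamped culture E2-equivalent concentration
#'   (default [estimate_e2_equivalent()]`(0.104, 1.5)` = 0.156).
#' @param starvation_h,exposure_h,knockdown_h Phase durations (h).
#' @param params `sig_params` used to translate `dose_nM` into an effective
#'   concentration.
#' @return A `protocol` object: ordered list of phases with name, duration,
#'   `e2_mode` and knockdown targets.
#' @export
protocol <- function(dose_nM = 100, knockdown = NULL,
                     e2_culture = estimate_e2_equivalent(0.104, 1.5),
                     starvation_h = 24, exposure_h = 100, knockdown_h = 24,
                     params = sig_params("III")) {
  if (!is.null(knockdown)) {
    bad <- setdiff(knockdown, c("GREB1", "PR", "TFF1"))
    if (length(bad)) stop("unknown knockdown target(s): ", paste(bad, collapse = ", "))
  }
  eff <- if (dose_nM <= 0) 0 else effective_dose(params, dose_nM)
  phases <- list(list(name = "culture", duration = NA_real_,
                      e2_mode = e2_clamp(e2_culture), knockdown = character()))
  if (!is.null(knockdown) && length(knockdown))
    phases <- c(phases, list(list(name = "knockdown", duration = knockdown_h,
                                  e2_mode = e2_clamp(e2_culture),
                                  knockdown = knockdown)))
  kd <- if (is.null(knockdown)) character() else knockdown
  phases <- c(phases,
              list(list(name = "starvation", duration = starvation_h,
                        e2_mode = e2_clamp(0), knockdown = kd)),
              list(list(name = "exposure", duration = exposure_h,
                        e2_mode = e2_free(eff), knockdown = kd)))
  structure(list(phases = phases, dose_nM = dose_nM, effective_dose = eff),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat("In-silico protocol, nominal dose ", x$dose_nM, " nM (effective ",
      signif(x$effective_dose, 3), ")\n", sep = "")
  for (ph in x$phases)
    cat(sprintf("  %-10s %6s h  E2 %s(%.3g)%s\n", ph$name,
                ifelse(is.na(ph$duration), "eq.", format(ph$duration)),
                ph$e2_mode$mode, ph$e2_mode$value,
                if (length(ph$knockdown))
                  paste0("  KD: ", paste(ph$knockdown, collapse = "+")) else ""))
  invisible(x)
}

#' Elementary starvation degradation model
#'
#' During starvation the three reporters decay exponentially:
#' `dX/dt = -d_X * X`, with closed form `X(t) = X0 * exp(-d * t)`.
#'
#' @param state Named vector `c(GREB1, PR, TFF1)`.
#' @param params Named list/vector with `d_GREB1`, `d_PR`, `d_TFF1` (1/h,
#'   distinct from, and typically lower than, the full-model rates).
#' @return Named derivative vector.
#' @export
degradation_rhs <- function(state, params) {
  if (any(state < 0)) stop("degradation_rhs: state must be non-negative")
  p <- as.list(params)
  c(GREB1 = -p$d_GREB1 * state[["GREB1"]],
    PR = -p$d_PR * state[["PR"]],
    TFF1 = -p$d_TFF1 * state[["TFF1"]])
}

#' @rdname degradation_rhs
#' @param t Time (h).
#' @param state0 Initial state.
#' @export
degradation_solution <- function(state0, params, t) {
  p <- as.list(params)
  d <- c(GREB1 = p$d_GREB1, PR = p$d_PR, TFF1 = p$d_TFF1)
  outer(t, d, function(tt, dd) exp(-dd * tt)) *
    rep(state0[c("GREB1", "PR", "TFF1")], each = length(t))
}

#' E2-equivalent concentration of complete medium
#'
#' The complete-medium E2-equivalent is the effective concentration at the
#' bracket-midpoint nominal dose multiplied by the complete-to-starved
#' expression ratio (`0.104 * 1.5 = 0.156` with the default anchors).
#'
#' @param effective_at_bracket_mid Effective concentration at the nominal
#'   bracket midpoint (a.u.).
#' @param complete_to_starved_ratio Expression ratio of complete medium to
#'   24 h-starved medium.
#' @return Effective E2-equivalent concentration (a.u.).
#' @export
estimate_e2_equivalent <- function(effective_at_bracket_mid,
                                   complete_to_starved_ratio) {
  stopifnot(effective_at_bracket_mid > 0, complete_to_starved_ratio > 0)
  effective_at_bracket_mid * complete_to_starved_ratio
}

#' @rdname estimate_e2_equivalent
#' @param lo,hi Bracketing nominal doses (nM).
#' @export
dose_bracket_midpoint <- function(lo, hi) (lo + hi) / 2

#' Run the full protocol for a population of virtual cells
#'
#' Phase 1 (culture) integrates the signaling model under the culture clamp
#' to steady state and the oscillator to its limit cycle; `n_cells` initial
#' CDK1/APC states are then sampled at random timepoints within one period.
#' The remaining phases (optional knockdown, starvation, exposure) are
#' simulated once for the signaling layer (one-way coupling) and per cell
#' for the oscillator, after which phases and durations are classified per
#' cell over the exposure window.
#'
#' @param model_id Signaling model (default "III").
#' @param sig_params,cyc_params Parameter objects.
#' @param protocol A [protocol()].
#' @param n_cells Number of virtual cells (default 100).
#' @param seed RNG seed for the initial-state sampling.
#' @param dt Output grid step (h).
#' @return A `protocol_sim` object: list with `signaling` (trajectory over
#'   the post-culture phases, time 0 = start of first non-culture phase),
#'   `cells` (long data.frame cell, time, CDK1, APC), `phase_calls`,
#'   `durations`, `culture` (steady state, limit-cycle period), `arrest`
#'   (per-cell logical for the exposure window), and the call metadata.
#' @export
run_protocol <- function(model_id = "III", sig_params = NULL,
                         cyc_params = NULL, protocol = NULL,
                         n_cells = 100, seed = 1L, dt = 0.1) {
  if (is.null(sig_params)) sig_params <- sig_params(model_id)
  if (is.null(cyc_params)) cyc_params <- cycle_params()
  if (is.null(protocol)) protocol <- protocol(params = sig_params)

  phases <- protocol$phases
  stopifnot(phases[[1]]$name == "culture")
  culture <- phases[[1]]
  later <- phases[-1]

  ## phase 1: signaling steady state + oscillator limit cycle
  ss <- signaling_steady_state(model_id, sig_params,
                               culture$e2_mode$value)
  st <- ss$state
  lc <- simulate_cycle(cyc_params, seq(0, 2400, by = 0.25),
                       GREB1 = st[["GREB1"]], E2_ER = st[["E2_ER"]],
                       PR = st[["PR"]])
  osc <- detect_oscillation(lc, t_tail = 600)
  if (!osc$oscillates) {
    return(structure(list(arrest_in_culture = TRUE, culture = list(
      state = st, residual = ss$residual, oscillation = osc)),
      class = "protocol_sim"))
  }
  inits <- sample_initial_states(lc, n_cells, seed = seed)

  ## later phases: signaling once, cells individually
  sig_traj <- NULL
  s_cur <- st
  t_off <- 0
  seg_info <- list()
  for (ph in later) {
    tg <- seq(0, ph$duration, by = dt)
    e2m <- ph$e2_mode
    init <- s_cur
    init["E2"] <- e2m$value  # clamp level, or the instantaneous exposure spike
    tr <- simulate_signaling(model_id, sig_params, e2m, tg,
                             knockdown = ph$knockdown, init = init)
    s_cur <- unlist(tr[nrow(tr), signaling_states(model_id)])
    s_cur[s_cur < 0] <- 0
    tr$time <- tr$time + t_off
    seg <- as.data.frame(tr); seg$phase_name <- ph$name
    seg_info[[ph$name]] <- c(start = t_off, end = t_off + ph$duration)
    sig_traj <- rbind(sig_traj, if (is.null(sig_traj)) seg else seg[-1, ])
    t_off <- t_off + ph$duration
  }
  fG <- stats::approxfun(sig_traj$time, sig_traj$GREB1, rule = 2)
  fE <- stats::approxfun(sig_traj$time, sig_traj$E2_ER, rule = 2)
  fP <- stats::approxfun(sig_traj$time, sig_traj$PR, rule = 2)

  t_all <- seq(0, t_off, by = dt)
  exp_win <- seg_info[["exposure"]]
  cells <- vector("list", n_cells)
  calls <- vector("list", n_cells)
  durs <- vector("list", n_cells)
  arrest <- logical(n_cells)
  n_peaks <- integer(n_cells)
  final_cdk1 <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    ctr <- simulate_cycle(cyc_params, t_all,
                          init = c(CDK1 = inits$CDK1[i], APC = inits$APC[i]),
                          GREB1 = fG, E2_ER = fE, PR = fP)
    cells[[i]] <- data.frame(cell = i, ctr)
    keep <- ctr$time >= exp_win["start"]
    sub <- ctr[keep, ]
    ph <- classify_phases(sub)
    calls[[i]] <- data.frame(cell = i, time = sub$time, phase = ph$phases)
    dd <- phase_durations_insilico(ph)
    if (nrow(dd)) durs[[i]] <- data.frame(cell = i, dd)
    ## arrest = no repeated CDK1 cycling in the exposure window (a single
    ## terminal spike from completing the ongoing cycle is allowed)
    pk <- .local_extrema(sub$time, sub$CDK1, "max")
    pk <- pk[pk$value - min(sub$CDK1) > 0.05 * max(diff(range(sub$CDK1)),
                                                   .Machine$double.eps), ]
    n_peaks[i] <- nrow(pk)
    final_cdk1[i] <- mean(sub$CDK1[sub$time >= max(sub$time) - 5])
    arrest[i] <- n_peaks[i] < 2
  }
  structure(list(
    signaling = sig_traj,
    segments = seg_info,
    cells = do.call(rbind, cells),
    phase_calls = do.call(rbind, calls),
    durations = if (length(Filter(Negate(is.null), durs)))
      do.call(rbind, Filter(Negate(is.null), durs))
    else data.frame(cell = integer(), cycle_index = integer(),
                    phase = character(), start = numeric(), end = numeric(),
                    duration_h = numeric(), complete = logical()),
    arrest = arrest,
    n_peaks = n_peaks,
    final_cdk1 = final_cdk1,
    culture = list(state = st, residual = ss$residual,
                   period = osc$period),
    arrest_in_culture = FALSE,
    protocol = protocol, n_cells = n_cells, seed = seed,
    model_id = model_id
  ), class = "protocol_sim")
}

#' @export
print.protocol_sim <- function(x, ...) {
  if (isTRUE(x$arrest_in_culture)) {
    cat("Protocol simulation: no limit cycle under culture conditions",
        "(arrest report)\n")
    return(invisible(x))
  }
  cat("Protocol simulation, Model ", x$model_id, ", ", x$n_cells,
      " cells, dose ", x$protocol$dose_nM, " nM\n", sep = "")
  cat("  culture period ", round(x$culture$period, 2), " h; ",
      sum(x$arrest), "/", x$n_cells, " cells arrested in exposure window\n",
      sep = "")
  cd <- x$durations[x$durations$complete, ]
  if (nrow(cd)) {
    med <- stats::aggregate(duration_h ~ phase, cd, stats::median)
    cat("  median complete phase durations (h):\n")
    for (j in seq_len(nrow(med)))
      cat(sprintf("    %-5s %6.2f\n", med$phase[j], med$duration_h[j]))
  } else cat("  no complete phases in the exposure window\n")
  invisible(x)
}

#' @export
summary.protocol_sim <- function(object, ...) {
  cd <- object$durations[object$durations$complete, , drop = FALSE]
  list(arrested_fraction = mean(object$arrest),
       culture_period_h = object$culture$period,
       median_durations_h = if (nrow(cd))
         stats::aggregate(duration_h ~ phase, cd, stats::median)
       else NULL,
       n_complete = nrow(cd))
}
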