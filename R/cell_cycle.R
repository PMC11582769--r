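#' Construct cell-cycle oscillator parameters
#'
#' Parameters of the two-variable CDK1/APC relaxation oscillator extended
#' with signaling inputs. CDK1 is activated at basal rate `a1`, inactivated
#' by active APC (rate `b1`, Hill constants `K1`, `n1`), and auto-activates
#' through the Cdc25 loop (rate `a3`, Hill constants `K3`, `n3`) plus a
#' GREB1-dependent term with rate `k_GREB1`. APC is activated by CDK1 (rate
#' `a2`, Hill `K2`, `n2`) and inactivated at rate `b2` multiplied by `r` and
#' by the instantaneous free E2-ERalpha and PR concentrations.
#'
#' With `k_GREB1 = 0` and `r * E2_ER * PR == 1` the system reduces exactly to
#' the base oscillator. The default five rate constants are the base values
#' divided by 11, which stretches the base limit-cycle period (~4.75 time
#' units) to roughly 52 h; `k_GREB1` and `r` defaults come from
#' [calibrate_coupling()] against the default signaling parameters so that
#' the steady-culture period is ~48 h.
#'
#' @param ... Named overrides of the defaults.
#' @param scale_div Divisor applied to a1, a2, a3, b1, b2 (default 11).
#' @return A `cycle_params` object.
#' @export
cycle_params <- function(..., scale_div = 11) {
  p <- list(a1 = 0.1, b1 = 3, a2 = 3, b2 = 0.4, a3 = 3,
            K1 = 0.5, K2 = 0.5, K3 = 0.5, n1 = 8, n2 = 8, n3 = 8,
            k_GREB1 = .default_coupling["k_GREB1"],
            r = .default_coupling["r"])
  for (k in c("a1", "b1", "a2", "b2", "a3")) p[[k]] <- p[[k]] / scale_div
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown cell-cycle parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p <- lapply(p, unname)
  if (any(unlist(p) < 0)) stop("cell-cycle parameters must be non-negative")
  if (any(unlist(p[c("n1", "n2", "n3")]) < 1)) stop("Hill coefficients must be >= 1")
  structure(p, class = "cycle_params")
}

## coupling defaults produced by inst/scripts/tune_coupling.R against
## default_sig_params("III"); see the methods vignette.
.default_coupling <- c(k_GREB1 = 0.000391722, r = 278.986)

#' Base (uncoupled) oscillator parameters
#'
#' The unscaled base constants; `scale_div = 1` gives the fast base cycle.
#' @inheritParams cycle_params
#' @return A `cycle_params` with `k_GREB1 = 0` and `r = 1`.
#' @export
base_cycle_params <- function(scale_div = 1) {
  cycle_params(k_GREB1 = 0, r = 1, scale_div = scale_div)
}

#' Right-hand side of the extended CDK1/APC oscillator
#'
#' @param state Named vector `c(CDK1 = , APC = )` of active fractions.
#' @param params `cycle_params`.
#' @param GREB1,E2_ER,PR Instantaneous signaling inputs (free forms).
#' @return Named derivative vector (1/h).
#' @export
cycle_rhs <- function(state, params, GREB1 = 0, E2_ER = 0, PR = 0) {
  if (any(c(GREB1, E2_ER, PR) < 0)) stop("signaling inputs must be non-negative")
  C <- state[["CDK1"]]; A <- state[["APC"]]
  p <- params
  hill <- function(x, K, n) x^n / (K^n + x^n)
  dC <- p$a1 - p$b1 * C * hill(A, p$K1, p$n1) +
    p$a3 * (1 - C) * hill(C, p$K3, p$n3) + p$k_GREB1 * GREB1
  dA <- p$a2 * (1 - A) * hill(C, p$K2, p$n2) - p$r * p$b2 * A * E2_ER * PR
  c(CDK1 = dC, APC = dA)
}

#' Simulate the oscillator under prescribed signaling inputs
#'
#' Inputs may be constants or functions of time (h), e.g. interpolants of a
#' signaling trajectory. One-way coupling: the signaling trajectory is not
#' affected by the cycle state.
#'
#' @param params `cycle_params`.
#' @param t_grid Increasing output times (h).
#' @param init Named initial state (default `c(CDK1 = 0.1, APC = 0.1)`).
#' @param GREB1,E2_ER,PR Constants or functions of time.
#' @param rtol,atol Solver tolerances.
#' @return data.frame `time`, `CDK1`, `APC`.
#' @export
simulate_cycle <- function(params, t_grid, init = c(CDK1 = 0.1, APC = 0.1),
                           GREB1 = 0, E2_ER = 0, PR = 0,
                           rtol = 1e-8, atol = 1e-10) {
  as_fun <- function(x) if (is.function(x)) x else function(t) x
  fG <- as_fun(GREB1); fE <- as_fun(E2_ER); fP <- as_fun(PR)
  fn <- function(t, y, parms) {
    y["APC"] <- min(max(y[["APC"]], 0), 1)
    y["CDK1"] <- max(y[["CDK1"]], 0)
    list(cycle_rhs(y, parms, GREB1 = fG(t), E2_ER = fE(t), PR = fP(t)))
  }
  out <- deSolve::lsoda(init, t_grid, fn, params, rtol = rtol, atol = atol)
  df <- as.data.frame(unclass(out)); names(df)[1] <- "time"
  df
}

#' Joint right-hand side of the coupled signaling + cell-cycle system
#'
#' The signaling derivatives do not depend on the cell-cycle state (one-way
#' coupling); the oscillator receives the instantaneous free GREB1, E2_ER
#' and PR concentrations.
#'
#' @inheritParams model_rhs
#' @param sig_state,cyc_state Named state vectors.
#' @param sig_params,cyc_params Parameter objects.
#' @param e2_clamped If `TRUE`, zero the E2 derivative.
#' @return Named joint derivative vector.
#' @export
coupled_rhs <- function(sig_state, cyc_state, sig_params, cyc_params,
                        model_id = "III", knockdown = character(),
                        e2_clamped = FALSE) {
  ds <- model_rhs(model_id, sig_state, sig_params, knockdown = knockdown)
  if (e2_clamped) ds["E2"] <- 0
  dc <- cycle_rhs(cyc_state, cyc_params,
                  GREB1 = sig_state[["GREB1"]],
                  E2_ER = sig_state[["E2_ER"]],
                  PR = sig_state[["PR"]])
  c(ds, dc)
}

#' Simulate the coupled system
#'
#' @inheritParams simulate_signaling
#' @param cyc_params `cycle_params`.
#' @param cyc_init Initial `c(CDK1, APC)`.
#' @return data.frame with time, signaling states, CDK1, APC.
#' @export
simulate_coupled <- function(model_id, sig_params, cyc_params, e2_input,
                             t_grid, cyc_init = c(CDK1 = 0.1, APC = 0.1),
                             knockdown = character(), init = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  if (is.null(init)) init <- initial_state(model_id, sig_params, e2_input)
  if (e2_input$mode == "clamp") init["E2"] <- e2_input$value
  y0 <- c(init, cyc_init)
  clamp <- e2_input$mode == "clamp"
  nsig <- length(init)
  fn <- function(t, y, parms) {
    y[y < 0] <- 0
    y["APC"] <- min(y[["APC"]], 1)
    list(coupled_rhs(y[seq_len(nsig)], y[c("CDK1", "APC")],
                     sig_params, cyc_params, model_id = model_id,
                     knockdown = knockdown, e2_clamped = clamp))
  }
  out <- deSolve::lsoda(y0, t_grid, fn, NULL, rtol = rtol, atol = atol)
  df <- as.data.frame(unclass(out)); names(df)[1] <- "time"
  df
}

## interior local extrema with parabolic refinement of time and value;
## plateau ties broken at the earliest index
.local_extrema <- function(t, x, what = c("max", "min")) {
  what <- match.arg(what)
  if (what == "min") x <- -x
  n <- length(x)
  if (n < 3) return(data.frame(index = integer(), time = numeric(), value = numeric()))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(idx)) return(data.frame(index = integer(), time = numeric(), value = numeric()))
  ref <- vapply(idx, function(i) {
    y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
    off <- max(min(off, 0.5), -0.5)
    tt <- t[i] + off * mean(diff(t[(i - 1):(i + 1)]))
    vv <- y2 - 0.25 * (y1 - y3) * off
    c(tt, vv)
  }, numeric(2))
  sign <- if (what == "min") -1 else 1
  data.frame(index = idx, time = ref[1, ], value = sign * ref[2, ])
}

#' Detect sustained oscillations in a trajectory
#'
#' A trajectory oscillates if its analysis tail contains at least three CDK1
#' maxima whose peak-to-trough amplitude exceeds `amplitude_tol` (as a
#' fraction of the observed range) and whose spacings vary by less than
#' `period_tol` (relative). The period is the mean spacing of the tail maxima.
#'
#' @param times,cdk1 Trajectory time grid (h) and CDK1 series; alternatively
#'   pass a data.frame with `time` and `CDK1` columns as `times`.
#' @param t_tail Length of the analysis tail in hours (default: second half).
#' @param amplitude_tol Minimal amplitude as fraction of the series range.
#' @param period_tol Maximal relative variation of inter-peak spacing.
#' @return List `oscillates`, `period` (NA when not oscillating), `peaks`.
#' @export
detect_oscillation <- function(times, cdk1 = NULL, t_tail = NULL,
                               amplitude_tol = 0.05, period_tol = 0.10) {
  if (is.data.frame(times)) {
    cdk1 <- times$CDK1
    times <- times$time
  }
  if (length(times) < 8) stop("trajectory too short for oscillation analysis")
  if (is.null(t_tail)) t_tail <- diff(range(times)) / 2
  keep <- times >= max(times) - t_tail
  t <- times[keep]; x <- cdk1[keep]
  rng <- diff(range(cdk1))
  if (rng <= .Machine$double.eps)
    return(list(oscillates = FALSE, period = NA_real_, peaks = numeric()))
  mx <- .local_extrema(t, x, "max")
  mn <- .local_extrema(t, x, "min")
  if (nrow(mx) < 3 || nrow(mn) < 1)
    return(list(oscillates = FALSE, period = NA_real_, peaks = mx$time))
  amp <- max(mx$value) - min(mn$value)
  sp <- diff(mx$time)
  ok <- amp > amplitude_tol * rng &&
    (length(sp) < 2 || (max(sp) - min(sp)) / mean(sp) < period_tol)
  list(oscillates = ok, period = if (ok) mean(sp) else NA_real_,
       peaks = mx$time)
}

#' Classify cell-cycle phases from CDK1/APC activities
#'
#' The S-G2-M to G1 transition is placed at interior minima of CDK1. The APC
#' threshold is computed once, as the first interior APC minimum plus 5% of
#' the difference between that minimum and the first APC maximum that follows
#' it; a downward threshold crossing switches G1 to G1/S and an upward
#' crossing switches G1/S to S-G2-M. Trajectories with no interior APC
#' extrema (or no CDK1 minimum) are reported as arrested: a single-phase
#' sequence labelled G1.
#'
#' @param times,cdk1,apc Trajectory (a data.frame with `time`, `CDK1`, `APC`
#'   may be given as `times`).
#' @return A `phase_seq`: list with `times`, `phases` (factor G1/G1S/SG2M),
#'   `transitions` (data.frame time, from, to), `apc_threshold`, `arrested`.
#' @export
classify_phases <- function(times, cdk1 = NULL, apc = NULL) {
  if (is.data.frame(times)) {
    cdk1 <- times$CDK1; apc <- times$APC; times <- times$time
  }
  lev <- c("G1", "G1S", "SG2M")
  arrest <- function() structure(
    list(times = times, phases = factor(rep("G1", length(times)), levels = lev),
         transitions = data.frame(time = numeric(), from = character(),
                                  to = character()),
         apc_threshold = NA_real_, arrested = TRUE), class = "phase_seq")

  apc_min <- .local_extrema(times, apc, "min")
  cdk_min <- .local_extrema(times, cdk1, "min")
  if (nrow(apc_min) == 0 || nrow(cdk_min) == 0) return(arrest())
  m0 <- apc_min[1, ]
  apc_max <- .local_extrema(times, apc, "max")
  apc_max <- apc_max[apc_max$time > m0$time, ]
  if (nrow(apc_max) == 0) return(arrest())
  thr <- m0$value + 0.05 * (apc_max$value[1] - m0$value)

  cross <- function(dir) {
    below <- apc < thr
    if (dir == "down") i <- which(!below[-length(below)] & below[-1])
    else i <- which(below[-length(below)] & !below[-1])
    if (!length(i)) return(numeric())
    # linear interpolation of the crossing time
    vapply(i, function(j) {
      t1 <- times[j]; t2 <- times[j + 1]
      v1 <- apc[j]; v2 <- apc[j + 1]
      t1 + (thr - v1) / (v2 - v1) * (t2 - t1)
    }, numeric(1))
  }
  ev <- rbind(
    data.frame(time = cross("down"), from = "G1", to = "G1S"),
    data.frame(time = cross("up"), from = "G1S", to = "SG2M"),
    data.frame(time = cdk_min$time, from = "SG2M", to = "G1")
  )
  ev <- ev[order(ev$time), ]
  if (!nrow(ev)) return(arrest())
  phases <- rep(ev$from[1], length(times))
  for (k in seq_len(nrow(ev)))
    phases[times >= ev$time[k]] <- ev$to[k]
  structure(list(times = times, phases = factor(phases, levels = lev),
                 transitions = ev, apc_threshold = thr, arrested = FALSE),
            class = "phase_seq")
}

#' @export
print.phase_seq <- function(x, ...) {
  if (x$arrested) {
    cat("Phase sequence: arrested (", length(x$times), " timepoints, all ",
        as.character(x$phases[1]), ")\n", sep = "")
  } else {
    cat("Phase sequence over [", min(x$times), ", ", max(x$times),
        "] h, APC threshold ", signif(x$apc_threshold, 4), ", ",
        nrow(x$transitions), " transitions\n", sep = "")
  }
  invisible(x)
}

#' Phase durations from a classified sequence
#'
#' Reports one record per phase occurrence whose start and end transitions
#' both lie inside the simulated window; occurrences truncated by the window
#' are marked incomplete. Durations use the (interpolated) transition times,
#' so per full cycle G1 + G1S + SG2M equals the oscillation period to within
#' one grid step.
#'
#' @param seq A `phase_seq` from [classify_phases()].
#' @return data.frame `cycle_index`, `phase`, `start`, `end`, `duration_h`,
#'   `complete`.
#' @export
phase_durations_insilico <- function(seq) {
  stopifnot(inherits(seq, "phase_seq"))
  ev <- seq$transitions
  t0 <- min(seq$times); t1 <- max(seq$times)
  if (seq$arrested || nrow(ev) == 0)
    return(data.frame(cycle_index = integer(), phase = character(),
                      start = numeric(), end = numeric(),
                      duration_h = numeric(), complete = logical()))
  bounds <- c(t0, ev$time, t1)
  phases <- c(as.character(ev$from[1]), as.character(ev$to))
  complete <- c(FALSE, rep(TRUE, nrow(ev) - 1), FALSE)
  out <- data.frame(phase = phases,
                    start = bounds[-length(bounds)],
                    end = bounds[-1],
                    complete = complete,
                    stringsAsFactors = FALSE)
  out$duration_h <- out$end - out$start
  out <- out[out$duration_h > 0, ]
  # cycle index advances at each SG2M -> G1 boundary (a division)
  ncyc <- cumsum(c(0, head(out$phase, -1) == "SG2M" & out$phase[-1] == "G1"))
  out$cycle_index <- ncyc + 1L
  rownames(out) <- NULL
  out[, c("cycle_index", "phase", "start", "end", "duration_h", "complete")]
}

#' Sample initial oscillator states along a limit cycle
#'
#' Draws `n` states at uniformly random timepoints within one period of a
#' limit-cycle trajectory (linear interpolation), reproducibly for a fixed
#' seed. Used to desynchronize virtual cells.
#'
#' @param traj data.frame `time`, `CDK1`, `APC` containing at least one full
#'   period of a sustained oscillation.
#' @param n Number of states to draw.
#' @param seed Integer RNG seed.
#' @return data.frame `CDK1`, `APC` (n rows), attribute `phase_times`.
#' @export
sample_initial_states <- function(traj, n, seed = 1L) {
  osc <- detect_oscillation(traj)
  if (!osc$oscillates) stop("trajectory has no sustained limit cycle")
  period <- osc$period
  tend <- max(traj$time)
  t0 <- tend - period
  if (t0 < min(traj$time)) stop("trajectory shorter than one period")
  set.seed(seed)
  ts <- t0 + stats::runif(n) * period
  out <- data.frame(
    CDK1 = stats::approx(traj$time, traj$CDK1, xout = ts)$y,
    APC = stats::approx(traj$time, traj$APC, xout = ts)$y
  )
  attr(out, "phase_times") <- ts
  out
}

#' Tune the signaling-to-cycle coupling strengths
#'
#' Chooses `r` so that, with the given signaling parameters held at their
#' steady-culture state (E2 clamped at the complete-medium equivalent), the
#' coupled oscillator's period matches `target_period_h`; `k_GREB1` is fixed
#' at a small value relative to the culture GREB1 level so that GREB1
#' knockdown slows CDK1 activation without abolishing oscillations.
#'
#' @param sig_params Signaling parameters (Model III).
#' @param cyc_params Starting cell-cycle parameters.
#' @param e2_culture Clamped culture E2-equivalent (default 0.156).
#' @param target_period_h Desired steady-culture period (default 48).
#' @param k_GREB1 Fixed GREB1 coupling rate; default scales a1 so the GREB1
#'   term contributes ~30% of basal CDK1 activation at the culture level.
#' @return `cyc_params` with tuned `k_GREB1` and `r` plus attribute
#'   `culture_state`.
#' @export
calibrate_coupling <- function(sig_params, cyc_params = cycle_params(),
                               e2_culture = 0.156, target_period_h = 48,
                               k_GREB1 = NULL) {
  ss <- signaling_steady_state("III", sig_params, e2_culture)
  st <- ss$state
  if (is.null(k_GREB1)) k_GREB1 <- 0.3 * cyc_params$a1 / st[["GREB1"]]
  cyc_params$k_GREB1 <- unname(k_GREB1)
  prod <- st[["E2_ER"]] * st[["PR"]]
  per_of <- function(r) {
    cp <- cyc_params; cp$r <- r
    tr <- simulate_cycle(cp, seq(0, 40 * target_period_h, by = 0.25),
                         GREB1 = st[["GREB1"]], E2_ER = st[["E2_ER"]],
                         PR = st[["PR"]])
    osc <- detect_oscillation(tr, t_tail = 10 * target_period_h)
    if (!osc$oscillates) NA_real_ else osc$period
  }
  # bracket on log r around the reduction point r*prod = 1
  r0 <- 1 / prod
  f <- function(lr) {
    p <- per_of(exp(lr))
    if (is.na(p)) return(NA_real_)
    p - target_period_h
  }
  grid <- seq(log(r0 / 10), log(r0 * 10), length.out = 13)
  fg <- vapply(grid, f, numeric(1))
  ok <- which(!is.na(fg))
  br <- NULL
  for (j in seq_along(ok)[-1]) {
    i1 <- ok[j - 1]; i2 <- ok[j]
    if (fg[i1] * fg[i2] <= 0) { br <- c(grid[i1], grid[i2]); break }
  }
  if (is.null(br))
    stop("could not bracket the target period; adjust k_GREB1 or signaling scale")
  root <- stats::uniroot(f, br, f.lower = fg[match(br[1], grid)],
                         f.upper = fg[match(br[2], grid)], tol = 1e-4)
  cyc_params$r <- exp(root$root)
  attr(cyc_params, "culture_state") <- st
  cyc_params
}
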