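#' Saturating interaction rate
#'
#' Binding, modification and stimulation of state variables are modelled with
#' terms of the form `p * X * Y / (1 + X + Y)`, which prevents unlimited
#' accumulation: the flux is bounded above by `p * min(X, Y)`.
#'
#' @param p Rate constant (1/h on the arbitrary-unit concentration scale).
#' @param X,Y Concentrations (a.u.), non-negative.
#' @return Flux in a.u./h.
#' @examples
#' saturating_rate(0.5, 2, 3)  # 0.5 * 6 / 6 = 0.5
#' @export
saturating_rate <- function(p, X, Y) {
  if (any(p < 0) || any(X < 0) || any(Y < 0))
    stop("saturating_rate: all inputs must be non-negative")
  p * X * Y / (1 + X + Y)
}

## single-species saturating stimulation x/(1+x)
.sat1 <- function(x) x / (1 + x)

.SIG_MODELS <- c("I", "II", "III")

#' State variable names of a signaling model
#' @param model_id `"I"`, `"II"` or `"III"`.
#' @return Character vector of state names in integration order.
#' @export
signaling_states <- function(model_id) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  if (model_id == "III")
    c("E2", "ER", "E2_ER", "E2_ER_PR", "E2_ER_PR_GREB1", "GREB1", "PR", "TFF1")
  else
    c("E2", "ER", "E2_ER", "E2_ER_GREB1", "GREB1", "PR", "TFF1")
}

#' Construct a signaling parameter set
#'
#' Parameters of the E2 signaling models. Binding (`b_*`) and degradation
#' (`d_*`) rate constants are constrained to `[0, 1]` (1/h); maximal
#' stimulation rates (`stim_*`, a.u./h) are non-negative and capped at
#' `stim_cap`. Synthesis rates are never set directly: they are derived from
#' degradation rates and initial states by [derive_synthesis()] so that the
#' unexposed system starts in steady state.
#'
#' `dose_map` maps nominal doses (nM, names) to effective concentrations
#' (a.u.) on the fitted dose scale; the lowest nominal dose is pinned at
#' effective 0.001 as the reference.
#'
#' @param model_id Model variant, `"I"`, `"II"` or `"III"`.
#' @param ... Named parameter overrides (see Details).
#' @param greb1_consumption Include the consumption of free GREB1 into its
#'   complex in the GREB1 equation of Models I/II (`TRUE`, mass-consistent,
#'   default) or reproduce the printed equations without it (`FALSE`).
#'   Model III always contains the consumption term.
#' @param stim_cap Upper bound for stimulation rates (default 1e3).
#' @return An object of class `sig_params` (named list).
#' @export
sig_params <- function(model_id = "III", ..., greb1_consumption = TRUE,
                       stim_cap = 1e3) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  p <- default_sig_params(model_id)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(p), "dose_map"))
  if (length(unknown))
    stop("unknown signaling parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  rates <- grep("^[bd]_", names(p), value = TRUE)
  for (nm in rates)
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  for (nm in grep("^stim_", names(p), value = TRUE))
    if (p[[nm]] < 0 || p[[nm]] > stim_cap)
      stop(nm, " must lie in [0, ", stim_cap, "]")
  p$model_id <- model_id
  p$greb1_consumption <- isTRUE(greb1_consumption)
  p$stim_cap <- stim_cap
  class(p) <- "sig_params"
  derive_synthesis(p)
}

#' Reference parameter values for the signaling models
#'
#' A synthetic reference set (not the published fit, whose values are in an
#' unavailable appendix) chosen so the models reproduce the qualitative
#' behaviour of the measured data: biphasic GREB1/TFF1 induction, near-linear
#' PR induction, and the knockdown dependency pattern. The dose map keeps the
#' published effective-scale anchors (0.055 nM -> 0.104, 100 nM -> 0.837) and
#' pins the lowest dose at 0.001.
#'
#' @param model_id Model variant.
#' @return Named list of parameter values.
#' @export
default_sig_params <- function(model_id = "III") {
  model_id <- match.arg(model_id, .SIG_MODELS)
  p <- list(
    b_E2_ER   = 0.06,
    d_ER      = 0.10,
    d_E2_ER   = 0.25,
    d_GREB1   = 0.04,
    d_PR      = 0.01,
    d_TFF1    = 0.03,
    stim_GREB1 = 60,
    stim_PR    = 0.6,
    stim_TFF1  = 6,
    ER_init    = 1.0,
    GREB1_init = 0.50,
    PR_init    = 0.30,
    TFF1_init  = 0.30,
    dose_map = c("0.001" = 0.001, "0.01" = 0.049, "0.055" = 0.104,
                 "0.1" = 0.135, "1" = 0.32, "10" = 0.55, "100" = 0.837)
  )
  if (model_id == "III") {
    p$b_E2_ER_PR <- 0.9
    p$b_E2_ER_PR_GREB1 <- 0.6
    p$d_E2_ER_PR <- 0.30
    p$d_E2_ER_PR_GREB1 <- 0.30
  } else {
    p$b_E2_ER_GREB1 <- 0.6
    p$d_E2_ER_GREB1 <- 0.30
  }
  p
}

#' Derive synthesis rates from degradation rates and initial states
#'
#' Synthesis parameters are made dependent on the degradation parameters and
#' initial states (`s_X = d_X * X_init`) so that, with E2 absent and all
#' complexes at zero, the system starts exactly in steady state.
#'
#' @param params A `sig_params` object (or named list with the `d_*` and
#'   `*_init` entries).
#' @return `params` with `s_ER`, `s_GREB1`, `s_PR`, `s_TFF1` set.
#' @export
derive_synthesis <- function(params) {
  params$s_ER    <- params$d_ER    * params$ER_init
  params$s_GREB1 <- params$d_GREB1 * params$GREB1_init
  params$s_PR    <- params$d_PR    * params$PR_init
  params$s_TFF1  <- params$d_TFF1  * params$TFF1_init
  params
}

#' Effective concentration for a nominal dose
#'
#' Looks up (or log-linearly interpolates) the effective concentration
#' perceived by the cells for a nominal E2 dose in nM.
#'
#' @param params `sig_params` carrying a `dose_map`.
#' @param nominal_nM Nominal dose in nM.
#' @return Effective concentration (a.u.).
#' @export
effective_dose <- function(params, nominal_nM) {
  dm <- params$dose_map
  nom <- as.numeric(names(dm))
  hit <- match(nominal_nM, nom)
  if (!is.na(hit)) return(unname(dm[hit]))
  if (nominal_nM <= 0) return(0)
  if (nominal_nM < min(nom) || nominal_nM > max(nom))
    stop("nominal dose outside the dose map range: ", nominal_nM)
  exp(stats::approx(log(nom), log(dm), xout = log(nominal_nM))$y)
}

#' Right-hand side of a signaling model
#'
#' Evaluates the time derivative of a signaling state under Model I, II or
#' III. In-silico knockdown of a target protein removes all positive (source)
#' terms from that protein's equation, leaving degradation and consumption.
#'
#' @param model_id Model variant.
#' @param state Named numeric vector over [signaling_states()].
#' @param params `sig_params`.
#' @param knockdown Character vector among `"GREB1"`, `"PR"`, `"TFF1"`.
#' @return Named derivative vector (a.u./h).
#' @export
model_rhs <- function(model_id, state, params, knockdown = character()) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  need <- signaling_states(model_id)
  if (!all(need %in% names(state)))
    stop("state is missing variables for Model ", model_id, ": ",
         paste(setdiff(need, names(state)), collapse = ", "))
  bad <- setdiff(knockdown, c("GREB1", "PR", "TFF1"))
  if (length(bad)) stop("unknown knockdown target(s): ", paste(bad, collapse = ", "))
  s <- as.list(state[need])
  p <- params
  kd <- function(x) x %in% knockdown

  f_ER <- saturating_rate(p$b_E2_ER, s$E2, s$ER)
  d <- c(E2 = -f_ER,
         ER = p$s_ER - f_ER - p$d_ER * s$ER)

  if (model_id %in% c("I", "II")) {
    f_G <- saturating_rate(p$b_E2_ER_GREB1, s$E2_ER, s$GREB1)
    d["E2_ER"] <- f_ER - f_G - p$d_E2_ER * s$E2_ER
    d["E2_ER_GREB1"] <- f_G - p$d_E2_ER_GREB1 * s$E2_ER_GREB1
    cons <- if (p$greb1_consumption) f_G else 0
    if (model_id == "I") {
      stim_g <- p$stim_GREB1 * .sat1(s$E2_ER_GREB1)
      stim_t <- p$stim_TFF1  * .sat1(s$E2_ER_GREB1)
    } else {
      stim_g <- p$stim_GREB1 * saturating_rate(1, s$E2_ER_GREB1, s$PR)
      stim_t <- p$stim_TFF1  * saturating_rate(1, s$E2_ER, s$PR)
    }
    stim_p <- p$stim_PR * .sat1(s$E2_ER_GREB1)
    d["GREB1"] <- (if (kd("GREB1")) 0 else p$s_GREB1 + stim_g) -
      cons - p$d_GREB1 * s$GREB1
    d["PR"] <- (if (kd("PR")) 0 else p$s_PR + stim_p) - p$d_PR * s$PR
    d["TFF1"] <- (if (kd("TFF1")) 0 else p$s_TFF1 + stim_t) - p$d_TFF1 * s$TFF1
  } else {
    f_P  <- saturating_rate(p$b_E2_ER_PR, s$E2_ER, s$PR)
    f_PG <- saturating_rate(p$b_E2_ER_PR_GREB1, s$E2_ER_PR, s$GREB1)
    d["E2_ER"] <- f_ER - f_P - p$d_E2_ER * s$E2_ER
    d["E2_ER_PR"] <- f_P - f_PG - p$d_E2_ER_PR * s$E2_ER_PR
    d["E2_ER_PR_GREB1"] <- f_PG - p$d_E2_ER_PR_GREB1 * s$E2_ER_PR_GREB1
    stim_g <- p$stim_GREB1 * .sat1(s$E2_ER_PR_GREB1)
    stim_p <- p$stim_PR    * .sat1(s$E2_ER_PR_GREB1)
    stim_t <- p$stim_TFF1  * saturating_rate(1, s$E2_ER, s$PR)
    d["GREB1"] <- (if (kd("GREB1")) 0 else p$s_GREB1 + stim_g) -
      f_PG - p$d_GREB1 * s$GREB1
    d["PR"] <- (if (kd("PR")) 0 else p$s_PR + stim_p) -
      f_P - p$d_PR * s$PR
    d["TFF1"] <- (if (kd("TFF1")) 0 else p$s_TFF1 + stim_t) - p$d_TFF1 * s$TFF1
  }
  d[need]
}

#' Knockdown-modified right-hand side
#'
#' @inheritParams model_rhs
#' @param targets Proteins to knock down (subset of GREB1, PR, TFF1).
#' @return A function `(state, params) -> derivative` with the targets'
#'   positive terms removed.
#' @export
apply_knockdown <- function(model_id, targets) {
  bad <- setdiff(targets, c("GREB1", "PR", "TFF1"))
  if (length(bad)) stop("unknown knockdown target(s): ", paste(bad, collapse = ", "))
  force(model_id)
  function(state, params) model_rhs(model_id, state, params, knockdown = targets)
}

#' E2 input modes
#'
#' Under `e2_clamp`, the E2 concentration is held constant (its derivative is
#' forced to zero at the clamped value), emulating continuous supply, e.g. by
#' the culture medium. Under `e2_free`, E2 starts at the given value and is
#' depleted through complex formation only (no synthesis term), which yields
#' the biphasic post-exposure decay.
#'
#' @param value Concentration in effective (a.u.) units.
#' @return An `e2_input` object.
#' @export
e2_clamp <- function(value) {
  stopifnot(value >= 0)
  structure(list(mode = "clamp", value = value), class = "e2_input")
}

#' @rdname e2_clamp
#' @export
e2_free <- function(value) {
  stopifnot(value >= 0)
  structure(list(mode = "free", value = value), class = "e2_input")
}

#' Initial state of a signaling model
#'
#' Complexes start at zero; free proteins at their `*_init` values; E2 at the
#' value of the E2 input.
#'
#' @inheritParams model_rhs
#' @param e2_input An [e2_clamp()] or [e2_free()] input.
#' @return Named numeric state vector.
#' @export
initial_state <- function(model_id, params, e2_input = e2_free(0)) {
  st <- stats::setNames(numeric(length(signaling_states(model_id))),
                        signaling_states(model_id))
  st["E2"] <- e2_input$value
  st["ER"] <- params$ER_init
  st["GREB1"] <- params$GREB1_init
  st["PR"] <- params$PR_init
  st["TFF1"] <- params$TFF1_init
  st
}

#' Simulate a signaling model
#'
#' Integrates the chosen model with a stiff-capable implicit solver (lsoda,
#' rtol 1e-8, atol 1e-10 by default). Clamping is implemented by zeroing the
#' E2 derivative, not by resetting the state.
#'
#' @inheritParams model_rhs
#' @param e2_input [e2_clamp()] or [e2_free()] input mode.
#' @param t_grid Increasing vector of output times (h).
#' @param init Optional full initial state (defaults to [initial_state()]).
#' @param rtol,atol Solver tolerances.
#' @return A `sig_traj`: data.frame with `time` and one column per state;
#'   attributes `model_id`, `params`, `e2_input`, `knockdown`.
#' @export
simulate_signaling <- function(model_id, params, e2_input, t_grid,
                               knockdown = character(), init = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")
  if (is.null(init)) init <- initial_state(model_id, params, e2_input)
  if (e2_input$mode == "clamp") init["E2"] <- e2_input$value
  clamp <- e2_input$mode == "clamp"
  pv <- .sig_parm_vector(model_id, params, knockdown, clamp)
  out <- deSolve::lsoda(init[signaling_states(model_id)], t_grid,
                        func = "derivs_sig", parms = pv,
                        dllname = "estrocycle", initfunc = "init_sig",
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("signaling integration failed; final state: ",
         paste(sprintf("%s=%.4g", colnames(out)[-1], out[nrow(out), -1]),
               collapse = ", "))
  traj <- as.data.frame(unclass(out))
  names(traj)[1] <- "time"
  structure(traj, model_id = model_id, params = params, e2_input = e2_input,
            knockdown = knockdown, class = c("sig_traj", "data.frame"))
}



## parameter vector for the compiled right-hand side (see src/sig_rhs.c)
.sig_parm_vector <- function(model_id, p, knockdown = character(),
                             clamp = FALSE) {
  v <- c(match(model_id, .SIG_MODELS), as.numeric(clamp),
         as.numeric(c("GREB1", "PR", "TFF1") %in% knockdown),
         p$b_E2_ER, p$d_ER, p$d_E2_ER,
         p$s_ER, p$s_GREB1, p$s_PR, p$s_TFF1,
         p$d_GREB1, p$d_PR, p$d_TFF1,
         p$stim_GREB1, p$stim_PR, p$stim_TFF1)
  if (model_id == "III")
    c(v, p$b_E2_ER_PR, p$b_E2_ER_PR_GREB1, p$d_E2_ER_PR, p$d_E2_ER_PR_GREB1)
  else
    c(v, p$b_E2_ER_GREB1, p$d_E2_ER_GREB1,
      as.numeric(isTRUE(p$greb1_consumption)), 0)
}

#' Observable totals of a signaling trajectory
#'
#' The measured reporter intensities correspond to total protein: free forms
#' plus the amount captured in complexes. Model I/II: `GREB1_total = GREB1 +
#' E2_ER_GREB1`, `PR_total = PR`. Model III: `GREB1_total = GREB1 +
#' E2_ER_PR_GREB1`, `PR_total = PR + E2_ER_PR + E2_ER_PR_GREB1`. TFF1 is free
#' in all models.
#'
#' @param traj A `sig_traj` (or data.frame of states with a `time` column).
#' @param model_id Model variant; defaults to the trajectory's own.
#' @return data.frame with `time`, `GREB1_total`, `PR_total`, `TFF1`.
#' @export
observable_totals <- function(traj, model_id = attr(traj, "model_id")) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  if (model_id == "III") {
    g <- traj$GREB1 + traj$E2_ER_PR_GREB1
    p <- traj$PR + traj$E2_ER_PR + traj$E2_ER_PR_GREB1
  } else {
    g <- traj$GREB1 + traj$E2_ER_GREB1
    p <- traj$PR
  }
  data.frame(time = traj$time, GREB1_total = g, PR_total = p, TFF1 = traj$TFF1)
}

#' Signaling steady state under a clamped E2 level
#'
#' Integrates under the clamp until the right-hand-side residual falls below
#' `tol` (max-norm), in chunks, and returns the final state.
#'
#' @inheritParams simulate_signaling
#' @param e2_value Clamped effective E2 concentration.
#' @param tol Residual tolerance (a.u./h).
#' @param chunk_h,max_h Chunk length and maximum total time.
#' @return List with `state`, `residual`, `time_needed`.
#' @export
signaling_steady_state <- function(model_id, params, e2_value,
                                   knockdown = character(), tol = 1e-8,
                                   chunk_h = 500, max_h = 2e4) {
  st <- initial_state(model_id, params, e2_clamp(e2_value))
  t_tot <- 0
  repeat {
    tr <- simulate_signaling(model_id, params, e2_clamp(e2_value),
                             t_grid = c(0, chunk_h / 2, chunk_h),
                             knockdown = knockdown, init = st)
    st <- unlist(tr[nrow(tr), signaling_states(model_id)])
    st[st < 0] <- 0
    t_tot <- t_tot + chunk_h
    res <- model_rhs(model_id, st, params, knockdown = knockdown)
    res["E2"] <- 0  # clamped
    if (max(abs(res)) < tol || t_tot >= max_h) break
  }
  list(state = st, residual = max(abs(res)), time_needed = t_tot)
}

#' @export
print.sig_params <- function(x, ...) {
  cat("E2 signaling parameters (Model ", x$model_id, ")\n", sep = "")
  num <- vapply(x, function(v) is.numeric(v) && length(v) == 1, logical(1))
  v <- unlist(x[num])
  print(round(v, 5))
  cat("dose map (nominal nM -> effective):\n")
  print(x$dose_map)
  invisible(x)
}

#' @export
print.sig_traj <- function(x, ...) {
  cat("Signaling trajectory, Model ", attr(x, "model_id"),
      ", ", nrow(x), " timepoints over [",
      min(x$time), ", ", max(x$time), "] h",
      if (length(attr(x, "knockdown")))
        paste0(", knockdown: ", paste(attr(x, "knockdown"), collapse = "+")),
      "\n", sep = "")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
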