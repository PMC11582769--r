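#' Normalize population-level reporter intensities
#'
#' Applies the population-level preprocessing: intensities are divided by
#' the mean of the matched DMSO technical replicates (same biological
#' replicate, reporter and timepoint), rows later than `t_max` hours are
#' dropped, and cell-count series are normalized to their first timepoint
#' instead of to DMSO.
#'
#' @param raw data.frame with columns `time_h`, `nominal_dose_nM`,
#'   `replicate`, `reporter` (GREB1/PR/TFF1, or "count"), `value`, and
#'   `treatment` (`"E2"` or `"DMSO"`).
#' @param t_max Cut-off time in hours (default 55).
#' @return data.frame of normalized E2 rows (`value` replaced by the ratio),
#'   with attribute `excluded` reporting rows dropped for missing controls
#'   and the time cut.
#' @export
preprocess_population <- function(raw, t_max = 55) {
  need <- c("time_h", "nominal_dose_nM", "replicate", "reporter", "value",
            "treatment")
  if (!all(need %in% names(raw)))
    stop("raw table must have columns: ", paste(need, collapse = ", "))
  n_cut <- sum(raw$time_h > t_max)
  raw <- raw[raw$time_h <= t_max, ]

  counts <- raw[raw$reporter == "count", ]
  meas <- raw[raw$reporter != "count", ]

  dmso <- meas[meas$treatment == "DMSO", ]
  e2 <- meas[meas$treatment == "E2", ]
  key <- function(d) paste(d$replicate, d$reporter, d$time_h, sep = "\r")
  ctrl_mean <- tapply(dmso$value, key(dmso), mean)
  idx <- match(key(e2), names(ctrl_mean))
  miss <- is.na(idx)
  out <- e2[!miss, ]
  out$value <- out$value / as.numeric(ctrl_mean[idx[!miss]])

  if (nrow(counts)) {
    ckey <- paste(counts$replicate, counts$nominal_dose_nM,
                  counts$treatment, sep = "\r")
    for (g in split(seq_len(nrow(counts)), ckey)) {
      v0 <- counts$value[g][which.min(counts$time_h[g])]
      counts$value[g] <- counts$value[g] / v0
    }
    out <- rbind(out, counts)
  }
  attr(out, "excluded") <- list(missing_control = sum(miss),
                                after_t_max = n_cut)
  out
}

#' Latin hypercube parameter initialization
#'
#' One stratum per start and dimension; fixed parameters are absent from the
#' sampled dimensions. Dimensions flagged `log` are sampled log-uniformly.
#'
#' @param n_starts Number of starts.
#' @param bounds data.frame with columns `name`, `lower`, `upper`, `log`
#'   (logical).
#' @param seed RNG seed.
#' @return Matrix (`n_starts` x `nrow(bounds)`) with named columns.
#' @export
latin_hypercube_init <- function(n_starts, bounds, seed = 1L) {
  stopifnot(all(c("name", "lower", "upper") %in% names(bounds)))
  if (is.null(bounds$log)) bounds$log <- FALSE
  if (any(!is.finite(bounds$lower)) || any(!is.finite(bounds$upper)))
    stop("bounds must be finite")
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, nrow(bounds))
  out <- sapply(seq_len(nrow(bounds)), function(j) {
    lo <- bounds$lower[j]; hi <- bounds$upper[j]
    if (bounds$log[j]) exp(log(lo) + u[, j] * (log(hi) - log(lo)))
    else lo + u[, j] * (hi - lo)
  })
  out <- matrix(out, nrow = n_starts)
  colnames(out) <- bounds$name
  out
}

#' Fit configuration for signaling calibration
#'
#' @param n_starts Number of Latin hypercube starts (default 75).
#' @param seed RNG seed for start sampling.
#' @param fixed Named list of parameters to hold fixed (complex initial
#'   states are structurally 0 and the lowest effective dose is always
#'   pinned at 0.001; entries here are additional).
#' @param stim_upper,init_upper,dose_upper Upper bounds for stimulation
#'   rates, initial states and effective doses.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @param rtol_sim Solver tolerance used inside the objective (looser than
#'   the presentation default, for speed).
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_starts = 75, seed = 1L, fixed = list(),
                       stim_upper = 1e3, init_upper = 10, dose_upper = 10,
                       max_iter = 50, rtol_sim = 1e-6) {
  structure(list(n_starts = n_starts, seed = seed, fixed = fixed,
                 stim_upper = stim_upper, init_upper = init_upper,
                 dose_upper = dose_upper, max_iter = max_iter,
                 rtol_sim = rtol_sim), class = "fit_config")
}

## free parameter bounds for a model variant + data doses
.fit_bounds <- function(model_id, doses, config) {
  binding <- if (model_id == "III")
    c("b_E2_ER", "b_E2_ER_PR", "b_E2_ER_PR_GREB1")
  else c("b_E2_ER", "b_E2_ER_GREB1")
  degr <- if (model_id == "III")
    c("d_ER", "d_E2_ER", "d_E2_ER_PR", "d_E2_ER_PR_GREB1",
      "d_GREB1", "d_PR", "d_TFF1")
  else c("d_ER", "d_E2_ER", "d_E2_ER_GREB1", "d_GREB1", "d_PR", "d_TFF1")
  stim <- c("stim_GREB1", "stim_PR", "stim_TFF1")
  inits <- c("ER_init", "GREB1_init", "PR_init", "TFF1_init")
  dose_par <- paste0("eff_", doses[-1])  # lowest dose pinned at 0.001
  b <- rbind(
    data.frame(name = c(binding, degr), lower = 1e-4, upper = 1, log = TRUE),
    data.frame(name = stim, lower = 1e-3, upper = config$stim_upper, log = TRUE),
    data.frame(name = inits, lower = 1e-3, upper = config$init_upper, log = TRUE),
    data.frame(name = dose_par, lower = 1e-3, upper = config$dose_upper,
               log = TRUE)
  )
  b[!(b$name %in% names(config$fixed)), ]
}

## build sig_params + dose map from a named parameter vector
.vec_to_params <- function(v, model_id, doses, config, template) {
  p <- template
  for (nm in names(config$fixed))
    if (!startsWith(nm, "eff_")) p[[nm]] <- config$fixed[[nm]]
  for (nm in names(v)) if (!startsWith(nm, "eff_")) p[[nm]] <- unname(v[nm])
  fx <- names(config$fixed)
  eff_all <- c(unlist(config$fixed[startsWith(as.character(fx), "eff_")]),
               v[startsWith(names(v), "eff_")])
  eff <- c(0.001, unname(eff_all[paste0("eff_", doses[-1])]))
  p$dose_map <- stats::setNames(eff, as.character(doses))
  derive_synthesis(p)
}

#' Fit a signaling model to dose-time reporter data
#'
#' Multi-start bounded least squares (Levenberg-Marquardt with
#' finite-difference Jacobians). Every candidate satisfies the steady-state
#' constraint structurally: synthesis rates are re-derived from the current
#' degradation rates and initial states before each objective evaluation.
#' Effective dose concentrations are fitted jointly, with the lowest dose
#' pinned at 0.001; complex initial states are fixed at 0. Replicates enter
#' the loss as separate residual rows. Converged starts are clustered into
#' optima (cost within 1% relative, normalized parameter L-infinity
#' distance below 5%).
#'
#' @param model_id Model variant.
#' @param data data.frame `time_h`, `nominal_dose_nM`, `replicate`,
#'   `reporter` (GREB1/PR/TFF1), `value` — normalized observables.
#' @param config A [fit_config()].
#' @return A `sig_fit` object with elements `params` (best-fit
#'   `sig_params`), `cost`, `starts` (per-start costs and convergence),
#'   `clusters`, `config`; methods: print, summary, coef, predict.
#' @export
fit_signaling <- function(model_id, data, config = fit_config()) {
  model_id <- match.arg(model_id, .SIG_MODELS)
  need <- c("time_h", "nominal_dose_nM", "replicate", "reporter", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  doses <- sort(unique(data$nominal_dose_nM))
  times <- sort(unique(data$time_h))
  if (length(doses) < 2 || length(times) < 5)
    stop("need at least 2 doses and 5 timepoints")
  rep_col <- match(data$reporter, c("GREB1", "PR", "TFF1"))
  if (anyNA(rep_col)) stop("reporter must be GREB1, PR or TFF1")
  obs_col <- c("GREB1_total", "PR_total", "TFF1")[rep_col]

  template <- sig_params(model_id)
  bounds <- .fit_bounds(model_id, doses, config)
  starts <- latin_hypercube_init(config$n_starts, bounds, seed = config$seed)

  drow <- match(data$nominal_dose_nM, doses)
  trow <- match(data$time_h, times)

  residual_fun <- function(theta) {
    v <- stats::setNames(exp(theta), bounds$name)
    p <- .vec_to_params(v, model_id, doses, config, template)
    pred <- matrix(NA_real_, length(times) * length(doses), 3,
                   dimnames = list(NULL, c("GREB1_total", "PR_total", "TFF1")))
    for (k in seq_along(doses)) {
      tr <- try(simulate_signaling(model_id, p,
                                   e2_free(unname(p$dose_map[k])),
                                   t_grid = times,
                                   rtol = config$rtol_sim,
                                   atol = config$rtol_sim * 1e-2),
                silent = TRUE)
      if (inherits(tr, "try-error")) return(rep(1e4, nrow(data)))
      ot <- observable_totals(tr, model_id)
      pred[(k - 1) * length(times) + seq_along(times), ] <-
        as.matrix(ot[, c("GREB1_total", "PR_total", "TFF1")])
    }
    idx <- cbind((drow - 1) * length(times) + trow, rep_col)
    pred[idx] - data$value
  }

  lower <- log(bounds$lower); upper <- log(bounds$upper)
  res_list <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    th0 <- log(pmin(pmax(starts[i, ], bounds$lower), bounds$upper))
    fit <- try(minpack.lm::nls.lm(
      par = th0, fn = residual_fun, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                           ptol = 1e-10, ftol = 1e-10)),
      silent = TRUE)
    if (inherits(fit, "try-error")) {
      res_list[[i]] <- list(cost = Inf, par = starts[i, ], ok = FALSE,
                            message = as.character(fit))
    } else {
      res_list[[i]] <- list(cost = sum(fit$fvec^2),
                            par = stats::setNames(exp(fit$par), bounds$name),
                            ok = TRUE, message = fit$message)
    }
  }
  costs <- vapply(res_list, `[[`, numeric(1), "cost")
  if (all(!is.finite(costs)))
    stop("all optimization starts failed; first message: ",
         res_list[[1]]$message)

  clusters <- .cluster_optima(res_list, bounds)
  best <- res_list[[which.min(costs)]]
  params <- .vec_to_params(best$par, model_id, doses, config, template)
  structure(list(
    model_id = model_id, params = params, cost = best$cost,
    best_par = best$par,
    starts = data.frame(start = seq_along(costs), cost = costs,
                        converged = vapply(res_list, `[[`, logical(1), "ok"),
                        cluster = clusters$assignment),
    clusters = clusters$summary,
    doses = doses, times = times, config = config,
    data = data
  ), class = "sig_fit")
}

## group converged starts into optima: cost within 1% relative and
## normalized L-infinity parameter distance < 5%
.cluster_optima <- function(res_list, bounds) {
  ok <- which(vapply(res_list, function(r) is.finite(r$cost), logical(1)))
  ord <- ok[order(vapply(res_list[ok], `[[`, numeric(1), "cost"))]
  assignment <- rep(NA_integer_, length(res_list))
  reps <- list()
  span <- log(bounds$upper) - log(bounds$lower)
  for (i in ord) {
    par_i <- log(res_list[[i]]$par)
    placed <- FALSE
    for (k in seq_along(reps)) {
      rk <- reps[[k]]
      rel_cost <- abs(res_list[[i]]$cost - rk$cost) /
        max(rk$cost, .Machine$double.eps)
      dist <- max(abs(par_i - rk$par) / span)
      if (rel_cost < 0.01 && dist < 0.05) {
        assignment[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1]] <- list(par = par_i, cost = res_list[[i]]$cost)
      assignment[i] <- length(reps)
    }
  }
  summary <- data.frame(
    cluster = seq_along(reps),
    cost = vapply(reps, `[[`, numeric(1), "cost"),
    n_starts = vapply(seq_along(reps), function(k)
      sum(assignment == k, na.rm = TRUE), integer(1))
  )
  list(assignment = assignment, summary = summary)
}

#' @export
print.sig_fit <- function(x, ...) {
  cat("Signaling model fit (Model ", x$model_id, ")\n", sep = "")
  cat("  ", nrow(x$starts), " starts, best cost ", signif(x$cost, 5),
      ", ", nrow(x$clusters), " optimum cluster(s)\n", sep = "")
  cat("  doses (nM): ", paste(x$doses, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.sig_fit <- function(object, ...) object$best_par

#' @export
summary.sig_fit <- function(object, ...) {
  structure(list(model_id = object$model_id, cost = object$cost,
                 clusters = object$clusters,
                 coef = object$best_par,
                 dose_map = object$params$dose_map,
                 n_data = nrow(object$data)), class = "summary.sig_fit")
}

#' @export
print.summary.sig_fit <- function(x, ...) {
  cat("Model ", x$model_id, " fit to ", x$n_data, " observations\n",
      "best cost: ", signif(x$cost, 6), "\noptimum clusters:\n", sep = "")
  print(x$clusters)
  cat("coefficients:\n"); print(signif(x$coef, 4))
  invisible(x)
}

#' @export
predict.sig_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$times else sort(unique(newdata$time_h))
  out <- NULL
  for (k in seq_along(object$doses)) {
    tr <- simulate_signaling(object$model_id, object$params,
                             e2_free(unname(object$params$dose_map[k])),
                             t_grid = times)
    ot <- observable_totals(tr, object$model_id)
    ot$nominal_dose_nM <- object$doses[k]
    out <- rbind(out, ot)
  }
  out
}

#' Fit the elementary starvation degradation model
#'
#' Per-protein exponential decay rates from starvation time courses, by
#' nonlinear least squares (`X0 * exp(-d t)`, both free) initialized from
#' the closed-form log-linear slope.
#'
#' @param data data.frame `time_h`, `reporter`, `value` (optionally
#'   `replicate`); values must be positive.
#' @return A `deg_fit`: list with `rates` (named d_GREB1/d_PR/d_TFF1 where
#'   present), `x0`, `fits` per reporter; print and coef methods.
#' @export
fit_degradation <- function(data) {
  stopifnot(all(c("time_h", "reporter", "value") %in% names(data)))
  if (any(data$value <= 0)) stop("intensities must be positive")
  fits <- lapply(split(data, data$reporter), function(d) {
    sl <- stats::lm(log(value) ~ time_h, data = d)
    d0 <- max(-unname(stats::coef(sl)[2]), 0)
    x0 <- exp(unname(stats::coef(sl)[1]))
    fit <- minpack.lm::nls.lm(
      par = c(log_x0 = log(x0), d = d0),
      fn = function(p) exp(p[1]) * exp(-max(p[2], 0) * d$time_h) - d$value,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    c(x0 = exp(fit$par[[1]]), d = max(fit$par[[2]], 0),
      cost = sum(fit$fvec^2))
  })
  rep_names <- names(fits)
  rates <- stats::setNames(vapply(fits, `[`, numeric(1), "d"),
                           paste0("d_", rep_names))
  x0 <- stats::setNames(vapply(fits, `[`, numeric(1), "x0"), rep_names)
  structure(list(rates = rates, x0 = x0, fits = fits), class = "deg_fit")
}

#' @export
coef.deg_fit <- function(object, ...) object$rates

#' @export
print.deg_fit <- function(x, ...) {
  cat("Starvation degradation fit\n")
  print(signif(x$rates, 5))
  invisible(x)
}
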