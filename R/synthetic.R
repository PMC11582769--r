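#' Synthetic-data generator configuration
#'
#' @param seed RNG seed (all generators are bit-reproducible under it).
#' @param doses_nM Nominal doses for expression tables.
#' @param times_h Measurement times (h).
#' @param replicates Biological replicates.
#' @param noise_sd Multiplicative lognormal sigma for intensities
#'   (default 0.1).
#' @param frame_interval_h FUCCI imaging interval (default 0.5).
#' @param g1_h,g1s_h,sg2m_h Scripted phase lengths (h).
#' @param n_frames FUCCI movie length in frames.
#' @param n_roots Number of founder cells.
#' @param field_px Label-movie field size (square).
#' @param n_nuclei Nuclei per field.
#' @param radius_px Nucleus semi-axis range.
#' @param drift_px Centroid drift per frame.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         doses_nM = c(0.001, 0.01, 0.1, 1, 10, 100),
                         times_h = 0:55, replicates = 3, noise_sd = 0.1,
                         frame_interval_h = 0.5, g1_h = 16, g1s_h = 6,
                         sg2m_h = 20, n_frames = 170, n_roots = 2,
                         field_px = 96, n_nuclei = 4,
                         radius_px = c(5, 8), drift_px = 2) {
  stopifnot(noise_sd >= 0, all(doses_nM >= 0))
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a dose-time reporter expression table
#'
#' Simulates the chosen signaling model per dose (exposure from the
#' unexposed steady state, free E2 depletion), evaluates the observable
#' totals, and multiplies by per-measurement lognormal replicate noise.
#' The generating parameters are returned as ground truth.
#'
#' @param model_id Model variant.
#' @param params `sig_params` ground truth (default reference set).
#' @param config A [synth_config()].
#' @param raw_with_dmso Also emit unnormalized E2 + DMSO control rows (for
#'   exercising [preprocess_population()]); the DMSO baseline decays slowly
#'   as in the measured control wells.
#' @return List `data` (`time_h`, `nominal_dose_nM`, `replicate`,
#'   `reporter`, `value`[, `treatment`]), `truth` (params).
#' @export
gen_expression_data <- function(model_id = "III", params = NULL,
                                config = synth_config(),
                                raw_with_dmso = FALSE) {
  if (is.null(params)) params <- sig_params(model_id)
  set.seed(config$seed)
  doses <- config$doses_nM
  rows <- list()
  for (d in doses) {
    eff <- effective_dose(params, d)
    tr <- simulate_signaling(model_id, params, e2_free(eff), config$times_h)
    ot <- observable_totals(tr, model_id)
    for (rep_i in seq_len(config$replicates)) {
      for (rp in c("GREB1", "PR", "TFF1")) {
        col <- c(GREB1 = "GREB1_total", PR = "PR_total", TFF1 = "TFF1")[rp]
        noise <- if (config$noise_sd > 0)
          stats::rlnorm(nrow(ot), -config$noise_sd^2 / 2, config$noise_sd)
        else 1
        rows[[length(rows) + 1]] <- data.frame(
          time_h = ot$time, nominal_dose_nM = d, replicate = rep_i,
          reporter = rp, value = ot[[col]] * noise)
      }
    }
  }
  data <- do.call(rbind, rows)
  if (raw_with_dmso) {
    base <- function(t) 100 * exp(-0.004 * t)  # slow control decline
    data$treatment <- "E2"
    data$value <- data$value * base(data$time_h)
    dm <- unique(data[, c("time_h", "replicate", "reporter")])
    dm <- dm[rep(seq_len(nrow(dm)), each = 2), ]
    dm$tech_rep <- rep(1:2, length.out = nrow(dm))
    dm$nominal_dose_nM <- 0
    dm$treatment <- "DMSO"
    dm$value <- base(dm$time_h) *
      if (config$noise_sd > 0)
        stats::rlnorm(nrow(dm), -config$noise_sd^2 / 2, config$noise_sd)
      else 1
    dm$tech_rep <- NULL
    data <- rbind(data, dm[, names(data)])
  }
  list(data = data, truth = params)
}

## phase-keyed intensity plateaus (normalized units)
.FUCCI_LEVELS <- list(
  G1   = c(cdt1 = 0.80, geminin = 0.002),
  G1S  = c(cdt1 = 0.30, geminin = 0.300),
  SG2M = c(cdt1 = 0.002, geminin = 0.80)
)

## transition-step placements (in frames, relative to the scripted phase
## boundary) chosen so that the centred-10 rolling mean + log-ratio rules
## recover the scripted boundaries exactly on noiseless tracks
.FUCCI_SHIFTS <- c(g1_to_g1s = 4L, g1s_to_sg2m = -5L, division = 3L)

#' Generate synthetic FUCCI tracks with scripted phases
#'
#' Builds a binary lineage tree of cells cycling through scripted G1, G1/S
#' and S-G2-M phases; Cdt1 is high in G1 and low from S onward, Geminin
#' rises at G1/S and drops sharply at division (the drop exceeds the
#' division-detection threshold), and the first post-division frame is
#' colorless. Intensity plateaus switch at transition frames offset from
#' the scripted boundaries so that the smoothing and log-ratio rules of the
#' track pipeline recover the scripted phases exactly in the noiseless
#' case. One daughter reuses her mother's object ID (as tracker exports
#' do); the other gets a fresh ID with `parent_id` set.
#'
#' @param config A [synth_config()].
#' @param n_divisions Divisions per founder lineage (tree depth; default 1).
#' @return List `data` (raw tracking table: `frame`, `object_id`,
#'   `parent_id`, `x`, `y`, `cdt1`, `geminin`, `hoechst`, `area`), `truth`
#'   (per-row `true_phase`, per-object lineage), `config`.
#' @export
gen_fucci_tracks <- function(config = synth_config(), n_divisions = 1) {
  set.seed(config$seed)
  fi <- config$frame_interval_h
  lens <- c(G1 = round(config$g1_h / fi), G1S = round(config$g1s_h / fi),
            SG2M = round(config$sg2m_h / fi))
  cyc <- sum(lens)
  nf <- config$n_frames

  ## per-founder: phase index sequence for a full lineage path; the tree is
  ## symmetric, so the phase script depends only on the founder offset
  next_oid <- 1L
  rows <- list()
  emit_cell <- function(start_frame, phase_pos, oid, parent, x0, y0, depth) {
    ## phase_pos: 0-based position within the cycle at start_frame
    frames <- start_frame:nf
    if (!length(frames)) return(invisible())
    pos <- (phase_pos + seq_along(frames) - 1) %% cyc
    phase <- ifelse(pos < lens["G1"], "G1",
                    ifelse(pos < lens["G1"] + lens["G1S"], "G1S", "SG2M"))
    ## the cell splits at the end of S-G2-M, unless the lineage has reached
    ## its scripted division budget (then the track just runs on)
    div_at <- which(pos == cyc - 1)
    split_here <- length(div_at) && depth < n_divisions
    last <- if (split_here) frames[div_at[1]] else max(frames)
    keep <- frames <= last
    frames <- frames[keep]; phase <- phase[keep]; pos <- pos[keep]
    rows[[length(rows) + 1]] <<- data.frame(
      frame = frames, object_id = oid, parent_id = parent,
      x = x0 + 0.2 * (frames - start_frame), y = y0,
      true_phase = phase, pos = pos, stringsAsFactors = FALSE)
    if (split_here && last < nf) {
      ## two daughters start at the next frame in G1 (position 0)
      d2 <- next_oid; next_oid <<- next_oid + 1L
      emit_cell(last + 1L, 0, oid, NA_integer_, x0 - 6, y0 + 6, depth + 1L)
      emit_cell(last + 1L, 0, d2, oid, x0 + 6, y0 - 6, depth + 1L)
    }
    invisible()
  }
  offsets <- floor(stats::runif(config$n_roots) * cyc)
  for (rt in seq_len(config$n_roots)) {
    oid <- next_oid; next_oid <- next_oid + 1L
    emit_cell(1L, offsets[rt], oid, NA_integer_,
              x0 = 20 + 40 * (rt - 1), y0 = 30, depth = 0L)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$object_id, tab$frame), ]

  ## intensity construction per lineage path: steps offset from boundaries
  lv <- .FUCCI_LEVELS; sh <- .FUCCI_SHIFTS
  step_phase <- function(pos) {
    ## effective plateau selector given the shifted step positions
    p <- ifelse(pos < lens["G1"] + sh["g1_to_g1s"], "G1",
                ifelse(pos < lens["G1"] + lens["G1S"] + sh["g1s_to_sg2m"],
                       "G1S", "SG2M"))
    ## division shift: the first sh["division"] frames of G1 still show
    ## S-G2-M levels (the visible drop comes sh["division"] frames after
    ## the scripted boundary)
    p[pos < sh["division"]] <- "SG2M"
    p
  }
  eff <- step_phase(tab$pos)
  ## colorless frame: the division drop itself
  colorless <- tab$pos == sh["division"]
  tab$cdt1 <- vapply(eff, function(p) lv[[p]]["cdt1"], numeric(1))
  tab$geminin <- vapply(eff, function(p) lv[[p]]["geminin"], numeric(1))
  tab$cdt1[colorless] <- 0
  tab$geminin[colorless] <- 0
  ## a cell present at frame 1 shows its phase levels unshifted (no
  ## pre-history): not needed, plateaus already defined for all pos
  tab$hoechst <- 0.4 + 0.2 * tab$frame / nf   # slow drift, keeps the
  tab$area <- 70 + 20 * tab$frame / nf        # channels non-degenerate
  if (config$noise_sd > 0) {
    nfac <- stats::rlnorm(2 * nrow(tab), -config$noise_sd^2 / 2,
                          config$noise_sd)
    tab$cdt1 <- tab$cdt1 * nfac[seq_len(nrow(tab))]
    tab$geminin <- tab$geminin * nfac[nrow(tab) + seq_len(nrow(tab))]
  }
  truth <- tab[, c("frame", "object_id", "true_phase")]
  data <- tab[, c("frame", "object_id", "parent_id", "x", "y",
                  "cdt1", "geminin", "hoechst", "area")]
  rownames(data) <- rownames(truth) <- NULL
  list(data = data, truth = truth, config = config)
}

#' Generate a synthetic label-image movie of drifting nuclei
#'
#' Elliptical nuclei drift with bounded per-frame displacement; an optional
#' scripted split replaces one nucleus by two adjacent daughters. Ground
#' truth lineage is returned. Overlapping nuclei (beyond touching) raise an
#' error.
#'
#' @param config A [synth_config()].
#' @param split Optional list `frame`, `nucleus` scripting one division.
#' @return List `labels` (list of integer matrices), `truth` (data.frame
#'   `frame`, `label`, `cell`, `parent`), `config`.
#' @export
gen_label_movie <- function(config = synth_config(), split = NULL) {
  set.seed(config$seed)
  n <- config$n_nuclei
  side <- config$field_px
  nfr <- min(config$n_frames, 40L)
  rad <- stats::runif(n, config$radius_px[1], config$radius_px[2])
  ## rejection-sampled non-touching placement; failure = geometry error
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      x <- stats::runif(1, side * 0.15, side * 0.85)
      y <- stats::runif(1, side * 0.15, side * 0.85)
      if (i == 1 || all(sqrt((x - cx[seq_len(i - 1)])^2 +
                               (y - cy[seq_len(i - 1)])^2) >
                          rad[i] + rad[seq_len(i - 1)] + 4)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("cannot place ", n, " non-overlapping nuclei in a ", side,
           "px field: overlapping-beyond-merge geometry")
  }
  alive <- data.frame(cell = seq_len(n), parent = NA_integer_,
                      x = cx, y = cy, a = rad, b = rad * 0.8)
  next_cell <- n + 1L
  paint <- function(al) {
    L <- matrix(0L, side, side)
    xs <- row(L); ys <- col(L)
    for (i in seq_len(nrow(al))) {
      m <- ((xs - al$x[i]) / al$a[i])^2 + ((ys - al$y[i]) / al$b[i])^2 <= 1
      if (any(L[m] != 0))
        stop("nuclei overlap beyond merge tolerance at cell ", al$cell[i])
      L[m] <- al$cell[i]
    }
    L
  }
  labels <- vector("list", nfr)
  truth <- list()
  for (f in seq_len(nfr)) {
    if (!is.null(split) && f == split$frame) {
      i <- which(alive$cell == split$nucleus)
      stopifnot(length(i) == 1)
      mom <- alive[i, ]
      da <- mom$a * 0.45
      off <- 2 * da + 3
      d1 <- transform(mom, cell = next_cell, parent = mom$cell,
                      x = mom$x - off / 2, a = da, b = mom$b * 0.45)
      d2 <- transform(mom, cell = next_cell + 1L, parent = mom$cell,
                      x = mom$x + off / 2, a = da, b = mom$b * 0.45)
      next_cell <- next_cell + 2L
      alive <- rbind(alive[-i, ], d1, d2)
    }
    if (f > 1) {
      ## drift with collision avoidance: retry directions, else stay put
      for (i in seq_len(nrow(alive))) {
        for (try in 1:8) {
          ang <- stats::runif(1, 0, 2 * pi)
          nx <- min(max(alive$x[i] + config$drift_px * cos(ang),
                        alive$a[i] + 1), side - alive$a[i] - 1)
          ny <- min(max(alive$y[i] + config$drift_px * sin(ang),
                        alive$b[i] + 1), side - alive$b[i] - 1)
          oth <- setdiff(seq_len(nrow(alive)), i)
          if (!length(oth) ||
              all(sqrt((nx - alive$x[oth])^2 + (ny - alive$y[oth])^2) >
                    alive$a[i] + alive$a[oth] + 2)) {
            alive$x[i] <- nx; alive$y[i] <- ny; break
          }
        }
      }
    }
    labels[[f]] <- paint(alive)
    truth[[f]] <- data.frame(frame = f, label = alive$cell,
                             cell = alive$cell, parent = alive$parent)
  }
  list(labels = labels, truth = do.call(rbind, truth), config = config)
}
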