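#' Relabel lineage tracks with dotted identifiers
#'
#' Tracker exports reuse object IDs across divisions (a daughter may keep
#' her mother's ID). Division events are recovered from parent links: when
#' new objects appear with `parent_id` pointing at an existing track, the
#' mother's samples up to that frame keep her ID, and the continuation plus
#' each new object become dotted children (`1 -> 1.1, 1.2`; grandchildren
#' `1.1.1`, `1.1.2`, ...). For every final-generation descendant a `family`
#' track is built containing all ancestor samples.
#'
#' @param raw data.frame with columns `frame`, `object_id`, `parent_id`
#'   (NA when none) and measurement columns (x, y, cdt1, geminin, hoechst,
#'   area, ...).
#' @return List with `tracks` (raw plus `track_id` dotted strings and
#'   `parent_track`) and `families` (data.frame rows replicated per family
#'   with `family_id` and `segment_id`).
#' @export
relabel_lineages <- function(raw) {
  stopifnot(all(c("frame", "object_id", "parent_id") %in% names(raw)))
  raw <- raw[order(raw$object_id, raw$frame), ]
  ids <- unique(raw$object_id)

  kids <- split(raw$object_id[!is.na(raw$parent_id) &
                                !duplicated(raw$object_id)],
                raw$parent_id[!is.na(raw$parent_id) &
                                !duplicated(raw$object_id)])
  first_frame <- tapply(raw$frame, raw$object_id, min)

  ## guard against cyclic parent links
  par_of <- tapply(raw$parent_id, raw$object_id, function(p) p[1])
  for (id in ids) {
    seen <- character(); cur <- as.character(id)
    while (!is.na(par_of[cur])) {
      if (cur %in% seen) stop("cyclic parent links at object ", cur)
      seen <- c(seen, cur)
      cur <- as.character(par_of[cur])
      if (!cur %in% names(par_of)) break
    }
  }

  raw$track_id <- as.character(raw$object_id)
  raw$parent_track <- NA_character_

  ## process divisions in frame order: each division of track T at frame f
  ## renames T's samples at frames >= f to T.1 and assigns the newborn
  ## object(s) T.2, T.3, ...
  ev <- data.frame(parent = rep(names(kids), lengths(kids)),
                   child = unlist(kids), stringsAsFactors = FALSE)
  if (nrow(ev)) {
    ev$frame <- first_frame[as.character(ev$child)]
    ev <- ev[order(ev$frame), ]
    for (pid in unique(ev$parent)) {
      sub <- ev[ev$parent == pid, ]
      for (f in unique(sub$frame)) {
        newborn <- sub$child[sub$frame == f]
        sel_parent <- raw$object_id == as.numeric(pid) & raw$frame < f
        cur_tid <- raw$track_id[sel_parent]
        if (!length(cur_tid)) next
        tid <- cur_tid[length(cur_tid)]  # current dotted id of the mother
        cont <- raw$object_id == as.numeric(pid) & raw$frame >= f
        k <- 1L
        if (any(cont)) {
          raw$track_id[cont] <- paste0(tid, ".", k)
          raw$parent_track[cont] <- tid
          k <- k + 1L
        }
        for (nb in newborn) {
          sel <- raw$object_id == nb
          raw$track_id[sel] <- paste0(tid, ".", k)
          raw$parent_track[sel] <- tid
          k <- k + 1L
        }
      }
    }
  }

  ## family track per leaf (track without children)
  parents <- unique(stats::na.omit(raw$parent_track))
  all_tr <- unique(raw$track_id)
  leaves <- setdiff(all_tr, parents)
  fam <- lapply(leaves, function(lf) {
    chain <- lf
    while (TRUE) {
      par <- raw$parent_track[raw$track_id == chain[1]][1]
      if (is.na(par)) break
      chain <- c(par, chain)
    }
    d <- raw[raw$track_id %in% chain, ]
    d <- d[order(d$frame), ]
    d$family_id <- lf
    d$segment_id <- d$track_id
    d
  })
  list(tracks = raw, families = do.call(rbind, fam))
}

#' Filter unreliable tracks
#'
#' The three rules, in order: (1) drop tracks shorter than 5 timepoints that
#' have no descendants; (2) drop family tracks of 30 timepoints or fewer;
#' (3) drop family tracks with more than `max_divisions` Geminin-drop
#' divisions ([detect_divisions()]).
#'
#' @param rel Output of [relabel_lineages()].
#' @param max_divisions Division cap (default 4).
#' @return List `families` (retained family rows) and `audit` (removal
#'   counts per rule).
#' @export
filter_tracks <- function(rel, max_divisions = 4) {
  tracks <- rel$tracks
  fam <- rel$families
  audit <- c(short_no_descendants = 0L, short_family = 0L,
             too_many_divisions = 0L)

  len <- table(tracks$track_id)
  has_child <- unique(stats::na.omit(tracks$parent_track))
  drop1 <- names(len)[len < 5 & !(names(len) %in% has_child)]
  audit["short_no_descendants"] <- length(drop1)
  fam <- fam[!(fam$segment_id %in% drop1), ]
  fam <- fam[!(fam$family_id %in% drop1), ]

  flen <- table(fam$family_id)
  drop2 <- names(flen)[flen <= 30]
  audit["short_family"] <- length(drop2)
  fam <- fam[!(fam$family_id %in% drop2), ]

  ndiv <- vapply(split(fam$geminin, fam$family_id),
                 function(g) length(detect_divisions(g)), integer(1))
  drop3 <- names(ndiv)[ndiv > max_divisions]
  audit["too_many_divisions"] <- length(drop3)
  fam <- fam[!(fam$family_id %in% drop3), ]

  list(families = fam, audit = audit)
}

#' Min-max normalization per channel
#'
#' `x' = (x - min(x)) / (max(x) - min(x))`, applied to all measurements of
#' one readout channel within one experiment.
#'
#' @param x Numeric vector.
#' @return Normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (diff(r) <= 0) stop("degenerate normalization: channel is constant")
  (x - r[1]) / (r[2] - r[1])
}

#' Rolling mean with centred or trailing window
#'
#' Centred windows of even width put the extra sample on the left (window
#' 10 = 5 left + focal + 4 right); edges shrink to the available samples.
#' Trailing windows cover the current and previous `window - 1` samples.
#'
#' @param x Numeric vector.
#' @param window Window size in samples (>= 1).
#' @param mode `"centered"` or `"trailing"`.
#' @return Smoothed vector of the same length.
#' @export
rolling_mean <- function(x, window, mode = c("centered", "trailing")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1)
  n <- length(x)
  if (window == 1 || n == 0) return(x)
  cs <- cumsum(c(0, x))
  if (mode == "centered") {
    left <- ceiling((window - 1) / 2); right <- window - 1 - left
    lo <- pmax(seq_len(n) - left, 1)
    hi <- pmin(seq_len(n) + right, n)
  } else {
    lo <- pmax(seq_len(n) - window + 1, 1)
    hi <- seq_len(n)
  }
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect cell divisions from the Geminin readout
#'
#' Geminin is smoothed with a trailing 2-sample rolling mean; a division is
#' flagged at every sample whose drop from the previous sample exceeds half
#' the standard deviation of the smoothed series (`d < -0.5 * SD`).
#'
#' @param geminin Numeric Geminin intensity series (one track).
#' @return Integer indices (positions of the post-drop samples).
#' @export
detect_divisions <- function(geminin) {
  if (length(geminin) < 3) return(integer())
  g <- rolling_mean(geminin, 2, "trailing")
  d <- diff(g)
  thr <- -0.5 * stats::sd(g)
  idx <- which(d < thr) + 1L
  if (!length(idx)) return(integer())
  ## the trailing smoothing spreads one drop over adjacent differences;
  ## consecutive flagged samples are one division event
  idx[c(TRUE, diff(idx) > 1)]
}

#' Log-transformed Geminin:Cdt1 ratio with sentinels
#'
#' `r = -100` when Geminin is 0, or both channels are below 1e-4;
#' `r = +100` when Cdt1 is 0 and Geminin exceeds 1e-4; otherwise
#' `log10(Geminin/Cdt1)` (infinite values from the remaining degenerate
#' corner are mapped onto the matching sentinel).
#'
#' @param geminin,cdt1 Smoothed, min-max-normalized intensities.
#' @return Numeric vector of log ratios.
#' @export
compute_log_ratio <- function(geminin, cdt1) {
  stopifnot(length(geminin) == length(cdt1))
  r <- numeric(length(geminin))
  s_neg <- geminin == 0 | (geminin < 1e-4 & cdt1 < 1e-4)
  s_pos <- !s_neg & cdt1 == 0 & geminin > 1e-4
  rest <- !s_neg & !s_pos
  r[s_neg] <- -100
  r[s_pos] <- 100
  r[rest] <- log10(geminin[rest] / cdt1[rest])
  r[rest & !is.finite(r)] <- sign(r[rest & !is.finite(r)]) * 100
  r[is.nan(r)] <- -100
  r
}

#' Assign cell-cycle phases from log ratio and channel intensities
#'
#' G1/S when `|r| < 2` (sentinels excluded); otherwise G1 when `r == -100`
#' or Cdt1 > Geminin; otherwise S-G2-M when `r == 100` or Geminin > Cdt1.
#' A sample matching none of the rules (exact tie) carries the previous
#' phase forward with a warning.
#'
#' @param r Log ratios from [compute_log_ratio()].
#' @param cdt1,geminin Smoothed intensities.
#' @return Character vector of phases (`G1`, `G1S`, `SG2M`).
#' @export
assign_phases <- function(r, cdt1, geminin) {
  n <- length(r)
  ph <- character(n)
  sent <- abs(r) == 100
  g1s <- !sent & abs(r) < 2
  g1 <- !g1s & (r == -100 | cdt1 > geminin)
  sgm <- !g1s & !g1 & (r == 100 | geminin > cdt1)
  ph[g1s] <- "G1S"; ph[g1] <- "G1"; ph[sgm] <- "SG2M"
  if (any(ph == "")) {
    warning(sum(ph == ""), " unassignable sample(s); carrying previous phase")
    for (i in which(ph == "")) ph[i] <- if (i > 1) ph[i - 1] else "G1"
  }
  ph
}

#' Remove transient phase flips
#'
#' Runs of at most `max_len` samples flanked on both sides by one and the
#' same phase are overwritten with the flanking phase, repeatedly until a
#' fixpoint is reached.
#'
#' @param phases Character vector of phase labels.
#' @param max_len Maximal length of a transient run (default 4).
#' @return Corrected phase vector.
#' @export
correct_transient_flips <- function(phases, max_len = 4) {
  repeat {
    r <- rle(phases)
    k <- length(r$lengths)
    changed <- FALSE
    if (k >= 3) {
      for (j in seq_len(k - 2)) {
        ## excursion away from phase X returning to X: the runs between the
        ## j-th X-run and the next X-run, if jointly short enough
        back <- which(r$values[(j + 1):k] == r$values[j])
        if (!length(back)) next
        nxt <- j + back[1]
        if (nxt == j + 1) next
        mid <- (j + 1):(nxt - 1)
        if (sum(r$lengths[mid]) <= max_len) {
          r$values[mid] <- r$values[j]
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) return(inverse.rle(r))
    phases <- inverse.rle(r)
  }
}

#' Correct forbidden G1/S calls across mitosis
#'
#' During mitosis the log ratio can transiently fall below 2, producing an
#' S-G2-M -> G1/S -> G1 sequence; the G1/S run is relabelled G1. A direct
#' S-G2-M -> G1/S -> S-G2-M excursion is left untouched, as is a track
#' ending in G1/S right after S-G2-M (flagged via attribute).
#'
#' @param phases Character vector of phase labels.
#' @return Corrected phase vector (attribute `flagged_tail` when the track
#'   ends in an uncorrectable G1/S run).
#' @export
correct_mitotic_g1s <- function(phases) {
  r <- rle(phases)
  flagged <- FALSE
  if (length(r$lengths) >= 2) {
    for (j in 2:length(r$lengths)) {
      if (r$values[j] == "G1S" && r$values[j - 1] == "SG2M") {
        if (j < length(r$lengths) && r$values[j + 1] == "G1")
          r$values[j] <- "G1"
        else if (j == length(r$lengths)) flagged <- TRUE
      }
    }
  }
  out <- inverse.rle(r)
  ## merging may create new adjacency; normalize
  attr(out, "flagged_tail") <- flagged
  out
}

#' Call cell-cycle phases on filtered family tracks
#'
#' The full per-track pipeline: min-max normalization per channel across the
#' experiment is assumed done; per family track the readouts are smoothed
#' with a centred 10-sample rolling mean, the log ratio and raw phases are
#' computed, and both corrections are applied.
#'
#' @param families Family-track data.frame (columns `family_id`, `frame`,
#'   `cdt1`, `geminin`).
#' @return Input with added columns `cdt1_s`, `geminin_s`, `log_ratio`,
#'   `phase`.
#' @export
call_phases <- function(families) {
  out <- lapply(split(families, families$family_id), function(d) {
    d <- d[order(d$frame), ]
    d$cdt1_s <- rolling_mean(d$cdt1, 10, "centered")
    d$geminin_s <- rolling_mean(d$geminin, 10, "centered")
    d$log_ratio <- compute_log_ratio(d$geminin_s, d$cdt1_s)
    ph <- assign_phases(d$log_ratio, d$cdt1_s, d$geminin_s)
    ph <- correct_transient_flips(ph)
    ph <- correct_mitotic_g1s(ph)
    d$phase <- as.character(ph)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quantify phase durations on deduplicated family tracks
#'
#' Ancestor segments shared between sibling families are counted once: each
#' segment is owned by the first family (in sorted family order) containing
#' it, remaining subtracks of 5 or fewer samples are dropped, and each phase
#' run is attributed to the family owning the sample at which the run
#' starts. Runs touching the observation window boundaries are censored:
#' kept in the table, excluded from summaries.
#'
#' @param called Output of [call_phases()].
#' @param frame_interval_h Imaging interval in hours (e.g. 0.5).
#' @return data.frame `family_id`, `phase`, `start_frame`, `end_frame`,
#'   `n_samples`, `duration_h`, `censored`.
#' @export
quantify_phase_durations <- function(called, frame_interval_h) {
  stopifnot(frame_interval_h > 0)
  fam_ids <- sort(unique(called$family_id))
  t_min <- min(called$frame); t_max <- max(called$frame)
  owned <- character()
  dropped <- 0L
  recs <- list()
  for (fid in fam_ids) {
    d <- called[called$family_id == fid, ]
    d <- d[order(d$frame), ]
    new <- !(d$segment_id %in% owned)
    owned <- union(owned, unique(d$segment_id[new]))
    if (sum(new) <= 5) { dropped <- dropped + 1L; next }
    own_start <- min(d$frame[new])
    r <- rle(d$phase)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$lengths)) {
      f0 <- d$frame[starts[j]]; f1 <- d$frame[ends[j]]
      if (f0 < own_start) next  # run owned by an ancestor's family
      cens <- (f0 <= t_min) || (f1 >= t_max) ||
        (starts[j] == 1) || (ends[j] == length(d$phase))
      recs[[length(recs) + 1]] <- data.frame(
        family_id = fid, phase = r$values[j], start_frame = f0,
        end_frame = f1, n_samples = r$lengths[j],
        duration_h = r$lengths[j] * frame_interval_h, censored = cens)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(family_id = character(), phase = character(),
               start_frame = numeric(), end_frame = numeric(),
               n_samples = integer(), duration_h = numeric(),
               censored = logical())
  attr(out, "dropped_subtracks") <- dropped
  out
}

#' Run the complete FUCCI pipeline on a raw tracking table
#'
#' Relabel, filter, normalize, call phases and quantify durations.
#'
#' @param raw Raw tracking table (see [relabel_lineages()]).
#' @param frame_interval_h Imaging interval (h).
#' @param normalize Min-max normalize cdt1/geminin/hoechst across the
#'   experiment first (default TRUE).
#' @return List `families` (with phase calls), `durations`, `audit`.
#' @export
fucci_pipeline <- function(raw, frame_interval_h = 0.5, normalize = TRUE) {
  if (normalize) {
    for (ch in intersect(c("cdt1", "geminin", "hoechst"), names(raw)))
      raw[[ch]] <- minmax_normalize(raw[[ch]])
  }
  rel <- relabel_lineages(raw)
  flt <- filter_tracks(rel)
  called <- call_phases(flt$families)
  durs <- quantify_phase_durations(called, frame_interval_h)
  list(families = called, durations = durs, audit = flt$audit)
}
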