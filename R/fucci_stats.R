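#' Games-Howell pairwise comparisons
#'
#' Pairwise tests for unequal variances and sample sizes: the statistic
#' `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` is referred to the
#' studentized range distribution with Welch degrees of freedom.
#'
#' @param values Numeric response vector.
#' @param groups Factor/character grouping vector.
#' @return data.frame `group1`, `group2`, `diff`, `se`, `t`, `df`, `p_adj`.
#' @export
games_howell <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  if (any(n < 2)) stop("every group needs at least two observations")
  cmb <- utils::combn(levels(groups), 2)
  out <- apply(cmb, 2, function(g) {
    i <- g[1]; j <- g[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    t_stat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(diff = unname(m[i] - m[j]), se = sqrt(unname(se2)),
      t = unname(t_stat), df = unname(df), p_adj = unname(p))
  })
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ], t(out),
             row.names = NULL)
}

#' Compare phase durations between conditions
#'
#' Per cell-cycle phase: Welch's one-way ANOVA omnibus test followed by
#' Games-Howell pairwise comparisons, on complete (non-censored) duration
#' records. Conditions with fewer than two complete records are skipped
#' with a notice.
#'
#' @param durations data.frame with columns `condition`, `phase`,
#'   `duration_h` and optionally `censored` (censored rows are dropped).
#' @return A `phase_test_report`: per phase, `n` per condition, `welch`
#'   (statistic, df, p) and `pairwise` (Games-Howell table); plus `skipped`.
#' @export
compare_conditions <- function(durations) {
  stopifnot(all(c("condition", "phase", "duration_h") %in% names(durations)))
  if ("censored" %in% names(durations))
    durations <- durations[!durations$censored, ]
  skipped <- character()
  report <- list()
  for (ph in unique(durations$phase)) {
    d <- durations[durations$phase == ph, ]
    cnt <- table(d$condition)
    keep <- names(cnt)[cnt >= 2]
    skipped <- union(skipped,
                     paste0(ph, ":", setdiff(names(cnt), keep)))
    d <- d[d$condition %in% keep, ]
    if (length(keep) < 2) {
      report[[ph]] <- list(n = cnt, welch = NULL, pairwise = NULL)
      next
    }
    d$condition <- factor(d$condition)
    if (all(tapply(d$duration_h, d$condition, stats::var) == 0) &&
        length(unique(d$duration_h)) == 1) {
      welch <- list(statistic = 0, p.value = 1)
    } else {
      aov <- stats::oneway.test(duration_h ~ condition, data = d,
                                var.equal = FALSE)
      welch <- list(statistic = unname(aov$statistic),
                    df = unname(aov$parameter), p.value = aov$p.value)
    }
    report[[ph]] <- list(n = cnt, welch = welch,
                         pairwise = games_howell(d$duration_h, d$condition))
  }
  structure(list(phases = report, skipped = skipped),
            class = "phase_test_report")
}

#' @export
print.phase_test_report <- function(x, ...) {
  for (ph in names(x$phases)) {
    cat("Phase ", ph, ":\n", sep = "")
    r <- x$phases[[ph]]
    if (is.null(r$welch)) { cat("  no test (insufficient records)\n"); next }
    cat(sprintf("  Welch ANOVA F = %.3f, p = %.3g\n",
                r$welch$statistic, r$welch$p.value))
    pw <- r$pairwise
    for (i in seq_len(nrow(pw)))
      cat(sprintf("  %s vs %s: diff = %.3f h, p_adj = %.3g\n",
                  pw$group1[i], pw$group2[i], pw$diff[i], pw$p_adj[i]))
  }
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Link label images into raw tracks
#'
#' Greedy maximum-overlap frame-to-frame linking: each object in frame t+1
#' is linked to the frame-t object with which it overlaps most, provided
#' their centres of mass are within `max_dist` pixels. A frame-t object
#' claimed by two objects is recorded as a division (both daughters receive
#' new object IDs with `parent_id` set); an unlinked object opens a new
#' track.
#'
#' @param labels List of integer label matrices (one per frame).
#' @param intensities Optional named list of lists of matrices (per channel
#'   per frame) whose per-object means are added as columns.
#' @param max_dist Maximal centroid displacement in pixels (default 40).
#' @return data.frame `frame`, `object_id`, `parent_id`, `x`, `y`, `area`
#'   (+ channel means), suitable for [relabel_lineages()].
#' @export
link_tracks <- function(labels, intensities = NULL, max_dist = 40) {
  props <- function(L) {
    ids <- setdiff(sort(unique(as.vector(L))), 0)
    if (!length(ids)) return(NULL)
    idx <- which(L > 0, arr.ind = TRUE)
    lab <- L[L > 0]
    data.frame(id = ids,
               x = tapply(idx[, 1], lab, mean)[as.character(ids)],
               y = tapply(idx[, 2], lab, mean)[as.character(ids)],
               area = as.integer(table(lab)[as.character(ids)]))
  }
  rows <- list()
  next_id <- 1L
  prev_map <- NULL  # label value in previous frame -> track object_id
  prev_lab <- NULL
  for (f in seq_along(labels)) {
    L <- labels[[f]]
    pr <- props(L)
    if (is.null(pr)) { prev_map <- NULL; prev_lab <- NULL; next }
    link <- rep(NA_integer_, nrow(pr))  # previous label value linked to
    if (!is.null(prev_map)) {
      ov <- table(prev_lab[prev_lab > 0 & L > 0], L[prev_lab > 0 & L > 0])
      prev_pr <- props(prev_lab)
      for (i in seq_len(nrow(pr))) {
        cand <- if (as.character(pr$id[i]) %in% colnames(ov))
          stats::setNames(as.numeric(ov[, as.character(pr$id[i])]),
                          rownames(ov)) else NULL
        if (is.null(cand) || !any(cand > 0)) next
        best <- names(cand)[which.max(cand)]
        pp <- prev_pr[prev_pr$id == as.numeric(best), ]
        if (sqrt((pp$x - pr$x[i])^2 + (pp$y - pr$y[i])^2) <= max_dist)
          link[i] <- as.numeric(best)
      }
    }
    obj_id <- integer(nrow(pr)); par_id <- rep(NA_integer_, nrow(pr))
    for (i in seq_len(nrow(pr))) {
      if (is.na(link[i])) {
        obj_id[i] <- next_id; next_id <- next_id + 1L
      }
    }
    if (any(!is.na(link))) {
      for (lv in unique(stats::na.omit(link))) {
        claim <- which(!is.na(link) & link == lv)
        mother <- prev_map[[as.character(lv)]]
        if (length(claim) == 1) {
          obj_id[claim] <- mother
        } else {
          for (i in claim) {  # division: new ids, parent recorded
            obj_id[i] <- next_id; next_id <- next_id + 1L
            par_id[i] <- mother
          }
        }
      }
    }
    row <- data.frame(frame = f, object_id = obj_id, parent_id = par_id,
                      x = pr$x, y = pr$y, area = pr$area)
    if (!is.null(intensities)) {
      for (ch in names(intensities)) {
        img <- intensities[[ch]][[f]]
        mns <- tapply(img[L > 0], L[L > 0], mean)
        row[[ch]] <- as.numeric(mns[as.character(pr$id)])
      }
    }
    rows[[f]] <- row
    prev_map <- stats::setNames(as.list(obj_id), as.character(pr$id))
    prev_lab <- L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
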