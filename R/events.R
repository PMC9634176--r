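#' Join the rattling episodes of a session into one series
#'
#' Extracts the magnitude samples of every rattling episode (half-open
#' `[onset, offset)` on the sensor clock) surviving the condition filter and
#' concatenates them in temporal order, recording each segment's source
#' interval and position. This joined series is what the coherence stage
#' analyses, and its boundaries keep the movement counter from merging
#' events across the artificial joins.
#'
#' @param m a [magnitude_series()] on the sensor clock.
#' @param track an aligned [annotation_track()].
#' @param condition `"ALL"` or one of the condition labels; filters the
#'   rattling episodes by their label.
#' @return A `joined_series`: list with `acc` (concatenated samples), `fs`,
#'   and `boundaries` (data frame: `onset_s`, `offset_s`, `condition`,
#'   `start_idx`, `end_idx` positions in the joined series). When no episode
#'   survives the filter, an empty sentinel (`n_episodes = 0`) is returned
#'   so callers can skip the visit.
#' @export
segment_episodes <- function(m, track, condition = "ALL") {
  stopifnot(inherits(m, "magnitude_series"), inherits(track, "annotation_track"))
  condition <- match.arg(condition, c("ALL", CONDITIONS))
  sub <- track[track$tier == "RATTLING", , drop = FALSE]
  if (condition != "ALL")
    sub <- sub[!is.na(sub$label) & sub$label == condition, , drop = FALSE]
  segs <- list()
  bounds <- list()
  pos <- 0L
  for (i in seq_len(nrow(sub))) {
    idx <- which(m$t >= sub$onset_s[i] & m$t < sub$offset_s[i])
    if (!length(idx)) next
    segs[[length(segs) + 1L]] <- m$acc[idx]
    bounds[[length(bounds) + 1L]] <- data.frame(
      onset_s = sub$onset_s[i], offset_s = sub$offset_s[i],
      condition = ifelse(is.na(sub$label[i]), "ALL", sub$label[i]),
      start_idx = pos + 1L, end_idx = pos + length(idx),
      stringsAsFactors = FALSE)
    pos <- pos + length(idx)
  }
  boundaries <- if (length(bounds)) do.call(rbind, bounds) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               condition = character(0), start_idx = integer(0),
               end_idx = integer(0))
  structure(list(acc = unlist(segs, use.names = FALSE) %||% numeric(0),
                 fs = m$fs, boundaries = boundaries,
                 n_episodes = nrow(boundaries)),
            class = "joined_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.joined_series <- function(x, ...) {
  cat(sprintf("<joined_series> %d episodes, %d samples @ %g Hz\n",
              x$n_episodes, length(x$acc), x$fs))
  invisible(x)
}

#' Count discrete rattling movements in joined episodes
#'
#' Runs the mean + 1 SD movement detector inside each episode segment
#' (threshold from that episode's own samples, robust to baseline drift
#' across the session; set `threshold_scope = "joined"` for a single
#' whole-series threshold) and applies the 50 ms merge rule within episodes
#' only — never across the artificial joins. With both arms supplied, the
#' supra-threshold intervals of the two arms are combined by union on the
#' time axis before run extraction, so a bimanual shake counts once; set
#' `per_arm = TRUE` to count each arm separately instead.
#'
#' Zero-variance episodes (no detectable movement at all) contribute zero
#' events and are reported in the result.
#'
#' @param joined a `joined_series` from [segment_episodes()] (left arm, or
#'   the only arm).
#' @param joined_right optional `joined_series` of the right arm, segmented
#'   with the same track and filter.
#' @param merge_gap_s merge gap for the 50 ms rule.
#' @param threshold_scope `"episode"` (default) or `"joined"`.
#' @param per_arm count each arm's events separately and sum, instead of
#'   the union.
#' @return List with `n_movements`, `per_episode_counts`, and
#'   `zero_variance_episodes` (indices).
#' @export
count_movements <- function(joined, joined_right = NULL,
                            merge_gap_s = 0.050,
                            threshold_scope = c("episode", "joined"),
                            per_arm = FALSE) {
  stopifnot(inherits(joined, "joined_series"))
  threshold_scope <- match.arg(threshold_scope)
  if (!is.null(joined_right)) {
    stopifnot(inherits(joined_right, "joined_series"),
              length(joined_right$acc) == length(joined$acc))
  }
  nb <- joined$n_episodes
  if (nb == 0 || !length(joined$acc))
    return(list(n_movements = 0L, per_episode_counts = integer(0),
                zero_variance_episodes = integer(0)))
  fs <- joined$fs
  arm_binary <- function(vals, scope_stats) {
    mu <- scope_stats[1]; sdev <- scope_stats[2]
    if (sdev == 0) return(NULL)
    as.numeric(vals > mu + sdev)
  }
  scope <- function(acc, seg_vals) {
    if (threshold_scope == "joined")
      c(mean(acc), sqrt(mean((acc - mean(acc))^2)))
    else
      c(mean(seg_vals), sqrt(mean((seg_vals - mean(seg_vals))^2)))
  }
  counts <- integer(nb)
  zero_var <- integer(0)
  for (i in seq_len(nb)) {
    rng <- joined$boundaries$start_idx[i]:joined$boundaries$end_idx[i]
    segs <- list(joined$acc[rng])
    if (!is.null(joined_right)) segs <- c(segs, list(joined_right$acc[rng]))
    accs <- list(joined$acc, if (!is.null(joined_right)) joined_right$acc)
    bins <- vector("list", length(segs))
    any_zero <- FALSE
    for (a in seq_along(segs)) {
      st <- scope(accs[[a]], segs[[a]])
      bb <- arm_binary(segs[[a]], st)
      if (is.null(bb)) { any_zero <- TRUE; bb <- numeric(length(segs[[a]])) }
      bins[[a]] <- bb
    }
    if (any_zero && all(vapply(bins, function(b) all(b == 0), TRUE)))
      zero_var <- c(zero_var, i)
    count_one <- function(b) {
      runs <- binary_runs(b)
      if (!nrow(runs)) return(0L)
      nrow(merge_runs(runs, fs, merge_gap_s))
    }
    if (per_arm) {
      counts[i] <- sum(vapply(bins, count_one, 0L))
    } else {
      u <- Reduce(pmax, bins)
      counts[i] <- count_one(u)
    }
  }
  if (length(zero_var))
    message(sprintf("%d zero-variance episode(s) contributed 0 events: %s",
                    length(zero_var), paste(zero_var, collapse = ", ")))
  list(n_movements = sum(counts), per_episode_counts = counts,
       zero_variance_episodes = zero_var)
}

#' Per-visit rattling metrics
#'
#' Episode count, mean episode duration, movement count and rattling
#' frequency (movements per second of total annotated rattling time, from
#' the video-derived durations), with the outlier rule applied: a visit with
#' rattling frequency above 2.5 Hz is flagged `excluded`.
#'
#' The optional re-coding filters mirror the study's control analyses:
#' `min_movements_per_episode` drops episodes with fewer detected movements
#' before summarising, and `min_episodes_per_visit` flags visits with too
#' few surviving episodes (`below_min_episodes`).
#'
#' @param joined a `joined_series` from [segment_episodes()].
#' @param counts result of [count_movements()] on that series.
#' @param visit_id identifier for the visit.
#' @param condition condition filter the series was segmented with.
#' @param freq_exclude_hz exclusion threshold in Hz.
#' @param min_movements_per_episode keep only episodes with at least this
#'   many detected movements.
#' @param min_episodes_per_visit minimum surviving episodes for the visit
#'   to count as analysable.
#' @return A one-row data frame (class `visit_metrics`): `visit_id`,
#'   `condition`, `n_episodes`, `mean_episode_dur_s`, `n_movements`,
#'   `rattling_freq_hz`, `excluded`, `below_min_episodes`.
#' @export
visit_metrics <- function(joined, counts, visit_id = "visit",
                          condition = "ALL", freq_exclude_hz = 2.5,
                          min_movements_per_episode = 1,
                          min_episodes_per_visit = 0) {
  stopifnot(inherits(joined, "joined_series"))
  keep <- counts$per_episode_counts >= min_movements_per_episode
  b <- joined$boundaries[keep, , drop = FALSE]
  cnt <- counts$per_episode_counts[keep]
  if (!nrow(b)) stop("no episodes survive the filters; skip this visit")
  durs <- b$offset_s - b$onset_s
  total <- sum(durs)
  if (total <= 0) stop("total rattling duration is zero")
  n_mov <- sum(cnt)
  freq <- n_mov / total
  out <- data.frame(visit_id = visit_id, condition = condition,
                    n_episodes = nrow(b), mean_episode_dur_s = mean(durs),
                    n_movements = n_mov, rattling_freq_hz = freq,
                    excluded = freq > freq_exclude_hz,
                    below_min_episodes = nrow(b) < min_episodes_per_visit,
                    stringsAsFactors = FALSE)
  class(out) <- c("visit_metrics", "data.frame")
  out
}
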