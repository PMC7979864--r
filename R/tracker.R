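# Greedy trajectory construction. Detections in consecutive frames extend
# existing trajectories when they fall below a class-dependent distance
# cutoff (and, in embedding modes, an appearance-similarity cutoff); all
# admissible pairs are matched greedily in increasing order of a combined
# cost, unmatched detections seed new trajectories, and trajectories whose
# detection gap exceeds a class/location-dependent cutoff are closed.

#' Tracker parameters
#'
#' @param a Half of a bee's longest dimension in px (distance-cutoff scale).
#' @param A Length-factor scale.
#' @param B Euclidean-distance scale in the combined cost.
#' @param c_v Appearance-similarity cutoff on the squared embedding
#'   distance.
#' @param angle_scale Weight of the orientation term in the angle variants.
#' @param gap_cell,gap_entrance,gap_default Gap cutoffs in seconds for
#'   trajectories whose recent history is mostly cell-bee, whose last
#'   detection is near the hive entrance, and all others.
#' @param min_traj Minimum stored trajectory timespan in seconds; shorter
#'   closed trajectories are discarded.
#' @param lookback Number of most recent trajectory detections whose
#'   embeddings enter the visual-similarity minimum (also the class-vote
#'   window).
#' @param entrance Entrance region: `list(shape = "disk", x, y, r)` or
#'   `list(shape = "rect", x0, x1, y0, y1)` in frame coordinates, or `NULL`.
#' @param fps Frame rate; the time difference in the distance cutoff is
#'   measured in frames.
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(a = 40, A = 30, B = 0.033, c_v = 1.75,
                           angle_scale = 0.25,
                           gap_cell = 10, gap_entrance = 1, gap_default = 3,
                           min_traj = 60, lookback = 10,
                           entrance = NULL, fps = 10) {
  stopifnot(a > 0, A > 0, B > 0, c_v > 0, angle_scale >= 0,
            gap_cell > 0, gap_entrance > 0, gap_default > 0,
            min_traj > 0, lookback >= 1, fps > 0)
  structure(list(a = a, A = A, B = B, c_v = c_v, angle_scale = angle_scale,
                 gap_cell = gap_cell, gap_entrance = gap_entrance,
                 gap_default = gap_default, min_traj = min_traj,
                 lookback = as.integer(lookback), entrance = entrance,
                 fps = fps),
            class = "tracker_params")
}

track_modes <- c("position", "position+angle", "embedding",
                 "embedding+angle", "rotated+angle")

mode_uses_embedding <- function(mode) grepl("embedding|rotated", mode)
mode_uses_angle <- function(mode) grepl("angle", mode)

in_entrance <- function(x, y, region) {
  if (is.null(region)) return(rep(FALSE, length(x)))
  if (identical(region$shape, "disk")) {
    (x - region$x)^2 + (y - region$y)^2 <= region$r^2
  } else if (identical(region$shape, "rect")) {
    x >= region$x0 & x <= region$x1 & y >= region$y0 & y <= region$y1
  } else stop("unknown entrance region shape")
}

new_traj <- function(id, det, row) {
  list(id = id, frames = det$frame, ts = det$t, xs = det$x, ys = det$y,
       bs = det$b, alphas = det$alpha, rows = row)
}

append_traj <- function(tr, det, row) {
  tr$frames <- c(tr$frames, det$frame)
  tr$ts <- c(tr$ts, det$t)
  tr$xs <- c(tr$xs, det$x)
  tr$ys <- c(tr$ys, det$y)
  tr$bs <- c(tr$bs, det$b)
  tr$alphas <- c(tr$alphas, det$alpha)
  tr$rows <- c(tr$rows, row)
  tr
}

# class of the recent history: TRUE when strictly more than half of the
# last min(lookback, length) positions are the given class
recent_majority <- function(tr, cls, lookback = 10L) {
  n <- length(tr$bs)
  recent <- tr$bs[max(1L, n - lookback + 1L):n]
  sum(recent == cls) > length(recent) / 2
}

#' Distance cutoff for extending a trajectory
#'
#' `a * sqrt(dt)` (dt in frames) when more than half of the trajectory's
#' recent positions are full-bees, `a / 3` otherwise (cell-bees barely
#' move).
#'
#' @param trajectory A trajectory as produced by the tracker (a list with at
#'   least `ts` and `bs`), or a detections `data.frame` with columns `t`
#'   and `b`.
#' @param t_i Candidate detection time in seconds (must exceed the
#'   trajectory's last time).
#' @param params A [tracker_params()].
#' @return Cutoff in px.
#' @export
distance_cutoff <- function(trajectory, t_i, params = tracker_params()) {
  if (is.data.frame(trajectory))
    trajectory <- list(ts = trajectory$t, bs = trajectory$b)
  t_j <- trajectory$ts[length(trajectory$ts)]
  if (t_i <= t_j) stop("t_i must be later than the trajectory's last time")
  if (recent_majority(trajectory, 1L, params$lookback)) {
    dt_frames <- (t_i - t_j) * params$fps
    params$a * sqrt(dt_frames)
  } else {
    params$a / 3
  }
}

#' Trajectory length factor
#'
#' `l = A * (1 - len / max_len)`, prioritising the extension of long
#' trajectories over short (possibly spurious) ones. Defined as 0 when no
#' trajectories exist yet.
#'
#' @param traj_len Length (detection count) of the candidate trajectory.
#' @param max_len Maximum length over all current trajectories.
#' @param A Scale factor.
#' @return Value in `[0, A]`.
#' @export
length_factor <- function(traj_len, max_len, A = 30) {
  if (max_len <= 0) return(0)
  A * (1 - traj_len / max_len)
}

#' Visual similarity between a trajectory and a detection
#'
#' Minimum squared Euclidean distance between the detection's embedding and
#' the embeddings of the trajectory's most recent detections (a window of
#' `lookback` positions).
#'
#' @param traj_embeddings Matrix of the trajectory's embeddings in time
#'   order (rows).
#' @param det_embedding Embedding vector of the detection.
#' @param lookback Window length.
#' @return Non-negative scalar.
#' @export
visual_similarity <- function(traj_embeddings, det_embedding,
                              lookback = 10L) {
  if (is.null(traj_embeddings) || nrow(traj_embeddings) == 0)
    stop("trajectory has no embeddings")
  n <- nrow(traj_embeddings)
  win <- traj_embeddings[max(1L, n - lookback + 1L):n, , drop = FALSE]
  min(rowSums(sweep(win, 2, det_embedding)^2))
}

#' Combined matching cost
#'
#' Position mode: `D = E + l`. Embedding modes: `D = B*E + V + l`. Angle
#' variants add `angle_scale * d_a` where `d_a = sin((a1 - a2)/2)^2`.
#'
#' @param E Euclidean distance in px.
#' @param V Squared embedding distance (required in embedding modes).
#' @param l Length factor.
#' @param mode One of `r paste(track_modes, collapse = ", ")`.
#' @param d_a Orientation dissimilarity term (0 when either detection lacks
#'   an angle).
#' @param params A [tracker_params()].
#' @return Scalar cost.
#' @export
pair_cost <- function(E, V = NULL, l = 0, mode = "position", d_a = 0,
                      params = tracker_params()) {
  mode <- match.arg(mode, track_modes)
  if (mode_uses_embedding(mode)) {
    if (is.null(V) || anyNA(V)) stop("embedding mode requires V")
    D <- params$B * E + V + l
  } else {
    D <- E + l
  }
  if (mode_uses_angle(mode)) D <- D + params$angle_scale * d_a
  D
}

angle_dissimilarity <- function(a1, a2) {
  d <- ifelse(is.na(a1) | is.na(a2), 0, sin((a1 - a2) * pi / 360)^2)
  d
}

#' Match one frame of detections to open trajectories
#'
#' Candidate pairs are limited by the distance cutoff (and the appearance
#' cutoff `c_v` in embedding modes), sorted by increasing combined cost and
#' assigned greedily one-to-one; ties are broken by trajectory id then
#' detection index. Unmatched detections seed new trajectories (after all
#' matches of the frame are committed).
#'
#' @param trajectories List of open trajectory objects.
#' @param detections Detections `data.frame`, all at one time.
#' @param params A [tracker_params()].
#' @param mode Matching mode.
#' @param embeddings Embedding matrix indexed by detection row (required in
#'   embedding modes).
#' @param det_rows Row indices of `detections` in the full detection table
#'   (used to look up embeddings); defaults to `seq_len(nrow(detections))`.
#' @return List with `pairs` (`data.frame` of `traj`, `det` indices) and
#'   `unmatched` (detection indices that seed new trajectories).
#' @export
match_frame <- function(trajectories, detections, params = tracker_params(),
                        mode = "position", embeddings = NULL,
                        det_rows = NULL) {
  mode <- match.arg(mode, track_modes)
  nd <- nrow(detections)
  nt <- length(trajectories)
  if (is.null(det_rows)) det_rows <- seq_len(nd)
  if (nd && length(unique(detections$t)) != 1L)
    stop("detections passed to match_frame must share one time")
  if (!nt || !nd)
    return(list(pairs = data.frame(traj = integer(0), det = integer(0)),
                unmatched = seq_len(nd)))
  use_emb <- mode_uses_embedding(mode)
  if (use_emb && is.null(embeddings))
    stop("embedding mode requires an embedding matrix")
  t_i <- detections$t[1]
  lens <- vapply(trajectories, function(tr) length(tr$ts), numeric(1))
  max_len <- max(lens)
  cand <- list()
  for (j in seq_len(nt)) {
    tr <- trajectories[[j]]
    if (t_i <= tr$ts[length(tr$ts)]) next
    cd <- distance_cutoff(tr, t_i, params)
    E <- sqrt((detections$x - tr$xs[length(tr$xs)])^2 +
              (detections$y - tr$ys[length(tr$ys)])^2)
    ok <- which(E <= cd)
    if (!length(ok)) next
    l <- length_factor(lens[j], max_len, params$A)
    if (use_emb) {
      n <- length(tr$rows)
      win <- tr$rows[max(1L, n - params$lookback + 1L):n]
      M <- embeddings[win, , drop = FALSE]
      Ed <- embeddings[det_rows[ok], , drop = FALSE]
      d2 <- outer(rowSums(M^2), rep(1, length(ok))) +
        outer(rep(1, nrow(M)), rowSums(Ed^2)) - 2 * tcrossprod(M, Ed)
      V <- apply(d2, 2, min)
      keep <- V < params$c_v
      ok <- ok[keep]; V <- V[keep]
      if (!length(ok)) next
      D <- params$B * E[ok] + V + l
    } else {
      D <- E[ok] + l
    }
    if (mode_uses_angle(mode)) {
      la <- tr$alphas[length(tr$alphas)]
      D <- D + params$angle_scale * angle_dissimilarity(la, detections$alpha[ok])
    }
    cand[[length(cand) + 1L]] <-
      data.frame(traj = j, det = ok, D = D,
                 tid = trajectories[[j]]$id)
  }
  if (!length(cand))
    return(list(pairs = data.frame(traj = integer(0), det = integer(0)),
                unmatched = seq_len(nd)))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$D, cand$tid, cand$det), , drop = FALSE]
  used_t <- logical(nt); used_d <- logical(nd)
  pt <- integer(0); pd <- integer(0)
  for (i in seq_len(nrow(cand))) {
    j <- cand$traj[i]; d <- cand$det[i]
    if (used_t[j] || used_d[d]) next
    used_t[j] <- TRUE; used_d[d] <- TRUE
    pt <- c(pt, j); pd <- c(pd, d)
  }
  list(pairs = data.frame(traj = pt, det = pd),
       unmatched = which(!used_d))
}

gap_cutoff <- function(tr, params) {
  if (recent_majority(tr, 2L, params$lookback)) return(params$gap_cell)
  n <- length(tr$xs)
  if (any(in_entrance(tr$xs[n], tr$ys[n], params$entrance)))
    return(params$gap_entrance)
  params$gap_default
}

#' Close stale trajectories
#'
#' A trajectory whose time since its last detection exceeds its gap cutoff
#' (10 s when its recent history is mostly cell-bee, 1 s when its last
#' detection lies in the entrance region, 3 s otherwise) is closed: kept as
#' finished when its timespan reaches `min_traj`, discarded otherwise.
#'
#' @param trajectories List of open trajectory objects.
#' @param t_now Current time in seconds.
#' @param params A [tracker_params()].
#' @return List with `open`, `finished`, `discarded` trajectory lists.
#' @export
close_stale <- function(trajectories, t_now, params = tracker_params()) {
  open <- list(); finished <- list(); discarded <- list()
  for (tr in trajectories) {
    gap <- t_now - tr$ts[length(tr$ts)]
    if (gap > gap_cutoff(tr, params)) {
      span <- tr$ts[length(tr$ts)] - tr$ts[1]
      if (span >= params$min_traj) finished[[length(finished) + 1L]] <- tr
      else discarded[[length(discarded) + 1L]] <- tr
    } else {
      open[[length(open) + 1L]] <- tr
    }
  }
  list(open = open, finished = finished, discarded = discarded)
}

finalize_tracks <- function(finished, discarded, open, params,
                            keep_all = FALSE) {
  for (tr in open) {
    span <- tr$ts[length(tr$ts)] - tr$ts[1]
    if (keep_all || span >= params$min_traj)
      finished[[length(finished) + 1L]] <- tr
    else discarded[[length(discarded) + 1L]] <- tr
  }
  list(finished = finished, discarded = discarded)
}

tracks_to_df <- function(trs) {
  if (!length(trs))
    return(data.frame(traj_id = integer(0), frame = integer(0),
                      t = numeric(0), x = numeric(0), y = numeric(0),
                      b = integer(0), alpha = numeric(0),
                      det_row = integer(0)))
  do.call(rbind, lapply(trs, function(tr) {
    data.frame(traj_id = tr$id, frame = tr$frames, t = tr$ts, x = tr$xs,
               y = tr$ys, b = tr$bs, alpha = tr$alphas, det_row = tr$rows)
  }))
}

track_core <- function(detections, params, mode, embeddings,
                       keep_all = FALSE, id_offset = 0L) {
  n <- nrow(detections)
  if (n && is.unsorted(detections$frame))
    stop("detections must be sorted by frame")
  open <- list(); finished <- list(); discarded <- list()
  next_id <- id_offset + 1L
  for (fr in unique(detections$frame)) {
    rows <- which(detections$frame == fr)
    dets <- detections[rows, , drop = FALSE]
    t_now <- dets$t[1]
    cl <- close_stale(open, t_now, params)
    open <- cl$open
    finished <- c(finished, cl$finished)
    discarded <- c(discarded, cl$discarded)
    m <- match_frame(open, dets, params, mode, embeddings, det_rows = rows)
    if (nrow(m$pairs)) for (i in seq_len(nrow(m$pairs))) {
      j <- m$pairs$traj[i]; d <- m$pairs$det[i]
      open[[j]] <- append_traj(open[[j]], dets[d, ], rows[d])
    }
    for (d in m$unmatched) {
      open[[length(open) + 1L]] <- new_traj(next_id, dets[d, ], rows[d])
      next_id <- next_id + 1L
    }
  }
  fin <- finalize_tracks(finished, discarded, open, params, keep_all)
  list(finished = fin$finished, discarded = fin$discarded,
       next_id = next_id)
}

#' Assemble detections into trajectories
#'
#' Runs the full matching pipeline: per-frame greedy matching, gap-based
#' closure, and a final flush. Deterministic for a given input.
#'
#' @param detections Detections `data.frame` sorted by frame with columns
#'   `frame, t, x, y, b, alpha` (extra columns are carried through via
#'   `det_row`).
#' @param params A [tracker_params()].
#' @param mode Matching mode, see [pair_cost()].
#' @param embeddings Embedding matrix with one row per detection row
#'   (required in embedding modes).
#' @return Object of class `bee_tracks`: list with `trajectories` (a
#'   `data.frame` with `traj_id, frame, t, x, y, b, alpha, det_row`),
#'   `n_discarded`, `mode`, `params`.
#' @export
track <- function(detections, params = tracker_params(), mode = "position",
                  embeddings = NULL) {
  mode <- match.arg(mode, track_modes)
  res <- track_core(detections, params, mode, embeddings)
  structure(list(trajectories = tracks_to_df(res$finished),
                 n_discarded = length(res$discarded),
                 mode = mode, params = params),
            class = "bee_tracks")
}

#' Segment-parallel tracking
#'
#' Splits the detection stream into fixed-length segments, tracks each
#' segment independently, then stitches trajectories across segment
#' boundaries using the same distance, appearance and cost criteria as
#' within-segment matching. The minimum-length filter is applied only after
#' stitching.
#'
#' @inheritParams track
#' @param segment Segment length in seconds.
#' @return A `bee_tracks` object.
#' @export
track_parallel <- function(detections, params = tracker_params(),
                           mode = "position", embeddings = NULL,
                           segment = 60) {
  mode <- match.arg(mode, track_modes)
  if (!nrow(detections)) return(track(detections, params, mode, embeddings))
  t0 <- detections$t[1]
  seg_id <- floor((detections$t - t0) / segment)
  segs <- sort(unique(seg_id))
  all_trs <- list()
  next_id <- 0L
  for (s in segs) {
    rows <- which(seg_id == s)
    sub <- detections[rows, , drop = FALSE]
    # preserve absolute row indices for embedding lookup
    res <- track_core_abs(sub, rows, params, mode, embeddings, next_id)
    next_id <- res$next_id
    seg_trs <- c(res$finished, res$discarded)
    if (!length(all_trs)) {
      all_trs <- seg_trs
    } else {
      all_trs <- stitch_segments(all_trs, seg_trs, params, mode, embeddings)
    }
  }
  finished <- list(); discarded <- list()
  for (tr in all_trs) {
    span <- tr$ts[length(tr$ts)] - tr$ts[1]
    if (span >= params$min_traj) finished[[length(finished) + 1L]] <- tr
    else discarded[[length(discarded) + 1L]] <- tr
  }
  structure(list(trajectories = tracks_to_df(finished),
                 n_discarded = length(discarded),
                 mode = mode, params = params),
            class = "bee_tracks")
}

# track_core on a detection subset whose rows map to absolute row indices
track_core_abs <- function(sub, rows, params, mode, embeddings, id_offset) {
  sub2 <- sub
  res <- track_core(sub2, params, mode,
                    embeddings = embeddings_remap(embeddings, rows),
                    keep_all = TRUE, id_offset = id_offset)
  # remap det_row back to absolute indices
  res$finished <- lapply(res$finished, function(tr) {
    tr$rows <- rows[tr$rows]; tr
  })
  res$discarded <- lapply(res$discarded, function(tr) {
    tr$rows <- rows[tr$rows]; tr
  })
  res
}

embeddings_remap <- function(embeddings, rows) {
  if (is.null(embeddings)) return(NULL)
  # track_core indexes embeddings by subset row; hand it the subset matrix
  embeddings[rows, , drop = FALSE]
}

# Greedy stitching of trajectories that end before a segment boundary to
# trajectories that start after it, using the same admissibility criteria
# and full pair cost.
stitch_segments <- function(prev, nxt, params, mode, embeddings) {
  if (!length(nxt)) return(prev)
  if (!length(prev)) return(nxt)
  starts <- vapply(nxt, function(tr) tr$ts[1], numeric(1))
  use_emb <- mode_uses_embedding(mode)
  lens <- vapply(prev, function(tr) length(tr$ts), numeric(1))
  max_len <- max(lens)
  cand <- list()
  for (j in seq_along(prev)) {
    tr <- prev[[j]]
    t_end <- tr$ts[length(tr$ts)]
    gap_ok <- which(starts > t_end &
                    (starts - t_end) <= gap_cutoff(tr, params))
    if (!length(gap_ok)) next
    l <- length_factor(lens[j], max_len, params$A)
    for (d in gap_ok) {
      hd <- nxt[[d]]
      E <- sqrt((hd$xs[1] - tr$xs[length(tr$xs)])^2 +
                (hd$ys[1] - tr$ys[length(tr$ys)])^2)
      cd <- distance_cutoff(tr, hd$ts[1], params)
      if (E > cd) next
      if (use_emb) {
        n <- length(tr$rows)
        win <- tr$rows[max(1L, n - params$lookback + 1L):n]
        V <- visual_similarity(embeddings[win, , drop = FALSE],
                               embeddings[hd$rows[1], ], params$lookback)
        if (V >= params$c_v) next
        D <- params$B * E + V + l
      } else D <- E + l
      if (mode_uses_angle(mode))
        D <- D + params$angle_scale *
          angle_dissimilarity(tr$alphas[length(tr$alphas)], hd$alphas[1])
      cand[[length(cand) + 1L]] <- data.frame(p = j, s = d, D = D,
                                              tid = tr$id)
    }
  }
  merged_into <- rep(NA_integer_, length(nxt))
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$D, cand$tid, cand$s), , drop = FALSE]
    used_p <- logical(length(prev)); used_s <- logical(length(nxt))
    for (i in seq_len(nrow(cand))) {
      p <- cand$p[i]; s <- cand$s[i]
      if (used_p[p] || used_s[s]) next
      used_p[p] <- TRUE; used_s[s] <- TRUE
      merged_into[s] <- p
    }
  }
  out <- prev
  for (s in seq_along(nxt)) {
    p <- merged_into[s]
    if (is.na(p)) {
      out[[length(out) + 1L]] <- nxt[[s]]
    } else {
      tr <- out[[p]]
      hd <- nxt[[s]]
      tr$frames <- c(tr$frames, hd$frames)
      tr$ts <- c(tr$ts, hd$ts)
      tr$xs <- c(tr$xs, hd$xs)
      tr$ys <- c(tr$ys, hd$ys)
      tr$bs <- c(tr$bs, hd$bs)
      tr$alphas <- c(tr$alphas, hd$alphas)
      tr$rows <- c(tr$rows, hd$rows)
      out[[p]] <- tr
    }
  }
  out
}

#' Score trajectories against ground-truth identities
#'
#' A trajectory is correct when (i) at least 80% of its detections carry a
#' single ground-truth identity and (ii) it covers at least 80% of that
#' identity's presence in the recording; at most one trajectory per
#' identity is counted. The proportion of correctly tracked bees is the
#' number of correct trajectories relative to the mean number of detections
#' per frame.
#'
#' @param tracks A `bee_tracks` object (or its `trajectories` data frame).
#' @param detections The detection table the tracker ran on, with a
#'   ground-truth `id` column.
#' @param purity Majority-identity fraction required (default 0.8).
#' @param coverage Fraction of the identity's presence timespan the
#'   trajectory must span (default 0.8).
#' @return List with `proportion_correct`, `n_correct`,
#'   `mean_detections_per_frame` and the per-trajectory table.
#' @export
score_against_truth <- function(tracks, detections, purity = 0.8,
                                coverage = 0.8) {
  df <- if (inherits(tracks, "bee_tracks")) tracks$trajectories else tracks
  if (is.null(detections$id)) stop("detections need a ground-truth id column")
  n_frames <- length(unique(detections$frame))
  mean_det <- nrow(detections) / n_frames
  pres <- do.call(rbind, lapply(split(detections$t, detections$id),
                                function(ts) data.frame(t0 = min(ts),
                                                        t1 = max(ts))))
  pres$id <- as.integer(rownames(pres))
  per_traj <- lapply(split(df, df$traj_id), function(tr) {
    ids <- detections$id[tr$det_row]
    tab <- table(ids)
    maj <- as.integer(names(which.max(tab)))
    frac <- max(tab) / length(ids)
    pr <- pres[pres$id == maj, ]
    span <- diff(range(tr$t))
    pspan <- pr$t1 - pr$t0
    cov <- if (pspan <= 0) 1 else
      max(0, min(max(tr$t), pr$t1) - max(min(tr$t), pr$t0)) / pspan
    data.frame(traj_id = tr$traj_id[1], majority_id = maj,
               purity = frac, coverage = cov,
               correct = frac >= purity & cov >= coverage)
  })
  per_traj <- do.call(rbind, per_traj)
  correct_ids <- unique(per_traj$majority_id[per_traj$correct])
  n_correct <- length(correct_ids)
  list(proportion_correct = n_correct / mean_det,
       n_correct = n_correct,
       mean_detections_per_frame = mean_det,
       per_trajectory = per_traj)
}
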