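# Motility, velocity and survival analytics for tracked sperm cells.
#
# Trajectories are data frames with columns time_s, x_um, y_um (times
# strictly increasing). The tracker is a deterministic greedy
# closest-pair-first mutual-nearest-neighbour linker: simple, fully
# reproducible, and accurate on well-separated tracks. Velocity is the
# curvilinear mean speed (total path length over elapsed time), the single
# velocity notion used throughout. Survival is binary: post-thaw motility
# strictly greater than zero.

new_trajectory <- function(time_s, x_um, y_um, track_id = NA) {
  data.frame(track_id = track_id, time_s = time_s, x_um = x_um, y_um = y_um)
}

assert_trajectory <- function(traj) {
  if (!is.data.frame(traj) ||
      !all(c("time_s", "x_um", "y_um") %in% names(traj)))
    stop("a trajectory needs columns `time_s`, `x_um`, `y_um`", call. = FALSE)
  if (nrow(traj) >= 2 && any(diff(traj$time_s) <= 0))
    stop("trajectory times must be strictly increasing", call. = FALSE)
  traj
}

#' Link per-frame detections into trajectories
#'
#' Deterministic greedy frame-to-frame linker: for each consecutive frame
#' pair, candidate links within `max_disp` are taken closest-pair-first
#' (each track head and each detection used at most once), unmatched
#' detections start new tracks, and unmatched tracks are closed. Ties are
#' broken by track then detection index, so the result is independent of
#' floating-point quirks in input ordering.
#'
#' @param frames List (length >= 2) of per-frame detections: each element a
#'   data frame or matrix with columns `x_um`/`y_um` (or two unnamed
#'   columns). Empty frames are allowed.
#' @param dt Frame interval, s (> 0).
#' @param max_disp Gate: maximum displacement linked between consecutive
#'   frames, um (> 0).
#' @return A list of trajectory data frames (`track_id`, `time_s`, `x_um`,
#'   `y_um`), in order of track creation.
#' @examples
#' frames <- lapply(0:4, function(i) data.frame(x_um = 3 * i, y_um = 0))
#' length(link_detections(frames, dt = 1, max_disp = 10))  # 1
#' @export
link_detections <- function(frames, dt, max_disp) {
  if (!is.list(frames) || length(frames) < 2)
    stop("`frames` must be a list of at least 2 frames", call. = FALSE)
  assert_positive(dt, "dt"); assert_positive(max_disp, "max_disp")
  as_xy <- function(f) {
    if (is.null(f) || NROW(f) == 0) return(matrix(numeric(0), ncol = 2))
    f <- as.data.frame(f)
    if (all(c("x_um", "y_um") %in% names(f))) cbind(f$x_um, f$y_um)
    else as.matrix(f[, 1:2])
  }

  tracks <- list()      # each: list(rows = data.frame, open = TRUE)
  f1 <- as_xy(frames[[1]])
  active <- integer(0)  # indices into `tracks` of tracks alive last frame
  for (i in seq_len(nrow(f1))) {
    tracks[[length(tracks) + 1]] <-
      new_trajectory(0, f1[i, 1], f1[i, 2])
    active <- c(active, length(tracks))
  }

  for (k in 2:length(frames)) {
    det <- as_xy(frames[[k]])
    t_now <- (k - 1) * dt
    n_act <- length(active); n_det <- nrow(det)
    track_used <- rep(FALSE, n_act); det_used <- rep(FALSE, n_det)

    if (n_act > 0 && n_det > 0) {
      heads <- t(vapply(active, function(ti) {
        r <- tracks[[ti]]
        c(r$x_um[nrow(r)], r$y_um[nrow(r)])
      }, numeric(2)))
      d <- sqrt(outer(heads[, 1], det[, 1], "-")^2 +
                outer(heads[, 2], det[, 2], "-")^2)
      cand <- which(d <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], cand[, 1], cand[, 2])
        for (ci in ord) {
          ti <- cand[ci, 1]; di <- cand[ci, 2]
          if (track_used[ti] || det_used[di]) next
          track_used[ti] <- TRUE; det_used[di] <- TRUE
          idx <- active[ti]
          tracks[[idx]] <- rbind(tracks[[idx]],
                                 new_trajectory(t_now, det[di, 1], det[di, 2]))
        }
      }
    }
    new_active <- active[track_used]
    for (di in seq_len(n_det)) {
      if (!det_used[di]) {
        tracks[[length(tracks) + 1]] <-
          new_trajectory(t_now, det[di, 1], det[di, 2])
        new_active <- c(new_active, length(tracks))
      }
    }
    active <- new_active
  }

  for (i in seq_along(tracks)) tracks[[i]]$track_id <- i
  tracks
}

#' Curvilinear mean speed of a trajectory
#'
#' Total path length divided by elapsed time, um/s — the "average velocity"
#' endpoint at the single-cell level.
#'
#' @param traj Trajectory data frame (`time_s`, `x_um`, `y_um`), >= 2
#'   samples.
#' @return Speed in um/s (>= 0).
#' @examples
#' track_velocity(data.frame(time_s = 0:1, x_um = c(0, 66), y_um = 0))  # 66
#' @export
track_velocity <- function(traj) {
  assert_trajectory(traj)
  if (nrow(traj) < 2)
    stop("need at least 2 samples for a velocity estimate", call. = FALSE)
  path <- sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
  path / (traj$time_s[nrow(traj)] - traj$time_s[1])
}

#' Classify a track as motile
#'
#' Motile iff the curvilinear speed is at least `speed_threshold` (boundary
#' counts as motile). The default 5 um/s sits an order of magnitude below
#' the typical 66 um/s swimming speed and separates drift/noise from
#' swimming.
#'
#' @param traj Trajectory data frame.
#' @param speed_threshold Threshold in um/s.
#' @return Logical flag.
#' @export
classify_motile <- function(traj, speed_threshold = 5) {
  track_velocity(traj) >= speed_threshold
}

#' Drop erratically moving tracks
#'
#' Optional quality filter for involuntary movements deviating strongly from
#' the cell's axis: removes tracks whose step-direction circular variance
#' (1 minus the mean resultant length of the step headings) exceeds
#' `max_circ_var`. Off by default in the summaries.
#'
#' @param trajs List of trajectories.
#' @param max_circ_var Cap on circular variance, in `[0, 1]`.
#' @return The filtered list.
#' @export
filter_erratic_tracks <- function(trajs, max_circ_var = 0.8) {
  keep <- vapply(trajs, function(tr) {
    assert_trajectory(tr)
    dx <- diff(tr$x_um); dy <- diff(tr$y_um)
    ok <- dx != 0 | dy != 0
    if (sum(ok) < 2) return(TRUE)
    th <- atan2(dy[ok], dx[ok])
    rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    (1 - rbar) <= max_circ_var
  }, logical(1))
  trajs[keep]
}

#' Percent motility of a set of tracks
#'
#' Raw motility is `100 * n_motile / n_tracks`; when the sample's initial
#' motility is supplied the value is normalized to it (and capped at 100),
#' matching the convention of reporting motility relative to the
#' pre-treatment state.
#'
#' @param trajs Nonempty list of trajectories.
#' @param threshold Motile speed threshold, um/s.
#' @param initial_motility_pct Optional initial motility in `(0, 100]` used
#'   for normalization.
#' @return Percentage in `[0, 100]`.
#' @examples
#' # 4 motile of 10 -> 40%; normalized to initial 80% -> 50%
#' @export
motility_percent <- function(trajs, threshold = 5,
                             initial_motility_pct = NULL) {
  if (!is.list(trajs) || length(trajs) == 0)
    stop("`trajs` must be a nonempty list of trajectories", call. = FALSE)
  raw <- 100 * mean(vapply(trajs, classify_motile, logical(1),
                           speed_threshold = threshold))
  if (is.null(initial_motility_pct)) return(raw)
  if (initial_motility_pct <= 0 || initial_motility_pct > 100)
    stop("`initial_motility_pct` must lie in (0, 100]", call. = FALSE)
  min(100, 100 * raw / initial_motility_pct)
}

#' Summarize a set of tracks
#'
#' @param trajs Nonempty list of trajectories.
#' @param threshold Motile speed threshold, um/s.
#' @param initial_motility_pct Optional normalization, see
#'   [motility_percent()].
#' @return A list of class `motility_summary`: `n_tracks`, `n_motile`,
#'   `motility_pct`, `mean_velocity` and `velocity_sd` (um/s, over motile
#'   tracks).
#' @export
motility_summary <- function(trajs, threshold = 5,
                             initial_motility_pct = NULL) {
  if (!is.list(trajs) || length(trajs) == 0)
    stop("`trajs` must be a nonempty list of trajectories", call. = FALSE)
  v <- vapply(trajs, track_velocity, numeric(1))
  motile <- v >= threshold
  structure(list(
    n_tracks = length(trajs),
    n_motile = sum(motile),
    motility_pct = motility_percent(trajs, threshold, initial_motility_pct),
    mean_velocity = if (any(motile)) mean(v[motile]) else 0,
    velocity_sd = if (sum(motile) > 1) stats::sd(v[motile]) else 0
  ), class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("%d tracks, %d motile (%.1f%%), mean speed %.1f +/- %.1f um/s\n",
              x$n_tracks, x$n_motile, x$motility_pct,
              x$mean_velocity, x$velocity_sd))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by enumerating all tables with the observed
#' margins and summing the hypergeometric probabilities not exceeding that
#' of the observed table (with the customary 1e-7 relative slack for
#' floating-point ties). A table with a zero margin carries no information;
#' by convention p = 1 is returned with a warning.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return Two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2))  # ~0.00794
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of nonnegative integer counts",
         call. = FALSE)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    warning("degenerate 2x2 table (zero margin): p = 1 by convention")
    return(1)
  }
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Survival analysis of a volume panel
#'
#' Groups survival records at a volume threshold, tests the association
#' between droplet size and post-thaw survival (motility strictly > 0) with
#' Fisher's exact test, and reports the empirical survival threshold — the
#' smallest initial volume with any post-thaw motility.
#'
#' @param records Data frame with columns `V0_nL`, `motility_30min_pct`,
#'   `motility_postthaw_pct`, `velocity_um_s`.
#' @param volume_threshold Analysis threshold in nL (default 30).
#' @return A list of class `survival_table`: the 2x2 `counts` matrix
#'   (rows below/above threshold, columns survived/died), `p_value`,
#'   `threshold_nL` used, and `empirical_threshold_nL` (NA when nothing
#'   survived).
#' @export
survival_table <- function(records, volume_threshold = 30) {
  need <- c("V0_nL", "motility_30min_pct", "motility_postthaw_pct",
            "velocity_um_s")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0) stop("`records` is empty", call. = FALSE)
  below <- records$V0_nL < volume_threshold
  if (all(below) || !any(below))
    stop("all records fall on one side of `volume_threshold`; ",
         "cannot form the 2x2 table", call. = FALSE)
  surv <- records$motility_postthaw_pct > 0
  counts <- matrix(c(sum(below & surv), sum(below & !surv),
                     sum(!below & surv), sum(!below & !surv)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("below", "above"),
                                   c("survived", "died")))
  emp <- if (any(surv)) min(records$V0_nL[surv]) else NA_real_
  structure(list(counts = counts,
                 p_value = fisher_exact_2x2(counts),
                 threshold_nL = volume_threshold,
                 empirical_threshold_nL = emp),
            class = "survival_table")
}

#' @export
print.survival_table <- function(x, ...) {
  cat(sprintf("Survival at the %g-nL threshold (Fisher exact p = %.3g)\n",
              x$threshold_nL, x$p_value))
  print(x$counts)
  cat(sprintf("smallest surviving volume: %s nL\n",
              format(x$empirical_threshold_nL)))
  invisible(x)
}

#' Detect bright cells in a single intensity frame
#'
#' Minimal image front-end: thresholds the frame at a fraction of its
#' maximum, labels 4-connected foreground components, and returns
#' intensity-weighted centroids in um (origin at the top-left corner, pixel
#' centers at half-integer pixel coordinates). A blank frame yields zero
#' detections, not an error.
#'
#' @param image Numeric matrix of intensities (rows = y, columns = x).
#' @param intensity_threshold Fraction of the frame maximum, in `(0, 1)`.
#' @param pixel_um Pixel pitch, um/px.
#' @return Data frame with columns `x_um`, `y_um` (possibly zero rows).
#' @export
detect_cells_in_frame <- function(image, intensity_threshold = 0.5,
                                  pixel_um = 1) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    stop("`image` must be a nonempty numeric matrix", call. = FALSE)
  assert_positive(pixel_um, "pixel_um")
  mx <- max(image)
  if (mx <= 0) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  mask <- image >= intensity_threshold * mx
  if (!any(mask)) return(data.frame(x_um = numeric(0), y_um = numeric(0)))

  nr <- nrow(image); nc <- ncol(image)
  labels <- matrix(0L, nr, nc)
  nlab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    nlab <- nlab + 1L
    stack <- start
    labels[start] <- nlab
    while (length(stack) > 0) {
      px <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- ((px - 1L) %% nr) + 1L
      j <- ((px - 1L) %/% nr) + 1L
      nb <- c(if (i > 1L) px - 1L, if (i < nr) px + 1L,
              if (j > 1L) px - nr, if (j < nc) px + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- nlab
      stack <- c(stack, nb)
    }
  }

  idx <- which(labels > 0L)
  lab <- labels[idx]
  w <- image[idx]
  row_i <- ((idx - 1L) %% nr) + 1L
  col_j <- ((idx - 1L) %/% nr) + 1L
  wsum <- tapply(w, lab, sum)
  x_px <- tapply(w * (col_j - 0.5), lab, sum) / wsum
  y_px <- tapply(w * (row_i - 0.5), lab, sum) / wsum
  data.frame(x_um = as.numeric(x_px) * pixel_um,
             y_um = as.numeric(y_px) * pixel_um)
}
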