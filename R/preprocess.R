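## Raw-recording preprocessing: filtering, synchronization, gap filling,
## scapula reconstruction, hand-force assembly and cycle segmentation.

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward filtering with coefficients from [signal::butter()].
#' Endpoints are handled by odd-reflection padding (default three filter
#' orders long) with a DC-matched initial state, so a constant signal is
#' reproduced to machine precision.
#'
#' @param x Uniformly sampled signal.
#' @param cutoff_hz Cutoff frequency (Hz); default 6.
#' @param rate Sampling rate (Hz).
#' @param order Filter order (per pass); default 4.
#' @param pad Reflection padding length; default `3 * order`.
#' @return Filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, cutoff_hz = 6, rate = 100, order = 4,
                                pad = 3 * order) {
  if (rate <= 2 * cutoff_hz) stop("butterworth_lowpass: rate must exceed 2 x cutoff")
  n <- length(x)
  if (n <= pad + 1) stop("butterworth_lowpass: series too short for filter warm-up")
  bf <- signal::butter(order, 2 * cutoff_hz / rate, type = "low")
  one_pass <- function(y) {
    ## odd reflection about the first sample; DC-exact zero state via
    ## offset subtraction (Butterworth DC gain is 1)
    head_pad <- 2 * y[1] - y[seq(pad + 1, 2, by = -1)]
    tail_pad <- 2 * y[length(y)] - y[seq(length(y) - 1, length(y) - pad)]
    yp <- c(head_pad, y, tail_pad)
    z <- signal::filter(bf, yp - yp[1]) + yp[1]
    z[(pad + 1):(pad + length(y))]
  }
  rev(one_pass(rev(one_pass(x))))
}

#' Linear resampling of a uniformly or non-uniformly sampled signal
#'
#' @param x Signal values.
#' @param time_in Sample times of `x` (or a scalar input rate in Hz, with
#'   samples assumed at `(0:(n-1))/rate`).
#' @param target_hz Target rate (ignored when `time_out` given).
#' @param time_out Explicit output timestamps.
#' @return List with `time` and `values`. No extrapolation: output times
#'   beyond the input range take the endpoint values.
#' @export
resample_linear <- function(x, time_in, target_hz = 100, time_out = NULL) {
  if (length(x) < 2) stop("resample_linear: need at least 2 samples")
  if (length(time_in) == 1) time_in <- (seq_along(x) - 1) / time_in
  if (is.null(time_out)) {
    time_out <- seq(time_in[1], time_in[length(time_in)], by = 1 / target_hz)
  }
  v <- stats::approx(time_in, x, xout = time_out, rule = 2)$y
  list(time = time_out, values = v)
}

## index and time of the single rising edge of a binary pulse channel
pulse_edge <- function(time, pulse, stream = "stream") {
  hi <- pulse >= 0.5
  edges <- which(hi[-1] & !hi[-length(hi)]) + 1L
  if (length(edges) == 0) stop("synchronize: no rising pulse edge in ", stream)
  if (length(edges) > 1) stop("synchronize: multiple rising pulse edges in ", stream)
  list(index = edges, time = time[edges])
}

#' Synchronize marker and force streams on their pulse edges
#'
#' Shifts the force-stream clock so the rising pulse edges coincide, then
#' resamples the force channel onto the marker clock by linear
#' interpolation.
#'
#' @param markers Marker stream: list with `time`, `pulse`, `data`.
#' @param force Force stream: list with `time`, `pulse`, `lateral`.
#' @return List: `markers` (unchanged), `force` with `time` on the marker
#'   clock and `lateral` resampled to it, plus the applied `offset` (s).
#' @export
synchronize <- function(markers, force) {
  em <- pulse_edge(markers$time, markers$pulse, "marker stream")
  ef <- pulse_edge(force$time, force$pulse, "force stream")
  offset <- em$time - ef$time
  t_aligned <- force$time + offset
  lat <- resample_linear(force$lateral, t_aligned, time_out = markers$time)
  list(markers = markers,
       force = list(time = markers$time, lateral = lat$values,
                    rate = markers$rate %||% 100),
       offset = offset)
}

#' Fill marker gaps by rigid-body transfer or cubic splines
#'
#' Gaps (runs of NA) no longer than `max_gap_frames` are filled: when the
#' marker belongs to a rigid marker group of which at least 3 other markers
#' are visible throughout the gap, the gap is filled by the group's rigid
#' transform from the nearest complete frame; otherwise by a natural cubic
#' spline per coordinate. Longer gaps set the trial exclusion flag.
#'
#' @param markers Marker stream (list with `time`, `data`, optional
#'   `groups`: named list of rigid marker groups).
#' @param max_gap_frames Longest fillable gap (frames), default 10.
#' @return List: `markers` (filled), `excluded`, `reason`, and a gap audit
#'   table.
#' @export
fill_gaps_spline <- function(markers, max_gap_frames = 10) {
  data <- markers$data
  groups <- markers$groups %||% list()
  excluded <- FALSE; reasons <- character(0)
  audit <- list()
  for (mn in names(data)) {
    X <- data[[mn]]
    miss <- !stats::complete.cases(X)
    if (!any(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      len <- r$lengths[g]; i0 <- starts[g]; i1 <- ends[g]
      if (len > max_gap_frames) {
        excluded <- TRUE
        reasons <- c(reasons, sprintf("%s: gap of %d frames exceeds %d",
                                      mn, len, max_gap_frames))
        audit[[length(audit) + 1L]] <- data.frame(
          marker = mn, start = i0, length = len, method = "excluded")
        next
      }
      grp <- NULL
      for (gn in names(groups)) {
        if (mn %in% groups[[gn]]) grp <- setdiff(groups[[gn]], mn)
      }
      method <- "spline"
      if (!is.null(grp) && length(grp) >= 3) {
        others <- lapply(grp, function(g2) data[[g2]])
        gap_ok <- all(Reduce(`&`, lapply(others, function(O)
          stats::complete.cases(O[i0:i1, , drop = FALSE]))))
        ref <- which(stats::complete.cases(X) &
                       Reduce(`&`, lapply(others, stats::complete.cases)))
        if (gap_ok && length(ref) > 0) {
          rf <- ref[which.min(pmin(abs(ref - i0), abs(ref - i1)))]
          A <- do.call(rbind, lapply(others, function(O) O[rf, ]))
          for (ii in i0:i1) {
            B <- do.call(rbind, lapply(others, function(O) O[ii, ]))
            tr <- rigid_transform(A, B)
            X[ii, ] <- as.vector(tr$R %*% X[rf, ]) + tr$t
          }
          method <- "rigid"
        }
      }
      if (method == "spline") {
        okf <- which(stats::complete.cases(X))
        for (cc in 1:3) {
          sp <- stats::splinefun(markers$time[okf], X[okf, cc],
                                 method = "natural")
          X[i0:i1, cc] <- sp(markers$time[i0:i1])
        }
      }
      audit[[length(audit) + 1L]] <- data.frame(
        marker = mn, start = i0, length = len, method = method)
    }
    data[[mn]] <- X
  }
  markers$data <- data
  list(markers = markers, excluded = excluded,
       reason = if (excluded) paste(reasons, collapse = "; ") else NA_character_,
       audit = if (length(audit)) do.call(rbind, audit) else NULL)
}

#' Reconstruct scapula landmarks from the acromion cluster
#'
#' For each landmark coordinate, a linear regression of the pointer
#' calibration offsets on bench-height fraction (1, 0.5, 0) is evaluated at
#' each frame's height fraction, then mapped through the frame's cluster
#' pose to lab coordinates.
#'
#' @param calib A `scapula_calibration` (one pose variant: list with
#'   `height_fraction` (length 3) and `offsets`, a landmark-named list of
#'   3 x 3 matrices, rows = heights, cols = xyz cluster-frame coords).
#' @param cluster_pose List of per-frame cluster frames (`origin`, `R`), as
#'   built by [cluster_frames()].
#' @param height_fraction Per-frame normalized barbell height in [0, 1].
#' @return Named list of n x 3 lab-frame landmark trajectories.
#' @export
reconstruct_scapula <- function(calib, cluster_pose, height_fraction) {
  h <- calib$height_fraction
  if (length(h) != 3 || !setequal(round(h, 6), c(1, 0.5, 0))) {
    stop("reconstruct_scapula: calibration must contain height levels 1, 0.5, 0")
  }
  n <- length(height_fraction)
  out <- list()
  for (lm in names(calib$offsets)) {
    O <- calib$offsets[[lm]]
    ## per-coordinate linear fit offset = a + b * height_fraction
    cf <- vapply(1:3, function(cc) stats::coef(stats::lm(O[, cc] ~ h)),
                 numeric(2))
    traj <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      off <- cf[1, ] + cf[2, ] * height_fraction[i]
      traj[i, ] <- cluster_pose[[i]]$origin +
        as.vector(cluster_pose[[i]]$R %*% off)
    }
    out[[lm]] <- traj
  }
  out
}

#' Cluster frames from three acromion cluster markers
#'
#' @param markers Marker stream containing `ACL1`, `ACL2`, `ACL3`.
#' @return List of per-frame frames (`origin`, `R`).
#' @export
cluster_frames <- function(markers) {
  A1 <- markers$data$ACL1; A2 <- markers$data$ACL2; A3 <- markers$data$ACL3
  if (is.null(A1) || is.null(A2) || is.null(A3)) {
    stop("cluster_frames: cluster markers ACL1-ACL3 required")
  }
  lapply(seq_len(nrow(A1)), function(i)
    frame_from_points(A1[i, ], A2[i, ], A3[i, ]))
}

#' Assemble the 3D hand force from the measured lateral component
#'
#' The vertical component is the gravity share of the barbell (half the
#' barbell weight per hand); the mediolateral component is the measured
#' lateral force minus the static bending correction at the trial's grip
#' width; the anteroposterior component is zero by assumption. Signs:
#' positive measured lateral force = exerted away from the body midline;
#' the stored `force_on_hand` is the barbell's reaction on the (right)
#' hand, so its x component is minus the exerted lateral force and its y
#' component is minus the vertical share.
#'
#' @param lateral Measured per-hand lateral force (N), on the marker clock.
#' @param barbell_mass Total barbell mass (kg), default 16.
#' @param grip_width Trial grip width (m), used for the bending correction.
#' @param bending_calibration Optional data frame (`grip_width`, `offset_n`)
#'   from the static bending calibration; widths outside the table emit a
#'   warning and use the nearest value.
#' @param time Optional timestamps stored alongside.
#' @return A `hand_force_series`.
#' @export
assemble_hand_force <- function(lateral, barbell_mass = 16, grip_width = NULL,
                                bending_calibration = NULL, time = NULL) {
  if (barbell_mass <= 0) stop("assemble_hand_force: barbell_mass must be > 0")
  vertical <- barbell_mass / 2 * GRAVITY
  corr <- 0
  if (!is.null(bending_calibration) && !is.null(grip_width)) {
    gw <- bending_calibration$grip_width
    if (grip_width < min(gw) || grip_width > max(gw)) {
      warning("assemble_hand_force: grip width outside bending calibration ",
              "range; nearest value used")
    }
    corr <- stats::approx(gw, bending_calibration$offset_n,
                          xout = grip_width, rule = 2)$y
  }
  lat <- lateral - corr
  n <- length(lat)
  structure(list(
    time = time %||% (seq_len(n) - 1) / 100,
    exerted_lateral = lat,
    vertical = vertical,
    force_on_hand = cbind(x = -lat, y = rep(-vertical, n), z = rep(0, n))
  ), class = "hand_force_series")
}

## strict local minima of x whose topographic prominence (height to the
## lower of the two enclosing maxima, bounded by the nearest lower points)
## exceeds `prom`
local_minima_prominence <- function(x, prom) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  keep <- integer(0)
  for (b in cand) {
    left <- which(x[seq_len(b - 1)] < x[b])
    l0 <- if (length(left)) max(left) else 1L
    right <- which(x[(b + 1):n] < x[b])
    r0 <- if (length(right)) b + min(right) else n
    p <- min(max(x[l0:b]), max(x[b:r0])) - x[b]
    if (p >= prom) keep <- c(keep, b)
  }
  keep
}

#' Segment bench-press repetitions and build the phase map
#'
#' Repetitions are located from the barbell-height minima (prominence
#' filtered); each repetition spans from the preceding height maximum to
#' the following one. The phase map is piecewise linear in time: descent
#' maps to [0, 50] percent and ascent to [50, 100], the lowest point
#' falling at exactly 50.
#'
#' @param height Barbell height signal (m).
#' @param time Timestamps.
#' @param prominence Minimum height excursion for a repetition (m).
#' @return A `cycle_partition`: data frame (`start`, `bottom`, `end`) plus
#'   a per-sample `phase` vector (NA outside repetitions) and `rep_id`.
#' @export
segment_cycles <- function(height, time = NULL, prominence = 0.05) {
  n <- length(height)
  time <- time %||% ((seq_len(n) - 1) / 100)
  bottoms <- local_minima_prominence(height, prominence)
  if (length(bottoms) == 0) {
    stop("segment_cycles: no repetition exceeds the prominence")
  }
  reps <- data.frame(start = integer(0), bottom = integer(0), end = integer(0))
  bounds <- c(1L, bottoms, n)
  for (bi in seq_along(bottoms)) {
    b <- bottoms[bi]
    lo <- bounds[bi]          # previous bottom (or series start)
    hi <- bounds[bi + 2L]     # next bottom (or series end)
    vals <- height[lo:b]   # last top sample before the descent
    s <- lo + length(vals) - which.max(rev(vals))
    e <- b + which.max(height[b:hi]) - 1L
    if (s < b && b < e) reps <- rbind(reps, data.frame(start = s, bottom = b, end = e))
  }
  if (nrow(reps) == 0) stop("segment_cycles: no valid repetition found")
  phase <- rep(NA_real_, n)
  rep_id <- rep(NA_integer_, n)
  for (ri in seq_len(nrow(reps))) {
    s <- reps$start[ri]; b <- reps$bottom[ri]; e <- reps$end[ri]
    phase[s:b] <- 50 * (time[s:b] - time[s]) / (time[b] - time[s])
    phase[b:e] <- 50 + 50 * (time[b:e] - time[b]) / (time[e] - time[b])
    rep_id[s:e] <- ri
  }
  structure(list(reps = reps, phase = phase, rep_id = rep_id, time = time),
            class = "cycle_partition")
}

#' Derived joint-center trajectories
#'
#' Wrist and elbow centers as epicondyle/styloid midpoints; the
#' glenohumeral center as a fixed offset in the scapula landmark frame
#' (offset taken from the model geometry).
#'
#' @param markers Marker stream including `RLEL`, `RMEL`, `RLWR`, `RMWR`
#'   and reconstructed `AA`, `TS`, `AI`.
#' @param model A `shoulder_model` providing the GH offset; default generic.
#' @return Named list of n x 3 trajectories (`elbow`, `wrist`, `gh`).
#' @export
compute_joint_centers <- function(markers, model = NULL) {
  d <- markers$data
  need <- c("RLEL", "RMEL", "RLWR", "RMWR")
  if (!all(need %in% names(d))) {
    stop("compute_joint_centers: missing markers ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  out <- list(elbow = (d$RLEL + d$RMEL) / 2, wrist = (d$RLWR + d$RMWR) / 2)
  if (all(c("AA", "TS", "AI") %in% names(d))) {
    model <- model %||% load_model()
    sc <- model$segments$scapula
    Lref <- frame_from_points(sc$landmarks$AA, sc$landmarks$TS, sc$landmarks$AI)
    gh_local <- as.vector(t(Lref$R) %*% (sc$points$gh_center - Lref$origin))
    n <- nrow(d$AA)
    gh <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      L <- frame_from_points(d$AA[i, ], d$TS[i, ], d$AI[i, ])
      gh[i, ] <- L$origin + as.vector(L$R %*% gh_local)
    }
    out$gh <- gh
  }
  out
}

#' Preprocess a raw trial recording
#'
#' Runs the full preprocessing chain: pulse synchronization, 6 Hz
#' zero-phase filtering and 100 Hz up-sampling of the lateral force, marker
#' gap filling, cycle segmentation from the barbell markers, scapula
#' landmark reconstruction and hand-force assembly.
#'
#' @param trial A `trial_recording` (see [simulate_trial()]).
#' @param calib A two-variant scapula calibration (see
#'   [generate_scapula_calibration()]); the variant matching the trial's
#'   scapula pose is used (retracted for retracted, neutral otherwise).
#' @param options List: `max_gap_frames` (10), `cutoff_hz` (6),
#'   `prominence` (0.05), `bending_calibration` (NULL).
#' @return A `clean_trial`: synchronized 100 Hz markers (including
#'   reconstructed scapula landmarks), `force` (`hand_force_series`),
#'   `partition`, `excluded` + `reason`, condition and subject metadata.
#' @export
preprocess_trial <- function(trial, calib, options = list()) {
  opt <- utils::modifyList(list(max_gap_frames = 10, cutoff_hz = 6,
                                prominence = 0.05,
                                bending_calibration = NULL), options)
  sync <- synchronize(trial$markers, trial$force)
  lat <- butterworth_lowpass(sync$force$lateral, opt$cutoff_hz,
                             rate = trial$markers$rate %||% 100)
  gf <- fill_gaps_spline(trial$markers, opt$max_gap_frames)
  mk <- gf$markers

  bar_h <- (mk$data$RBAR[, 2] + mk$data$LBAR[, 2]) / 2
  partition <- segment_cycles(bar_h, mk$time, prominence = opt$prominence)
  ## per-frame normalized height between each repetition's bottom and top
  hf <- rep(NA_real_, length(bar_h))
  for (ri in seq_len(nrow(partition$reps))) {
    r <- partition$reps[ri, ]
    span <- r$start:r$end
    h0 <- bar_h[r$bottom]; h1 <- max(bar_h[c(r$start, r$end)])
    hf[span] <- pmin(pmax((bar_h[span] - h0) / (h1 - h0), 0), 1)
  }
  hf[is.na(hf)] <- 1  # lead-in/out at the top

  variant <- if (identical(trial$condition$scapula_pose, "retracted"))
    "retracted" else "neutral"
  cl <- cluster_frames(mk)
  scap <- reconstruct_scapula(calib[[variant]], cl, hf)
  for (lm in names(scap)) mk$data[[lm]] <- scap[[lm]]

  force <- assemble_hand_force(lat, trial$barbell_mass,
                               grip_width = trial$grip_width,
                               bending_calibration = opt$bending_calibration,
                               time = mk$time)
  structure(list(markers = mk, force = force, partition = partition,
                 barbell_height = bar_h, height_fraction = hf,
                 excluded = gf$excluded, reason = gf$reason,
                 gap_audit = gf$audit, sync_offset = sync$offset,
                 condition = trial$condition, subject_id = trial$subject_id),
            class = "clean_trial")
}
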