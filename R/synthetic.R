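## Synthetic cohort, technique grid and raw-recording generator.
##
## The generator emulates the measurement setup the analysis assumes:
## 100 Hz marker trajectories driven by a subject-scaled model through a
## smooth bench-press cycle, a 48 Hz instrumented-barbell lateral force
## channel with a shared sync pulse, pointer calibrations of the scapula
## landmarks at three bench heights, and a large between-subject spread in
## mediolateral hand force.

.bp_cache <- new.env(parent = emptyenv())

generic_model <- function() {
  if (is.null(.bp_cache$generic)) .bp_cache$generic <- load_model()
  .bp_cache$generic
}

#' Synthetic-data generation defaults
#'
#' Central parameter set of the generator: cohort sampling distributions
#' (cohort means 1.80 m height, 87 kg mass), cycle tempo (2 s descent +
#' 2 s ascent), 1 mm marker noise, stream offset range, and the
#' mediolateral-force model (subject-level mean fraction of the 78.48 N
#' vertical share, large between-subject spread, condition-level shifts).
#'
#' @return Named list of defaults; override individual entries through the
#'   `noise`/`params` arguments of the generator functions.
#' @export
bp_sim_defaults <- function() {
  list(
    height_mean = 1.80, height_sd = 0.10,
    mass_mean = 87, mass_sd = 8,
    baw_height_ratio = 0.22, baw_sd = 0.015,
    experience_mean = 6.7, experience_sd = 3.9,
    marker_sd = 0.001,
    descent_s = 2, ascent_s = 2, lead_in_s = 0.4, lead_out_s = 0.3,
    marker_rate = 100, force_rate = 48,
    pulse_time = 0.25, offset_range = 0.45,
    barbell_mass = 16,
    lateral_frac_base = 0.24, lateral_frac_between_sd = 0.70,
    lateral_effects = list(grip = c("1" = 0.03, "1.5" = 0, "2" = 0.11),
                           abduction = c("45" = 0.06, "70" = 0, "90" = 0.02),
                           pose = c(neutral = 0, retracted = 0.21,
                                    released = -0.05)),
    lateral_rep_sd = 0.05, lateral_wiggle = 0.04, force_noise_sd = 1.0,
    eps_top = 0.25,
    eps_bottom = c("1" = 2.1, "1.5" = 1.9, "2" = 1.7),
    sc_protraction = -0.10, sc_elevation = 0.05,
    pose_offsets = list(
      neutral = c(),
      retracted = c(ac_retraction = 0.18, sc_protraction = -0.12),
      released = c(ac_tilt = -0.08, ac_rotation = 0.05)),
    cycle_coupling = c(ac_retraction = 0.04, sc_elevation = 0.03),
    segment_ratios = c(upper_arm = 0.186, forearm = 0.146, hand = 0.108,
                       trunk = 0.288)
  )
}

#' Generate a synthetic subject
#'
#' Anthropometry is sampled from the cohort distributions (height
#' 1.80 +/- 0.10 m, mass 87 +/- 8 kg); segment lengths derive from height by
#' a fixed proportion table. Each subject also carries a subject-level
#' mediolateral force propensity (fraction of the vertical hand force),
#' reproducing the large between-individual spread in exerted lateral
#' forces.
#'
#' @param seed Non-negative integer; the subject is a pure function of it.
#' @param overrides Named list overriding sampled fields (`height`, `mass`,
#'   `biacromial_width`, `experience_years`, `lateral_frac`).
#' @param params Generator defaults, see [bp_sim_defaults()].
#' @return A `subject_anthropometry` object.
#' @export
generate_subject <- function(seed, overrides = list(), params = bp_sim_defaults()) {
  stopifnot(is.numeric(seed), seed >= 0)
  s <- with_seed(derive_seed(seed, "subject"), {
    list(height = stats::rnorm(1, params$height_mean, params$height_sd),
         mass = stats::rnorm(1, params$mass_mean, params$mass_sd),
         baw_dev = stats::rnorm(1, 0, params$baw_sd),
         experience_years = max(3, stats::rnorm(1, params$experience_mean,
                                                params$experience_sd)),
         lateral_frac = stats::rnorm(1, params$lateral_frac_base,
                                     params$lateral_frac_between_sd))
  })
  height <- overrides$height %||% s$height
  mass <- overrides$mass %||% s$mass
  baw <- overrides$biacromial_width %||% (params$baw_height_ratio * height + s$baw_dev)
  check_range(height, 1.0, 2.3, "height")
  check_range(mass, 30, 200, "mass")
  check_range(baw, 0.25, 0.55, "biacromial_width")
  segl <- c(params$segment_ratios * height, biacromial = baw)
  structure(list(
    subject_id = sprintf("S%03d", as.integer(seed)),
    seed = as.integer(seed),
    height = height, mass = mass, biacromial_width = baw,
    experience_years = overrides$experience_years %||% s$experience_years,
    lateral_frac = overrides$lateral_frac %||% s$lateral_frac,
    segment_lengths = segl
  ), class = "subject_anthropometry")
}

#' @export
print.subject_anthropometry <- function(x, ...) {
  cat(sprintf("Subject %s: height %.2f m, mass %.1f kg, BAW %.3f m\n",
              x$subject_id, x$height, x$mass, x$biacromial_width))
  invisible(x)
}

#' Grip width implied by a condition
#'
#' Grip width is the bi-acromial width times the condition's grip factor.
#' @param subject A `subject_anthropometry`.
#' @param condition A technique-grid row.
#' @export
grip_width <- function(subject, condition) {
  as.numeric(condition$grip_width_baw) * subject$biacromial_width
}

#' The 3 x 3 x 3 technique grid
#'
#' All 27 combinations of grip width (1, 1.5, 2 BAW), shoulder abduction
#' (45, 70, 90 degrees) and scapula pose (neutral, retracted, released).
#' Exactly 6 combinations are flagged unsafe: the narrow 1 BAW grip
#' combined with 70 or 90 degree abduction, across the three scapula poses,
#' leaving 21 performed conditions.
#'
#' @param unsafe_rule Function (grip, abduction) -> logical; the default
#'   implements the rule above.
#' @return Data frame with `grip_width_baw`, `abduction_deg`,
#'   `scapula_pose`, `is_safe`, `id`.
#' @export
technique_grid <- function(unsafe_rule = function(grip, abd) grip == 1 & abd >= 70) {
  g <- expand.grid(grip_width_baw = c(1, 1.5, 2),
                   abduction_deg = c(45, 70, 90),
                   scapula_pose = c("neutral", "retracted", "released"),
                   stringsAsFactors = FALSE)
  g$is_safe <- !unsafe_rule(g$grip_width_baw, g$abduction_deg)
  g$id <- sprintf("g%s_a%d_%s", g$grip_width_baw, g$abduction_deg,
                  g$scapula_pose)
  g
}

#' Subject-specific true model
#'
#' Scales the generic model directly from the subject's segment lengths
#' (this is the model that synthesizes the markers; the pipeline recovers
#' an estimate of it through [scale_model()] on a static trial).
#' @param subject A `subject_anthropometry`.
#' @export
subject_model <- function(subject) {
  gm <- generic_model()
  hf <- subject$height / gm$generic_height
  factors <- c(thorax = hf,
               clavicle = subject$biacromial_width / gm$generic_baw,
               scapula = hf,
               humerus = unname(subject$segment_lengths["upper_arm"]) /
                 (0.186 * gm$generic_height),
               forearm = unname(subject$segment_lengths["forearm"]) /
                 (0.146 * gm$generic_height))
  scale_model_by_factors(gm, factors, mass_scale = subject$mass / gm$generic_mass)
}

## humeral axial rotation keeping the elbow flexion axis horizontal and the
## forearm swinging upward, given plane angle alpha and elevation dip delta
gh_rot_for_vertical_forearm <- function(alpha, delta) {
  R1 <- rot_y(-alpha) %*% rot_x(delta)
  e1y <- R1[2, 1]; e2y <- R1[2, 2]
  s0 <- atan2(-e1y, e2y)
  for (sg in c(s0, s0 + pi)) {
    Rh <- R1 %*% rot_z(sg)
    if (Rh[2, 2] > 0) return(sg)   # local +y (flexion direction) points up
  }
  s0
}

## assemble the full coordinate vector for one frame of the press cycle
press_posture <- function(model, alpha, delta, eps, scap, params) {
  q <- posture_vector(model, c(
    sc_protraction = params$sc_protraction, sc_elevation = params$sc_elevation))
  q[names(scap)] <- scap
  q["gh_plane"] <- alpha
  q["gh_elev"] <- delta
  q["gh_rot"] <- gh_rot_for_vertical_forearm(alpha, delta)
  q["elbow_flexion"] <- eps
  q
}

## closed-form elevation dip placing the hand at half the grip width.
## With zero humeral axial rotation the hand's lateral coordinate is
##   gh_x + cos(a) v1 - sin(a) sin(d) v2 - sin(a) cos(d) v3
## with v the hand position in the humerus frame, so d solves
## A sin(d) + B cos(d) = C.
solve_delta <- function(model, gh_x, alpha, eps, target_x,
                        guess = NULL, lower = -1.2, upper = 1.54) {
  hl <- model$segments$forearm$points$hand_center
  Lh <- -model$segments$forearm$joint_location[3]
  v1 <- hl[1]
  v2 <- cos(eps) * hl[2] - sin(eps) * hl[3]
  v3 <- sin(eps) * hl[2] + cos(eps) * hl[3] - Lh
  A <- -sin(alpha) * v2
  B <- -sin(alpha) * v3
  C <- target_x - gh_x - cos(alpha) * v1
  R <- sqrt(A^2 + B^2)
  if (abs(C) > R) {
    stop(sprintf(paste0("solve_delta: no admissible arm elevation for ",
                        "alpha=%.2f, eps=%.2f, target x=%.3f"),
                 alpha, eps, target_x))
  }
  psi <- atan2(B, A)
  base <- asin(max(-1, min(1, C / R)))
  cand <- c(base - psi, pi - base - psi)
  cand <- ((cand + pi) %% (2 * pi)) - pi
  cand <- cand[cand >= lower & cand <= upper]
  if (length(cand) == 0) {
    stop("solve_delta: no arm elevation within joint limits")
  }
  if (is.null(guess)) cand[which.max(cand)]
  else cand[which.min(abs(cand - guess))]
}

## scapula coordinate offsets for a condition at cycle depth w in [0,1]
scap_coords <- function(pose, w, params) {
  off <- c(ac_retraction = 0, ac_rotation = 0, ac_tilt = 0)
  po <- params$pose_offsets[[pose]]
  base_sc <- c(sc_protraction = params$sc_protraction,
               sc_elevation = params$sc_elevation)
  for (nm in names(po)) {
    if (nm %in% names(off)) off[nm] <- off[nm] + po[nm]
    else base_sc[nm] <- base_sc[nm] + po[nm]
  }
  cc <- params$cycle_coupling
  for (nm in names(cc)) {
    if (nm %in% names(off)) off[nm] <- off[nm] + cc[nm] * w
    else base_sc[nm] <- base_sc[nm] + cc[nm] * w
  }
  c(base_sc, off)
}

#' Simulate a raw bench-press trial recording
#'
#' Drives the subject's true model through `n_reps` smooth press cycles
#' honoring the condition's grip width, abduction angle and scapula pose;
#' synthesizes 100 Hz markers by forward kinematics (additive Gaussian
#' noise), a 48 Hz mediolateral hand-force channel with subject-level mean
#' and condition shifts, and one rising sync pulse per stream with a random
#' stream offset. Fully reproducible given `seed`.
#'
#' @param subject A `subject_anthropometry`.
#' @param condition A safe technique-grid row.
#' @param n_reps Repetitions (default 3, as performed per technique).
#' @param noise Named overrides of [bp_sim_defaults()] entries (e.g.
#'   `marker_sd = 0`, `lateral_frac = 0.3` to pin the mediolateral mean).
#' @param seed Integer seed.
#' @return List of class `trial_recording` with `markers`, `force`,
#'   `condition`, `grip_width`, `barbell_mass`, and a `ground_truth`
#'   attribute-free companion element.
#' @export
simulate_trial <- function(subject, condition, n_reps = 3, noise = list(),
                           seed = 0) {
  if (is.data.frame(condition)) condition <- as.list(condition[1, ])
  if (!isTRUE(condition$is_safe)) {
    stop("simulate_trial: refusing to simulate an unsafe condition (",
         condition$id %||% "", ")")
  }
  if (n_reps < 1) stop("simulate_trial: n_reps must be >= 1")
  params <- utils::modifyList(bp_sim_defaults(), noise)
  model <- subject_model(subject)
  rate <- params$marker_rate
  Td <- params$descent_s; Ta <- params$ascent_s
  Trep <- Td + Ta
  Ttot <- params$lead_in_s + n_reps * Trep + params$lead_out_s
  n <- floor(Ttot * rate) + 1L
  tt <- (seq_len(n) - 1) / rate

  ## cycle depth w(t) in [0,1]
  w <- numeric(n)
  for (i in seq_len(n)) {
    u <- tt[i] - params$lead_in_s
    if (u <= 0 || u >= n_reps * Trep) { w[i] <- 0; next }
    ur <- u %% Trep
    w[i] <- if (ur <= Td) (1 - cos(pi * ur / Td)) / 2
            else (1 + cos(pi * (ur - Td) / Ta)) / 2
  }

  alpha <- condition$abduction_deg * pi / 180
  gkey <- as.character(condition$grip_width_baw)
  eps_bot <- params$eps_bottom[[gkey]]
  eps <- params$eps_top + (eps_bot - params$eps_top) * w
  w2 <- grip_width(subject, condition) / 2

  nq <- model$nq
  Q <- matrix(0, n, nq, dimnames = list(NULL, model$dof_table$name))
  delta <- numeric(n)
  guess <- NULL
  for (i in seq_len(n)) {
    scap <- scap_coords(condition$scapula_pose, w[i], params)
    q0 <- press_posture(model, alpha, 0, 0, scap, params)
    gh_x <- forward_kinematics(model, q0)$origin$humerus[1]
    d <- solve_delta(model, gh_x, alpha, eps[i], w2, guess = guess)
    delta[i] <- d; guess <- d
    Q[i, ] <- press_posture(model, alpha, d, eps[i], scap, params)
  }

  ## forward kinematics -> markers (+ mirrored left side, + barbell ends)
  marker_names <- names(model$markers)
  right_only <- setdiff(marker_names, names(model$config$left_markers))
  data <- lapply(right_only, function(x) matrix(NA_real_, n, 3))
  names(data) <- right_only
  hand <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    fr <- forward_kinematics(model, Q[i, ])
    for (mn in right_only) {
      mk <- model$markers[[mn]]
      data[[mn]][i, ] <- fk_point(fr, mk$segment, mk$point)
    }
    hand[i, ] <- fk_point(fr, "forearm", model$segments$forearm$points$hand_center)
  }
  mirror <- c(LACR = "RACR", LLEL = "RLEL", LMEL = "RMEL",
              LLWR = "RLWR", LMWR = "RMWR")
  for (lm in names(mirror)) {
    data[[lm]] <- data[[mirror[lm]]] * matrix(rep(c(-1, 1, 1), each = n), n, 3)
  }
  bar_reach <- w2 + 0.30
  data$RBAR <- cbind(rep(bar_reach, n), hand[, 2], hand[, 3])
  data$LBAR <- cbind(rep(-bar_reach, n), hand[, 2], hand[, 3])

  seed_i <- derive_seed(seed, subject$subject_id, condition$id %||% "cond")
  gt_lateral <- NULL
  rec <- with_seed(seed_i, {
    if (params$marker_sd > 0) {
      for (mn in names(data)) {
        data[[mn]] <- data[[mn]] +
          matrix(stats::rnorm(3 * n, 0, params$marker_sd), n, 3)
      }
    }
    ## marker-stream pulse: rises exactly on a marker sample
    pulse_m <- as.numeric(tt >= params$pulse_time - 1e-9)
    ## force stream: its clock starts `offset` before/after the marker clock
    ## and its pulse edge falls exactly on one of its own samples
    frate <- params$force_rate
    offset <- stats::runif(1, -params$offset_range, params$offset_range)
    k_e <- max(2L, round((params$pulse_time - offset) * frate))
    ts_f <- params$pulse_time - k_e / frate   # global time of force sample 0
    nf <- floor((Ttot - ts_f) * frate) + 1L
    tf_global <- ts_f + (seq_len(nf) - 1) / frate
    pulse_f <- as.numeric(seq_len(nf) - 1 >= k_e)

    ## mediolateral force (N) as a function of global time
    V <- params$barbell_mass / 2 * GRAVITY
    eff <- params$lateral_effects
    cond_eff <- eff$grip[[gkey]] +
      eff$abduction[[as.character(condition$abduction_deg)]] +
      eff$pose[[condition$scapula_pose]]
    mu <- params$lateral_frac %||% (subject$lateral_frac + cond_eff)
    rep_off <- stats::rnorm(n_reps, 0, params$lateral_rep_sd)
    phi <- stats::runif(1, 0, 2 * pi)
    g_lat <- function(gt) {
      u <- gt - params$lead_in_s
      ri <- pmin(pmax(floor(u / Trep) + 1, 1), n_reps)
      V * (mu + rep_off[ri] +
             params$lateral_wiggle * sin(2 * pi * gt / Trep + phi))
    }
    lat <- g_lat(pmin(pmax(tf_global, 0), Ttot)) +
      stats::rnorm(nf, 0, params$force_noise_sd)
    gt_lateral <- list(mu = mu, rep_off = rep_off, cond_eff = cond_eff,
                       V = V)
    list(pulse_m = pulse_m, tf = (seq_len(nf) - 1) / frate,
         pulse_f = pulse_f, lat = lat, offset = ts_f,
         gt_lateral = gt_lateral)
  })
  gt_lateral <- rec$gt_lateral

  groups <- list(acromion_cluster = c("ACL1", "ACL2", "ACL3", "RACR"),
                 barbell = c("RBAR", "LBAR"))
  structure(list(
    subject_id = subject$subject_id,
    condition = condition,
    barbell_mass = params$barbell_mass,
    grip_width = 2 * w2,
    markers = list(time = tt, rate = rate, data = data,
                   pulse = rec$pulse_m, groups = groups),
    force = list(time = rec$tf, rate = params$force_rate,
                 lateral = rec$lat, pulse = rec$pulse_f),
    ground_truth = list(q = Q, time = tt, depth = w, delta = delta,
                        eps = eps, lateral = gt_lateral,
                        stream_offset = rec$offset, seed = seed,
                        n_reps = n_reps)
  ), class = "trial_recording")
}

#' Inject marker gaps into a recording
#'
#' Replaces the specified sample runs with NA and keeps gap bookkeeping on
#' the trial for test assertions.
#'
#' @param trial A `trial_recording`.
#' @param gap_spec List of `list(marker =, start =, length =)`.
#' @return The modified trial.
#' @export
inject_marker_gaps <- function(trial, gap_spec) {
  n <- length(trial$markers$time)
  seen <- list()
  for (g in gap_spec) {
    if (g$start < 1 || g$start + g$length - 1 > n) {
      stop("inject_marker_gaps: gap outside record length")
    }
    idx <- g$start:(g$start + g$length - 1)
    prev <- seen[[g$marker]]
    if (!is.null(prev) && any(idx %in% prev)) {
      stop("inject_marker_gaps: overlapping gaps on marker ", g$marker)
    }
    seen[[g$marker]] <- c(prev, idx)
    trial$markers$data[[g$marker]][idx, ] <- NA_real_
  }
  trial$gaps <- gap_spec
  trial
}

#' Pointer calibration of the scapula landmarks
#'
#' For both the neutral and retracted scapula variants, returns the
#' cluster-frame offsets of the trigonum spinae (TS), angulus acromialis
#' (AA) and angulus inferior (AI) at the up, mid and down bench positions
#' (height fractions 1, 0.5, 0). Offsets vary linearly with height by the
#' configurable artifact `slope` (per meter-equivalent of the height
#' fraction) plus Gaussian pointer noise.
#'
#' @param subject A `subject_anthropometry`.
#' @param seed Integer seed.
#' @param noise_sd Pointer noise SD (m), default 0.
#' @param slope 3-vector artifact slope (m per unit height fraction).
#' @param params Generator defaults.
#' @return List with `neutral` and `retracted` calibration variants.
#' @export
generate_scapula_calibration <- function(subject, seed = 0, noise_sd = 0,
                                         slope = c(0, 0, 0),
                                         params = bp_sim_defaults()) {
  model <- subject_model(subject)
  hts <- c(1, 0.5, 0)
  out <- list()
  rs <- derive_seed(seed, subject$subject_id, "calib")
  with_seed(rs, {
    for (variant in c("neutral", "retracted")) {
      offsets <- list(AA = matrix(0, 3, 3), TS = matrix(0, 3, 3),
                      AI = matrix(0, 3, 3))
      poses <- vector("list", 3)
      for (hi in seq_along(hts)) {
        h <- hts[hi]
        scap <- scap_coords(variant, 1 - h, params)
        q <- press_posture(model, 70 * pi / 180, 0.6 * (1 - h) + 0.4,
                           params$eps_top + (1 - h), scap, params)
        fr <- forward_kinematics(model, q)
        cl <- frame_from_points(
          fk_point(fr, "scapula", model$segments$scapula$markers$ACL1),
          fk_point(fr, "scapula", model$segments$scapula$markers$ACL2),
          fk_point(fr, "scapula", model$segments$scapula$markers$ACL3))
        poses[[hi]] <- cl
        for (lm in names(offsets)) {
          p <- fk_point(fr, "scapula", model$segments$scapula$landmarks[[lm]])
          off <- as.vector(t(cl$R) %*% (p - cl$origin)) + slope * h +
            stats::rnorm(3, 0, noise_sd)
          offsets[[lm]][hi, ] <- off
        }
      }
      out[[variant]] <- list(height_fraction = hts, offsets = offsets,
                             cluster_poses = poses)
    }
  })
  structure(out, class = "scapula_calibration")
}

#' Static calibration markers for model scaling
#'
#' Markers (including the pointer-derived scapula landmarks) at the
#' reference posture of the subject's true model, with optional noise.
#'
#' @param subject A `subject_anthropometry`.
#' @param noise_sd Marker noise SD (m).
#' @param seed Integer seed.
#' @return Named matrix (markers x 3).
#' @export
generate_static_markers <- function(subject, noise_sd = 0, seed = 0) {
  model <- subject_model(subject)
  q <- posture_vector(model, model$reference_posture)
  mk <- model_markers(model, q)
  if (noise_sd > 0) {
    mk <- mk + with_seed(derive_seed(seed, subject$subject_id, "static"),
                         matrix(stats::rnorm(length(mk), 0, noise_sd),
                                nrow(mk), 3))
  }
  mk
}
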