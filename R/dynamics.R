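## Muscle geometry, passive forces and quasi-static inverse dynamics.

seg_index_vec <- function() {
  stats::setNames(seq_along(segment_order), segment_order)
}

## per-path-point pulling force directions for unit tension: each point is
## pulled toward its neighbors along the polyline
path_point_forces <- function(P) {
  np <- nrow(P)
  f <- matrix(0, np, 3)
  for (k in seq_len(np)) {
    if (k > 1) {
      d <- P[k - 1, ] - P[k, ]
      nd <- vnorm(d)
      if (nd < 1e-9) stop("degenerate zero-length muscle path segment")
      f[k, ] <- f[k, ] + d / nd
    }
    if (k < np) {
      d <- P[k + 1, ] - P[k, ]
      nd <- vnorm(d)
      if (nd < 1e-9) stop("degenerate zero-length muscle path segment")
      f[k, ] <- f[k, ] + d / nd
    }
  }
  f
}

#' Muscle moment arms and path geometry at a posture
#'
#' Moment arms follow the tendon-excursion convention: the moment arm of a
#' bundle about a coordinate equals minus the partial derivative of its path
#' length with respect to that coordinate, evaluated here analytically as
#' the torque per unit tension about the coordinate's instantaneous axis.
#'
#' @param model A `shoulder_model`.
#' @param q Coordinate vector (or pass `frames`).
#' @param frames Optional precomputed [forward_kinematics()] output.
#' @return List: `length` (per bundle, m), `lnorm` (normalized by optimal
#'   length), `moment_arm` (bundles x coordinates, m).
#' @export
muscle_geometry <- function(model, q = NULL, frames = NULL) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  si_v <- seg_index_vec(); dof_seg <- si_v[model$dof_table$segment]
  nmus <- length(model$muscles)
  nq <- model$nq
  arm <- matrix(0, nmus, nq,
                dimnames = list(names(model$muscles), model$dof_table$name))
  len <- numeric(nmus)
  for (i in seq_len(nmus)) {
    m <- model$muscles[[i]]
    P <- muscle_path_lab(model, frames, m$name)
    len[i] <- sum(sqrt(rowSums(diff(P)^2)))
    f <- path_point_forces(P)
    pseg <- si_v[vapply(m$path, `[[`, character(1), "segment")]
    for (j in seq_len(nq)) {
      distal <- pseg >= dof_seg[j]
      if (!any(distal) || all(distal)) next  # path does not cross the joint
      a <- frames$dof_axis[, j]; cj <- frames$dof_center[, j]
      tau <- 0
      for (k in which(distal)) {
        tau <- tau + sum(a * cross3(P[k, ] - cj, f[k, ]))
      }
      arm[i, j] <- tau
    }
  }
  names(len) <- names(model$muscles)
  lopt <- vapply(model$muscles, `[[`, numeric(1), "lopt")
  list(length = len, lnorm = len / lopt, moment_arm = arm)
}

#' Passive muscle force
#'
#' Zero at or below the slack length, exponential rise above it:
#' `fmax * k1 * (exp(k2 * (lnorm - slack)) - 1)`.
#'
#' @param bundle A muscle bundle (element of `model$muscles`), needing
#'   `fmax` and `slack`.
#' @param lnorm Path length normalized by the optimal path length.
#' @param k1,k2 Passive stiffness shape parameters.
#' @return Passive force in N.
#' @export
passive_force <- function(bundle, lnorm, k1 = 0.015, k2 = 6) {
  if (any(lnorm <= 0)) stop("passive_force: normalized length must be > 0")
  ifelse(lnorm <= bundle$slack, 0,
         bundle$fmax * k1 * (exp(k2 * (lnorm - bundle$slack)) - 1))
}

## generalized force about each coordinate from a point force F applied at
## lab point p on `segment` (zero for coordinates proximal of the segment)
generalized_force_point <- function(model, frames, segment, p, F) {
  si_v <- seg_index_vec(); dof_seg <- si_v[model$dof_table$segment]
  si <- si_v[[segment]]
  out <- numeric(model$nq)
  for (j in seq_len(model$nq)) {
    if (dof_seg[j] > si) next
    a <- frames$dof_axis[, j]
    out[j] <- sum(a * cross3(p - frames$dof_center[, j], F))
  }
  out
}

#' Net joint moments by quasi-static inverse dynamics
#'
#' Computes, per frame, the generalized moments the muscles must produce to
#' balance the external hand force and segment gravity. By default the
#' analysis is quasi-static (accelerations ignored); with
#' `quasi_static = FALSE` translational segment inertia (point masses at the
#' segment centers of mass, accelerations by finite differences) is added.
#'
#' @param model A `shoulder_model`.
#' @param posture A `posture_series`.
#' @param hand_force Either a `hand_force_series` (see
#'   [assemble_hand_force()]) or an n x 3 matrix of lab-frame force on the
#'   hand center, sampled on the posture frames.
#' @param gravity Include segment weight terms.
#' @param quasi_static Ignore inertial terms (default).
#' @return Frames x coordinates matrix of required muscle moments (N m).
#' @export
inverse_dynamics <- function(model, posture, hand_force, gravity = TRUE,
                             quasi_static = TRUE) {
  Fh <- hand_force_matrix(hand_force, nrow(posture$q), posture$sample_index)
  n <- nrow(posture$q)
  M <- matrix(0, n, model$nq,
              dimnames = list(NULL, model$dof_table$name))
  movable <- setdiff(segment_order, "thorax")
  com_lab <- if (!quasi_static) {
    lapply(movable, function(sn) matrix(0, n, 3))
  } else NULL
  if (!is.null(com_lab)) names(com_lab) <- movable

  frames_list <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- forward_kinematics(model, posture$q[i, ])
    frames_list[[i]] <- fr
    Q <- generalized_force_point(model, fr, "forearm",
                                 fk_point(fr, "forearm",
                                          model$segments$forearm$points$hand_center),
                                 Fh[i, ])
    if (gravity) {
      for (sn in movable) {
        s <- model$segments[[sn]]
        pc <- fk_point(fr, sn, s$com)
        Q <- Q + generalized_force_point(model, fr, sn, pc,
                                         c(0, -s$mass * GRAVITY, 0))
        if (!is.null(com_lab)) com_lab[[sn]][i, ] <- pc
      }
    } else if (!is.null(com_lab)) {
      for (sn in movable) {
        com_lab[[sn]][i, ] <- fk_point(fr, sn, model$segments[[sn]]$com)
      }
    }
    M[i, ] <- -Q
  }

  if (!quasi_static && n >= 3) {
    h <- diff(posture$time)
    for (sn in movable) {
      s <- model$segments[[sn]]
      acc <- matrix(0, n, 3)
      for (i in 2:(n - 1)) {
        hh <- posture$time[i + 1] - posture$time[i - 1]
        acc[i, ] <- 4 * (com_lab[[sn]][i + 1, ] - 2 * com_lab[[sn]][i, ] +
                           com_lab[[sn]][i - 1, ]) / hh^2
      }
      for (i in seq_len(n)) {
        fr <- frames_list[[i]]
        si_v <- seg_index_vec(); dof_seg <- si_v[model$dof_table$segment]
        si <- si_v[[sn]]
        for (j in seq_len(model$nq)) {
          if (dof_seg[j] > si) next
          a <- fr$dof_axis[, j]
          M[i, j] <- M[i, j] +
            s$mass * sum(a * cross3(com_lab[[sn]][i, ] - fr$dof_center[, j],
                                    acc[i, ]))
        }
      }
    }
  }
  M
}

## accept a hand_force_series or a plain matrix; subset to posture frames
hand_force_matrix <- function(hand_force, n, sample_index) {
  if (inherits(hand_force, "hand_force_series")) {
    Fm <- hand_force$force_on_hand[sample_index, , drop = FALSE]
  } else {
    Fm <- as.matrix(hand_force)
    if (nrow(Fm) == 1) Fm <- Fm[rep(1, n), , drop = FALSE]
    else if (nrow(Fm) != n) Fm <- Fm[sample_index, , drop = FALSE]
  }
  stopifnot(nrow(Fm) == n, ncol(Fm) == 3)
  Fm
}
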