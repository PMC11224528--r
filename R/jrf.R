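## Joint reaction forces and their compression/shear decomposition.

#' Joint reaction forces at one frame
#'
#' Quasi-static free-body balance: the force transmitted across a joint is
#' the sum of all external, gravitational and boundary-crossing muscle
#' forces acting on the distal free body. The glenohumeral (GH) reaction is
#' reported as the force the humeral head exerts on the glenoid, decomposed
#' in the scapular glenoid basis (compression positive from the humeral-head
#' center toward the glenoid center); the acromioclavicular (AC) reaction as
#' the force the scapula exerts on the clavicle, decomposed in the clavicle
#' basis (compression positive along the clavicle toward the sternum;
#' anterior and superior shear positive).
#'
#' @param model A `shoulder_model`.
#' @param q Coordinate vector.
#' @param activations Named (or ordered) activation vector in [0, 1].
#' @param F_hand Lab-frame external force on the hand center (3-vector).
#' @param frames Optional precomputed kinematics.
#' @param gravity Include segment weights.
#' @return List with `gh` and `ac`, each containing the lab-frame `force`
#'   and its `compression`, `shear_ap`, `shear_si`, `total`.
#' @export
joint_reaction <- function(model, q, activations, F_hand,
                           frames = NULL, gravity = TRUE) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  geo <- muscle_geometry(model, frames = frames)
  fmax <- vapply(model$muscles, `[[`, numeric(1), "fmax")
  fpass <- vapply(seq_along(model$muscles), function(i)
    passive_force(model$muscles[[i]], geo$lnorm[i],
                  model$passive$k1, model$passive$k2), numeric(1))
  tension <- activations * fmax + fpass
  maps <- reaction_maps(model, frames, F_hand, gravity = gravity)
  out <- list()
  for (jn in c("gh", "ac")) {
    Fj <- maps[[jn]]$F_const + as.vector(maps[[jn]]$U %*% tension)
    B <- if (jn == "gh") glenoid_basis(model, frames)
         else clavicle_basis(model, frames)
    out[[jn]] <- c(list(force = Fj), decompose_jrf(Fj, B))
  }
  out
}

#' Decompose a reaction force into compression and shear components
#'
#' Projects a lab-frame force vector onto an orthonormal joint basis whose
#' first column is the compression axis, second the anterior shear axis and
#' third the superior shear axis. The decomposition is an isometry:
#' `total^2 = compression^2 + shear_ap^2 + shear_si^2`.
#'
#' @param force 3-vector (N).
#' @param basis 3 x 3 matrix with orthonormal columns (axis, ap, si).
#' @return List: `compression`, `shear_ap`, `shear_si`, `total`.
#' @export
decompose_jrf <- function(force, basis) {
  if (max(abs(crossprod(basis) - diag(3))) > 1e-8) {
    stop("decompose_jrf: basis is not orthonormal")
  }
  v <- as.vector(t(basis) %*% force)
  list(compression = v[1], shear_ap = v[2], shear_si = v[3],
       total = vnorm(force))
}

#' Mediolateral hand-force direction sweep
#'
#' Re-solves a trial's muscle redundancy for a family of hand-force
#' directions: the vertical component is fixed and the mediolateral
#' component set to `fraction x vertical` (positive fractions laterally
#' directed, negative medially). Per fraction, cycle-mean reaction
#' components are reported per joint, with the total as the Euclidean norm
#' of the per-component means.
#'
#' @param model A `shoulder_model`.
#' @param posture A `posture_series` for the example trial.
#' @param fractions Numeric vector in [-0.5, 2] by default.
#' @param vertical_force Per-hand vertical force magnitude (N), default the
#'   16 kg barbell's per-hand share, 78.48 N.
#' @param options Solver options, see [rmr_solve()].
#' @return Data frame: fraction, joint, mean compression/shear components,
#'   `total` (norm of means), `feasible_frac`, `flagged`.
#' @export
force_direction_sweep <- function(model, posture, fractions = seq(-0.5, 2, by = 0.25),
                                  vertical_force = 78.48, options = list()) {
  if (any(fractions < -0.5 - 1e-9) || any(fractions > 2 + 1e-9)) {
    warning("force_direction_sweep: fractions outside [-0.5, 2]")
  }
  n <- nrow(posture$q)
  rows <- list()
  for (fr in fractions) {
    ## lateral exertion on the bar -> medial (-x) reaction on the right hand
    Fh <- cbind(rep(-fr * vertical_force, n), rep(-vertical_force, n), 0)
    sol <- rmr_solve(model, make_posture_series(posture$q, posture$time),
                     Fh, options = options)
    for (jn in c("gh", "ac")) {
      m <- colMeans(sol$jrf[[jn]][, c("compression", "shear_ap", "shear_si")])
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, joint = jn,
        compression = m[1], shear_ap = m[2], shear_si = m[3],
        total = sqrt(sum(m^2)),
        feasible_frac = mean(sol$feasible),
        flagged = sol$trial_flagged, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
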