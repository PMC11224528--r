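## Minimal-effort muscle redundancy solver with glenohumeral stability cone.

#' Solve one minimal-effort activation quadratic program
#'
#' Minimizes the sum of squared activations subject to linear moment
#' balance, activation bounds and (optionally) the glenohumeral stability
#' cone. The elliptical cone is enforced exactly up to a polyhedral
#' approximation by its supporting hyperplanes: for facet angles `phi`,
#' `cos(phi)/tan_ap * shear_ap + sin(phi)/tan_si * shear_si <= compression`.
#'
#' @param A_eq Constraint matrix (moments x activations): row j holds
#'   moment arm times maximal force per bundle.
#' @param b_eq Required net moments minus the passive-force contribution.
#' @param lb,ub Activation bounds (rate bounds already intersected with
#'   [0, 1]).
#' @param cone Optional list with `G` (3 x n map from activations to the
#'   reaction force in the glenoid basis: compression, anterior shear,
#'   superior shear), `r0` (activation-independent reaction), `tan_ap`,
#'   `tan_si`, `n_facets`.
#' @return List: `a`, `objective`, `feasible`, `residual` (moment-balance
#'   residual norm), `fallback` (solution from the minimum-violation
#'   problem).
#' @export
solve_activation_qp <- function(A_eq, b_eq, lb, ub, cone = NULL) {
  n <- ncol(A_eq)
  Ain <- NULL; bin <- NULL
  if (!is.null(cone)) {
    phi <- seq(0, 2 * pi, length.out = cone$n_facets + 1L)[-(cone$n_facets + 1L)]
    Np <- cbind(-1, cos(phi) / cone$tan_ap, sin(phi) / cone$tan_si)
    Ain <- Np %*% cone$G
    bin <- -as.vector(Np %*% cone$r0)
  }
  sol <- tryCatch(
    pracma::quadprog(diag(2, n), rep(0, n), A = Ain, b = bin,
                     Aeq = A_eq, beq = b_eq, lb = lb, ub = ub),
    error = function(e) NULL)
  tol_eq <- 1e-6 * (1 + max(abs(b_eq))) + 1e-9
  if (!is.null(sol)) {
    a <- pmin(pmax(sol$xmin, lb), ub)
    res <- vnorm(A_eq %*% a - b_eq)
    if (res <= tol_eq) {
      return(list(a = a, objective = sum(a^2), feasible = TRUE,
                  residual = res, fallback = FALSE))
    }
  }
  ## minimum-violation fallback: least-squares moment balance with a fixed
  ## effort weight (N m per unit activation), bounds (and cone, if still
  ## consistent) kept; the effort term stops near-singular violation
  ## minimizers from recruiting arbitrary co-contraction
  fb <- function(Ai, bi) {
    C <- 2 * (crossprod(A_eq) + diag(1, n))
    d <- -2 * as.vector(crossprod(A_eq, b_eq))
    tryCatch(pracma::quadprog(C, d, A = Ai, b = bi, lb = lb, ub = ub),
             error = function(e) NULL)
  }
  sol2 <- fb(Ain, bin)
  if (is.null(sol2)) sol2 <- fb(NULL, NULL)
  a <- if (is.null(sol2)) pmin(pmax(rep(0, n), lb), ub)
       else pmin(pmax(sol2$xmin, lb), ub)
  list(a = a, objective = sum(a^2), feasible = FALSE,
       residual = vnorm(A_eq %*% a - b_eq), fallback = TRUE)
}

## glenoid basis (columns: compression axis, anterior shear, superior shear)
glenoid_basis <- function(model, frames) {
  sc <- model$segments$scapula$points
  u <- unitv(as.vector(frames$R$scapula %*% (sc$glenoid_center - sc$gh_center)))
  y <- frames$R$scapula[, 2]
  a <- unitv(y - sum(y * u) * u)
  z <- frames$R$scapula[, 3]
  s <- unitv(z - sum(z * u) * u - sum(z * a) * a)
  cbind(axis = u, ap = a, si = s)
}

## clavicle basis at the AC joint: compression along the clavicle long axis
## pointing from AC toward SC (medially)
clavicle_basis <- function(model, frames) {
  u <- -frames$R$clavicle[, 1]
  a <- frames$R$clavicle[, 2]
  s <- frames$R$clavicle[, 3]
  cbind(axis = u, ap = a, si = s)
}

## net force (lab) applied by one muscle per unit tension to the free body
## consisting of `segments_in`
muscle_force_on_subtree <- function(P, path_segments, segments_in) {
  f <- path_point_forces(P)
  out <- c(0, 0, 0)
  for (k in seq_len(nrow(P))) {
    if (path_segments[k] %in% segments_in) out <- out + f[k, ]
  }
  out
}

## activation-independent and per-unit-activation reaction maps at a frame
reaction_maps <- function(model, frames, F_hand, gravity = TRUE) {
  joints <- list(gh = c("humerus", "forearm"),
                 ac = c("scapula", "humerus", "forearm"))
  mus <- model$muscles
  nm <- length(mus)
  paths <- lapply(names(mus), function(nm_) muscle_path_lab(model, frames, nm_))
  psegs <- lapply(mus, function(m) vapply(m$path, `[[`, character(1), "segment"))
  out <- list()
  for (jn in names(joints)) {
    segs_in <- joints[[jn]]
    Fc <- F_hand
    if (gravity) {
      for (sn in segs_in) {
        Fc <- Fc + c(0, -model$segments[[sn]]$mass * GRAVITY, 0)
      }
    }
    U <- matrix(0, 3, nm, dimnames = list(NULL, names(mus)))
    for (i in seq_len(nm)) {
      U[, i] <- muscle_force_on_subtree(paths[[i]], psegs[[i]], segs_in)
    }
    out[[jn]] <- list(F_const = Fc, U = U)
  }
  out
}

#' Solve activations for a single frame
#'
#' Builds the moment-balance and stability-cone constraints at the given
#' posture and calls [solve_activation_qp()].
#'
#' @param model A `shoulder_model`.
#' @param q Coordinate vector.
#' @param M Named net-moment vector over the model coordinates (N m);
#'   only `model$solver_dofs` are balanced.
#' @param F_hand Lab-frame external force on the hand center (3-vector),
#'   needed for the stability constraint and reported reactions.
#' @param a_prev Previous-frame activations (rate coupling), or `NULL`.
#' @param dt Time step to the previous frame (s).
#' @param options List: `stability` (default TRUE), `rate_bounds` (TRUE),
#'   `gravity` (TRUE).
#' @return List with activations `a`, `objective`, `feasible`, `residual`,
#'   `theta` (angle of the GH reaction to the glenoid axis, rad),
#'   `theta_max_dir` (admissible angle in that direction).
#' @export
solve_frame <- function(model, q, M, F_hand = c(0, 0, 0), a_prev = NULL,
                        dt = NULL, options = list()) {
  opt <- utils::modifyList(list(stability = TRUE, rate_bounds = TRUE,
                                gravity = TRUE), options)
  frames <- forward_kinematics(model, q)
  geo <- muscle_geometry(model, frames = frames)
  fmax <- vapply(model$muscles, `[[`, numeric(1), "fmax")
  fpass <- vapply(seq_along(model$muscles), function(i)
    passive_force(model$muscles[[i]], geo$lnorm[i],
                  model$passive$k1, model$passive$k2), numeric(1))
  sdofs <- model$solver_dofs
  Rm <- geo$moment_arm[, sdofs, drop = FALSE]
  A_eq <- t(Rm * fmax)                       # moments x muscles
  b_eq <- M[sdofs] - as.vector(t(Rm) %*% fpass)

  n <- length(fmax)
  lb <- rep(0, n); ub <- rep(1, n)
  if (opt$rate_bounds && !is.null(a_prev) && !is.null(dt)) {
    tau <- model$activation_dynamics
    lb <- pmax(lb, a_prev - dt / tau$tau_deact)
    ub <- pmin(ub, a_prev + dt / tau$tau_act)
  }

  maps <- reaction_maps(model, frames, F_hand, gravity = opt$gravity)
  B <- glenoid_basis(model, frames)
  r0 <- as.vector(t(B) %*% (maps$gh$F_const + maps$gh$U %*% fpass))
  G <- t(B) %*% sweep(maps$gh$U, 2, fmax, `*`)
  cone <- if (opt$stability) {
    list(G = G, r0 = r0, tan_ap = model$stability$tan_ap,
         tan_si = model$stability$tan_si, n_facets = model$stability$n_facets)
  } else NULL

  sol <- solve_activation_qp(A_eq, b_eq, lb, ub, cone)
  rx <- r0 + as.vector(G %*% sol$a)
  sh <- sqrt(rx[2]^2 + rx[3]^2)
  theta <- atan2(sh, rx[1])
  phi_dir <- atan2(rx[3], rx[2])
  tmax <- atan(1 / sqrt((cos(phi_dir) / model$stability$tan_ap)^2 +
                          (sin(phi_dir) / model$stability$tan_si)^2))
  ## reaction decompositions from the maps already in hand
  tension <- sol$a * fmax + fpass
  Bc <- clavicle_basis(model, frames)
  jr <- list(
    gh = c(compression = rx[1], shear_ap = rx[2], shear_si = rx[3],
           total = vnorm(rx)),
    ac = {
      Fac <- maps$ac$F_const + as.vector(maps$ac$U %*% tension)
      v <- as.vector(t(Bc) %*% Fac)
      c(compression = v[1], shear_ap = v[2], shear_si = v[3],
        total = vnorm(Fac))
    })
  c(sol, list(theta = theta, theta_max_dir = tmax,
              reaction_glenoid = rx, jr = jr, frames = frames,
              fpass = fpass))
}

#' Fit minimal-effort activations over a trial
#'
#' Runs the per-frame redundancy solver in time order with warm starts and
#' activation-rate coupling between consecutive frames, then assembles the
#' glenohumeral and acromioclavicular reaction series.
#'
#' @param model A `shoulder_model` (scaled to the subject).
#' @param posture A `posture_series` from [inverse_kinematics()].
#' @param hand_force A `hand_force_series` or n x 3 force-on-hand matrix
#'   (full-rate; subset by the posture's `sample_index`).
#' @param options Passed to [solve_frame()]; additionally `max_infeasible`
#'   (fraction of infeasible frames above which the trial is flagged,
#'   default 0.1) and `quasi_static` for the inverse dynamics.
#' @return An object of class `rmr_solution`.
#' @export
rmr_solve <- function(model, posture, hand_force, options = list()) {
  opt <- utils::modifyList(list(stability = TRUE, rate_bounds = TRUE,
                                gravity = TRUE, max_infeasible = 0.1,
                                quasi_static = TRUE), options)
  Fh <- hand_force_matrix(hand_force, nrow(posture$q), posture$sample_index)
  M <- inverse_dynamics(model, posture, Fh, gravity = opt$gravity,
                        quasi_static = opt$quasi_static)
  n <- nrow(posture$q)
  nm <- length(model$muscles)
  act <- matrix(0, n, nm, dimnames = list(NULL, names(model$muscles)))
  feas <- logical(n); objv <- numeric(n); theta <- numeric(n)
  resid <- numeric(n)
  jrf <- list(gh = matrix(0, n, 4), ac = matrix(0, n, 4))
  colnames(jrf$gh) <- colnames(jrf$ac) <-
    c("compression", "shear_ap", "shear_si", "total")
  a_prev <- NULL
  for (i in seq_len(n)) {
    dt <- if (i > 1) posture$time[i] - posture$time[i - 1] else NULL
    fs <- solve_frame(model, posture$q[i, ], M[i, ], Fh[i, ],
                      a_prev = a_prev, dt = dt, options = opt)
    act[i, ] <- fs$a
    feas[i] <- fs$feasible; objv[i] <- fs$objective
    theta[i] <- fs$theta; resid[i] <- fs$residual
    jrf$gh[i, ] <- fs$jr$gh
    jrf$ac[i, ] <- fs$jr$ac
    a_prev <- fs$a
  }
  structure(list(activations = act, feasible = feas, objective = objv,
                 theta = theta, residual = resid, jrf = jrf,
                 moments = M, time = posture$time,
                 sample_index = posture$sample_index,
                 trial_flagged = mean(!feas) > opt$max_infeasible,
                 options = opt, muscle_groups =
                   vapply(model$muscles, `[[`, character(1), "group")),
            class = "rmr_solution")
}

#' @export
print.rmr_solution <- function(x, ...) {
  cat("Muscle redundancy solution:", nrow(x$activations), "frames,",
      ncol(x$activations), "bundles\n")
  cat(sprintf("  feasible frames: %d/%d%s\n", sum(x$feasible),
              length(x$feasible),
              if (x$trial_flagged) "  [TRIAL FLAGGED]" else ""))
  cat(sprintf("  peak GH reaction: %.0f N; peak AC reaction: %.0f N\n",
              max(x$jrf$gh[, "total"]), max(x$jrf$ac[, "total"])))
  invisible(x)
}

#' @export
summary.rmr_solution <- function(object, ...) {
  pk <- apply(object$activations, 2, max)
  out <- data.frame(bundle = names(pk), group = object$muscle_groups,
                    peak_activation = unname(pk), row.names = NULL)
  class(out) <- c("summary.rmr_solution", "data.frame")
  out
}

#' @export
coef.rmr_solution <- function(object, ...) object$activations

#' @export
plot.rmr_solution <- function(x, which = c("activations", "jrf"), ...) {
  which <- match.arg(which)
  tt <- x$time
  if (which == "activations") {
    grp <- x$muscle_groups
    sel <- names(grp)[grp %in% c("rotator_cuff", "pectoralis")]
    graphics::matplot(tt, x$activations[, sel], type = "l", lty = 1,
                      xlab = "time (s)", ylab = "activation", ...)
    graphics::legend("topleft", legend = sel, col = seq_along(sel),
                     lty = 1, cex = 0.6, bty = "n")
  } else {
    graphics::matplot(tt, cbind(x$jrf$gh[, "total"], x$jrf$ac[, "total"]),
                      type = "l", lty = 1, xlab = "time (s)",
                      ylab = "joint reaction force (N)", ...)
    graphics::legend("topleft", legend = c("GH", "AC"), col = 1:2, lty = 1,
                     bty = "n")
  }
  invisible(x)
}
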