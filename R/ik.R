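#' Inverse kinematics by damped Gauss-Newton
#'
#' Per frame, finds the coordinate vector minimizing the weighted sum of
#' squared distances between experimental markers and the model's virtual
#' markers. The Jacobian is analytic (rigid-body velocity identities), each
#' frame is warm-started from the previous solution, and coordinates are
#' clamped to their configured ranges.
#'
#' @param model A `shoulder_model`.
#' @param markers Marker series: list with `time` (length n) and `data`
#'   (named list of n x 3 matrices, NA for missing samples).
#' @param weights Named tracking weights; defaults to the model's.
#' @param q0 Starting posture for the first frame (named values or full
#'   vector); defaults to the model reference posture.
#' @param stride Solve every `stride`-th frame (>= 1).
#' @param max_iter,tol Gauss-Newton iteration cap and step tolerance.
#' @param flag_rms Residual RMS (m) above which a frame is flagged.
#' @return A `posture_series`: coordinates `q` (frames x nq), velocities and
#'   accelerations by central differences, per-frame residual RMS and flags.
#' @export
inverse_kinematics <- function(model, markers, weights = NULL, q0 = NULL,
                               stride = 1L, max_iter = 30L, tol = 1e-9,
                               flag_rms = 0.03) {
  weights <- weights %||% model$marker_weights
  tracked <- names(weights)[weights > 0]
  tracked <- intersect(tracked, intersect(names(model$markers), names(markers$data)))
  if (length(tracked) < 4) stop("inverse_kinematics: fewer than 4 tracked markers")
  span <- segment_dof_span(model)
  seg_of <- vapply(model$markers[tracked], `[[`, character(1), "segment")
  w <- sqrt(weights[tracked])

  n <- length(markers$time)
  idx <- seq(1L, n, by = as.integer(stride))
  nq <- model$nq
  lo <- model$dof_table$lo; hi <- model$dof_table$hi
  qmat <- matrix(NA_real_, length(idx), nq,
                 dimnames = list(NULL, model$dof_table$name))
  rms <- numeric(length(idx)); flagged <- logical(length(idx))

  q <- if (is.null(q0)) posture_vector(model, model$reference_posture)
       else posture_vector(model, q0)

  obs <- lapply(tracked, function(mn) markers$data[[mn]])
  names(obs) <- tracked

  for (fi in seq_along(idx)) {
    t_i <- idx[fi]
    tgt <- lapply(obs, function(o) o[t_i, ])
    ok <- vapply(tgt, function(v) all(is.finite(v)), logical(1))
    use <- tracked[ok]
    if (length(use) < 4) {
      flagged[fi] <- TRUE; rms[fi] <- NA_real_; qmat[fi, ] <- q
      next
    }
    lambda <- 1e-8
    for (it in seq_len(max_iter)) {
      fr <- forward_kinematics(model, q)
      m_res <- matrix(0, 3 * length(use), 1)
      J <- matrix(0, 3 * length(use), nq)
      for (mi in seq_along(use)) {
        mn <- use[mi]
        p <- fk_point(fr, seg_of[mn], model$markers[[mn]]$point)
        rows <- (3 * mi - 2):(3 * mi)
        m_res[rows, 1] <- w[mn] * (p - tgt[[mn]])
        for (j in span[[seg_of[mn]]]) {
          J[rows, j] <- w[mn] * cross3(fr$dof_axis[, j], p - fr$dof_center[, j])
        }
      }
      H <- crossprod(J) + diag(lambda, nq)
      g <- crossprod(J, m_res)
      dq <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(dq)) { lambda <- lambda * 100; next }
      q_new <- pmin(pmax(q + as.vector(dq), lo), hi)
      if (max(abs(q_new - q)) < tol) { q <- q_new; break }
      q <- q_new
    }
    fr <- forward_kinematics(model, q)
    res2 <- 0
    for (mn in use) {
      p <- fk_point(fr, seg_of[mn], model$markers[[mn]]$point)
      res2 <- res2 + sum((p - tgt[[mn]])^2)
    }
    rms[fi] <- sqrt(res2 / (3 * length(use)))
    flagged[fi] <- !is.finite(rms[fi]) || rms[fi] > flag_rms
    qmat[fi, ] <- q
  }

  make_posture_series(qmat, markers$time[idx], sample_index = idx,
                      residual_rms = rms, flagged = flagged)
}

#' Construct a posture series
#'
#' Velocities and accelerations are computed by central differences.
#' @param q Frames x nq coordinate matrix.
#' @param time Frame timestamps (s).
#' @param sample_index Optional indices into the originating full-rate
#'   recording (used for cycle normalization after strided solves).
#' @param residual_rms,flagged Optional per-frame diagnostics.
#' @export
make_posture_series <- function(q, time, sample_index = seq_len(nrow(q)),
                                residual_rms = NULL, flagged = NULL) {
  n <- nrow(q)
  qd <- matrix(0, n, ncol(q), dimnames = dimnames(q))
  qdd <- qd
  if (n >= 3) {
    dt <- diff(time)
    for (i in 2:(n - 1)) {
      h <- time[i + 1] - time[i - 1]
      qd[i, ] <- (q[i + 1, ] - q[i - 1, ]) / h
      qdd[i, ] <- 4 * (q[i + 1, ] - 2 * q[i, ] + q[i - 1, ]) / h^2
    }
    qd[1, ] <- (q[2, ] - q[1, ]) / dt[1]
    qd[n, ] <- (q[n, ] - q[n - 1, ]) / dt[n - 1]
  }
  structure(list(q = q, qd = qd, qdd = qdd, time = time,
                 sample_index = sample_index,
                 residual_rms = residual_rms %||% rep(NA_real_, n),
                 flagged = flagged %||% rep(FALSE, n)),
            class = "posture_series")
}

#' @export
print.posture_series <- function(x, ...) {
  cat("Posture series:", nrow(x$q), "frames,", ncol(x$q), "coordinates\n")
  if (any(is.finite(x$residual_rms))) {
    cat(sprintf("  marker residual RMS: median %.2f mm, max %.2f mm\n",
                1000 * stats::median(x$residual_rms, na.rm = TRUE),
                1000 * max(x$residual_rms, na.rm = TRUE)))
  }
  if (any(x$flagged)) cat("  flagged frames:", sum(x$flagged), "\n")
  invisible(x)
}
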