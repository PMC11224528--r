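## Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_subject <- function() {
  if (is.null(.fx$subject)) {
    .fx$subject <- generate_subject(1, overrides = list(height = 1.80,
                                                        mass = 85,
                                                        biacromial_width = 0.39))
  }
  .fx$subject
}

fx_model <- function() {
  if (is.null(.fx$model)) .fx$model <- subject_model(fx_subject())
  .fx$model
}

fx_generic <- function() {
  if (is.null(.fx$generic)) .fx$generic <- load_model()
  .fx$generic
}

## one clean, noise-free mid-grid trial reused across files
fx_clean_trial <- function() {
  if (is.null(.fx$clean)) {
    grid <- technique_grid()
    cond <- grid[grid$id == "g1.5_a70_neutral", ]
    trial <- simulate_trial(fx_subject(), cond, n_reps = 2,
                            noise = list(marker_sd = 0, force_noise_sd = 0,
                                         lateral_frac = 0.3),
                            seed = 7)
    calib <- generate_scapula_calibration(fx_subject())
    .fx$trial <- trial
    .fx$clean <- preprocess_trial(trial, calib)
  }
  .fx$clean
}

fx_raw_trial <- function() {
  fx_clean_trial()
  .fx$trial
}

fx_posture <- function(stride = 10) {
  key <- paste0("pos", stride)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- inverse_kinematics(fx_model(), fx_clean_trial()$markers,
                                     stride = stride)
  }
  .fx[[key]]
}

## exhaustive search over the feasible set of a toy activation problem with
## more muscles than equality constraints: the last (n - m) activations are
## enumerated on a grid, the first m solved from the equalities, candidates
## filtered on bounds and (optionally) the stability cone. Independent of
## the QP path.
grid_search_oracle <- function(A_eq, b_eq, cone = NULL, step = 1e-3,
                               lb = NULL, ub = NULL) {
  n <- ncol(A_eq); m <- nrow(A_eq)
  lb <- lb %||% rep(0, n); ub <- ub %||% rep(1, n)
  stopifnot(n - m >= 1, n - m <= 2)
  Ahead <- A_eq[, 1:m, drop = FALSE]
  free_grid <- lapply((m + 1):n, function(j) seq(lb[j], ub[j], by = step))
  best <- NULL; best_obj <- Inf
  cone_ok <- function(a) {
    if (is.null(cone)) return(TRUE)
    r <- cone$r0 + as.vector(cone$G %*% a)
    sqrt((r[2] / cone$tan_ap)^2 + (r[3] / cone$tan_si)^2) <= r[1] + 1e-9
  }
  if (n - m == 1) {
    for (x in free_grid[[1]]) {
      head <- solve(Ahead, b_eq - A_eq[, n] * x)
      a <- c(head, x)
      if (all(a >= lb - 1e-12) && all(a <= ub + 1e-12) && cone_ok(a)) {
        o <- sum(a^2)
        if (o < best_obj) { best_obj <- o; best <- a }
      }
    }
  } else {
    for (x in free_grid[[1]]) for (y in free_grid[[2]]) {
      head <- solve(Ahead, b_eq - A_eq[, n - 1] * x - A_eq[, n] * y)
      a <- c(head, x, y)
      if (all(a >= lb - 1e-12) && all(a <= ub + 1e-12) && cone_ok(a)) {
        o <- sum(a^2)
        if (o < best_obj) { best_obj <- o; best <- a }
      }
    }
  }
  list(a = best, objective = best_obj)
}

## independent rotation matrix for oracle constructions in tests
rot_z_test <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

## smooth (low-pass filtered) unit-variance noise continuums
smooth_noise <- function(n_subj, n_nodes = 101) {
  B <- matrix(stats::rnorm(n_subj * (n_nodes + 20)), n_subj)
  k <- stats::dnorm(seq(-2, 2, length.out = 9)); k <- k / sum(k)
  B <- t(apply(B, 1, function(x) stats::filter(x, k, sides = 2)))
  B <- B[, 11:(10 + n_nodes), drop = FALSE]
  B / stats::sd(as.vector(B))
}
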