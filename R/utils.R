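#' @keywords internal
"_PACKAGE"

## Small geometry / validation helpers shared across modules.
## Lab frame convention (subject supine on the bench):
##   x: subject's right (mediolateral, lateral positive for the right arm)
##   y: vertical up (the subject's anterior direction when supine)
##   z: toward the subject's head (superior)

rot_x <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3)
}

rot_y <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}

rot_z <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

rot_axis <- function(axis, a) {
  switch(axis, x = rot_x(a), y = rot_y(a), z = rot_z(a),
         stop("unknown rotation axis: ", axis))
}

unit_axis <- function(axis) {
  switch(axis,
         x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         stop("unknown rotation axis: ", axis))
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Right-handed orthonormal frame from an origin and two spanning directions:
## x along u, z along the component of (u x v), y completing the triad.
frame_from_points <- function(origin, p_x, p_other) {
  ex <- unitv(p_x - origin)
  w <- (p_other - origin)
  ez <- unitv(cross3(ex, w))
  ey <- cross3(ez, ex)
  list(origin = origin, R = cbind(ex, ey, ez, deparse.level = 0))
}

## Kabsch rigid alignment: rotation + translation mapping point set A onto B
## (rows are points). Least-squares optimal, reflection-free.
rigid_transform <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), nrow(A) >= 3)
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cb - as.vector(R %*% ca))
}

apply_rigid <- function(tr, P) {
  sweep(P %*% t(tr$R), 2, tr$t, `+`)
}

## deterministic child seed derived from a base seed and a stream label;
## kept below 2^31 - 1
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_range <- function(value, lo, hi, field) {
  if (!is.finite(value) || value <= lo || value >= hi) {
    stop(sprintf("field '%s' = %g outside admissible range (%g, %g)",
                 field, value, lo, hi), call. = FALSE)
  }
  invisible(value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## standard gravity used throughout (m/s^2)
GRAVITY <- 9.81
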