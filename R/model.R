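#' Load the reduced shoulder-girdle model
#'
#' Reads a model parameter file (YAML) describing the thorax--clavicle--
#' scapula--humerus--forearm chain, its virtual markers, aggregate muscle
#' bundles and the glenohumeral stability cone, validates it, and returns a
#' ready-to-use model object. Muscle optimal path lengths given as null in
#' the file are calibrated at the reference posture.
#'
#' @param config Path to a model YAML file. Defaults to the generic model
#'   shipped with the package.
#' @return An object of class `shoulder_model`.
#' @export
load_model <- function(config = default_model_file()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  build_model(cfg)
}

#' @rdname load_model
#' @export
default_model_file <- function() {
  system.file("extdata", "default_model.yaml", package = "bpshoulder",
              mustWork = TRUE)
}

#' Save a model back to YAML
#'
#' @param model A `shoulder_model`.
#' @param path Output file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "shoulder_model"))
  yaml::write_yaml(model$config, path, precision = 12L)
  invisible(path)
}

segment_order <- c("thorax", "clavicle", "scapula", "humerus", "forearm")

build_model <- function(cfg) {
  validate_model_config(cfg)
  segs <- lapply(cfg$segments, function(s) {
    ## guard against YAML 1.1 implicit booleans for bare y/n axis letters
    s$dofs <- lapply(s$dofs, function(d) {
      if (is.logical(d$axis)) d$axis <- if (isTRUE(d$axis)) "y" else "n"
      d
    })
    s$com <- as.numeric(s$com)
    if (!is.null(s$joint_location)) s$joint_location <- as.numeric(s$joint_location)
    s$markers <- lapply(s$markers, as.numeric)
    s$landmarks <- lapply(s$landmarks, as.numeric)
    s$points <- lapply(s$points, as.numeric)
    s
  })
  segs <- segs[segment_order]

  dof_rows <- list()
  for (sn in segment_order) {
    for (d in segs[[sn]]$dofs) {
      dof_rows[[length(dof_rows) + 1L]] <- data.frame(
        name = d$name, segment = sn, axis = d$axis, sign = as.numeric(d$sign),
        lo = d$range[[1]], hi = d$range[[2]], stringsAsFactors = FALSE)
    }
  }
  dof_table <- do.call(rbind, dof_rows)

  markers <- list()
  for (sn in segment_order) {
    for (mn in names(segs[[sn]]$markers)) {
      markers[[mn]] <- list(segment = sn, point = segs[[sn]]$markers[[mn]])
    }
    for (mn in names(segs[[sn]]$landmarks)) {
      markers[[mn]] <- list(segment = sn, point = segs[[sn]]$landmarks[[mn]])
    }
  }
  for (mn in names(cfg$left_markers)) {
    markers[[mn]] <- list(segment = "thorax",
                          point = as.numeric(cfg$left_markers[[mn]]))
  }
  weights <- vapply(cfg$marker_weights, as.numeric, numeric(1))

  muscles <- lapply(cfg$muscles, function(m) {
    m$fmax <- as.numeric(m$fmax)
    m$slack <- as.numeric(m$slack)
    m$path <- lapply(m$path, function(p)
      list(segment = p$segment, point = as.numeric(p$point)))
    m
  })
  names(muscles) <- vapply(muscles, `[[`, character(1), "name")

  depth <- vnorm(segs$scapula$points$glenoid_center - segs$scapula$points$gh_center)
  stability <- list(
    tan_ap = as.numeric(cfg$stability$ap_radius) / depth,
    tan_si = as.numeric(cfg$stability$si_radius) / depth,
    n_facets = as.integer(cfg$stability$n_facets %||% 48L))

  model <- structure(list(
    config = cfg,
    name = cfg$name,
    segments = segs,
    dof_table = dof_table,
    nq = nrow(dof_table),
    markers = markers,
    marker_weights = weights,
    muscles = muscles,
    passive = list(k1 = as.numeric(cfg$passive$k1),
                   k2 = as.numeric(cfg$passive$k2)),
    stability = stability,
    activation_dynamics = lapply(cfg$activation_dynamics, as.numeric),
    solver_dofs = unlist(cfg$solver_dofs),
    generic_height = as.numeric(cfg$generic_height),
    generic_mass = as.numeric(cfg$generic_mass),
    generic_baw = as.numeric(cfg$generic_biacromial_width),
    reference_posture = vapply(cfg$reference_posture, as.numeric, numeric(1))
  ), class = "shoulder_model")

  ## calibrate optimal path lengths at the reference posture
  qref <- posture_vector(model, model$reference_posture)
  fr <- forward_kinematics(model, qref)
  for (i in seq_along(model$muscles)) {
    if (is.null(model$muscles[[i]]$lopt)) {
      model$muscles[[i]]$lopt <- muscle_path_length(model, fr, names(model$muscles)[i])
    } else {
      model$muscles[[i]]$lopt <- as.numeric(model$muscles[[i]]$lopt)
    }
  }
  model
}

validate_model_config <- function(cfg) {
  need <- c("segments", "muscles", "stability", "marker_weights",
            "reference_posture", "solver_dofs")
  for (f in need) {
    if (is.null(cfg[[f]])) stop("model config: missing field '", f, "'")
  }
  if (!setequal(names(cfg$segments), segment_order)) {
    stop("model config: segments must be exactly {",
         paste(segment_order, collapse = ", "), "}")
  }
  for (sn in names(cfg$segments)) {
    s <- cfg$segments[[sn]]
    if (is.null(s$mass) || as.numeric(s$mass) <= 0) {
      stop("model config: segment '", sn, "' has non-positive mass")
    }
    if (sn != "thorax" && is.null(s$joint_location)) {
      stop("model config: segment '", sn, "' missing field 'joint_location'")
    }
  }
  groups <- vapply(cfg$muscles, `[[`, character(1), "group")
  mnames <- vapply(cfg$muscles, `[[`, character(1), "name")
  if (anyDuplicated(mnames)) stop("model config: duplicate muscle names")
  cuff_req <- c("supraspinatus_ant", "supraspinatus_post", "infraspinatus",
                "subscapularis", "teres_minor")
  if (!all(cuff_req %in% mnames[groups == "rotator_cuff"])) {
    stop("model config: rotator_cuff group must include ",
         paste(cuff_req, collapse = ", "))
  }
  if (!all(c("pect_clavicular", "pect_sternal") %in% mnames[groups == "pectoralis"])) {
    stop("model config: pectoralis group must include pect_clavicular, pect_sternal")
  }
  for (m in cfg$muscles) {
    if (as.numeric(m$fmax) <= 0) stop("model config: muscle '", m$name, "': fmax must be > 0")
    if (length(m$path) < 2) stop("model config: muscle '", m$name, "': path needs >= 2 points")
  }
  invisible(TRUE)
}

#' @export
print.shoulder_model <- function(x, ...) {
  cat("Reduced shoulder-girdle model:", x$name, "\n")
  cat("  segments:", paste(segment_order, collapse = " -> "), "\n")
  cat("  coordinates:", x$nq, "(", paste(x$dof_table$name, collapse = ", "), ")\n")
  cat("  muscle bundles:", length(x$muscles), "\n")
  cat(sprintf("  stability cone half-angles: %.1f deg (AP), %.1f deg (SI)\n",
              atan(x$stability$tan_ap) * 180 / pi,
              atan(x$stability$tan_si) * 180 / pi))
  invisible(x)
}

#' Build a full coordinate vector from named values
#'
#' Missing coordinates default to 0.
#' @param model A `shoulder_model`.
#' @param values Named numeric vector or list of coordinate values (rad).
#' @export
posture_vector <- function(model, values = NULL) {
  q <- stats::setNames(numeric(model$nq), model$dof_table$name)
  if (!is.null(values)) {
    values <- unlist(values)
    unknown <- setdiff(names(values), names(q))
    if (length(unknown)) stop("unknown coordinate(s): ", paste(unknown, collapse = ", "))
    q[names(values)] <- values
  }
  q
}

#' Forward kinematics
#'
#' Computes lab-frame pose of every segment at coordinate vector `q`,
#' together with the lab-frame axis and center of every rotational
#' coordinate (used by the analytic inverse-kinematics Jacobian and the
#' tendon-excursion moment arms).
#'
#' @param model A `shoulder_model`.
#' @param q Numeric coordinate vector (length `model$nq`, radians), in
#'   `model$dof_table` order.
#' @return List with `R` / `origin` per segment and per-coordinate `axis` /
#'   `center` matrices.
#' @export
forward_kinematics <- function(model, q) {
  segs <- model$segments
  R <- list(); o <- list()
  nq <- model$nq
  dof_axis <- matrix(0, 3, nq)
  dof_center <- matrix(0, 3, nq)
  k <- 0L
  for (sn in segment_order) {
    s <- segs[[sn]]
    if (is.null(s$parent)) {
      Rs <- diag(3); os <- c(0, 0, 0)
    } else {
      Rp <- R[[s$parent]]; op <- o[[s$parent]]
      os <- op + as.vector(Rp %*% s$joint_location)
      Rs <- Rp
      for (d in s$dofs) {
        k <- k + 1L
        dof_axis[, k] <- as.vector(Rs %*% (as.numeric(d$sign) * unit_axis(d$axis)))
        dof_center[, k] <- os
        Rs <- Rs %*% rot_axis(d$axis, as.numeric(d$sign) * q[k])
      }
    }
    R[[sn]] <- Rs; o[[sn]] <- os
  }
  list(R = R, origin = o, dof_axis = dof_axis, dof_center = dof_center)
}

## lab position of a segment-local point
fk_point <- function(frames, segment, point) {
  frames$origin[[segment]] + as.vector(frames$R[[segment]] %*% point)
}

#' Virtual marker positions at a posture
#'
#' @param model A `shoulder_model`.
#' @param q Coordinate vector, or `NULL` to pass precomputed `frames`.
#' @param frames Optional output of [forward_kinematics()].
#' @return Matrix (markers x 3) of lab coordinates.
#' @export
model_markers <- function(model, q = NULL, frames = NULL) {
  if (is.null(frames)) frames <- forward_kinematics(model, q)
  out <- t(vapply(model$markers, function(m)
    fk_point(frames, m$segment, m$point), numeric(3)))
  rownames(out) <- names(model$markers)
  out
}

## index of the first coordinate belonging to each segment; a path point on
## segment s moves with coordinates 1..dof_end[s]
segment_dof_span <- function(model) {
  idx <- integer(0)
  out <- list()
  k <- 0L
  for (sn in segment_order) {
    nd <- length(model$segments[[sn]]$dofs)
    out[[sn]] <- if (nd + k == 0L) integer(0) else seq_len(k + nd)
    k <- k + nd
  }
  out
}

muscle_path_lab <- function(model, frames, name) {
  m <- model$muscles[[name]]
  t(vapply(m$path, function(p) fk_point(frames, p$segment, p$point), numeric(3)))
}

muscle_path_length <- function(model, frames, name) {
  P <- muscle_path_lab(model, frames, name)
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Scale the generic model to a subject
#'
#' Per-segment scale factors are the ratio of measured to generic landmark
#' distances at the static posture; geometry (joint locations, markers,
#' muscle attachments, centers of mass) scales linearly, segment masses by
#' the ratio of subject to generic body mass. Optimal muscle path lengths
#' are recalibrated on the scaled geometry.
#'
#' @param model A `shoulder_model` (generic).
#' @param anthro A `subject_anthropometry` object (see [generate_subject()]).
#' @param static_markers Named list (or matrix with row names) of 3D marker
#'   positions from a static trial; must include each segment's scale pair.
#' @return A scaled `shoulder_model`.
#' @export
scale_model <- function(model, anthro, static_markers) {
  if (is.matrix(static_markers)) {
    static_markers <- stats::setNames(
      lapply(seq_len(nrow(static_markers)), function(i) static_markers[i, ]),
      rownames(static_markers))
  }
  qref <- posture_vector(model, model$reference_posture)
  fr <- forward_kinematics(model, qref)
  mk <- model_markers(model, frames = fr)

  factors <- stats::setNames(numeric(length(segment_order)), segment_order)
  for (sn in segment_order) {
    pair <- unlist(model$segments[[sn]]$scale_pair)
    for (p in pair) {
      if (is.null(static_markers[[p]])) {
        stop("scale_model: static markers missing landmark '", p,
             "' needed to scale segment '", sn, "'")
      }
    }
    generic_d <- vnorm(mk[pair[1], ] - mk[pair[2], ])
    measured_d <- vnorm(static_markers[[pair[1]]] - static_markers[[pair[2]]])
    factors[sn] <- measured_d / generic_d
  }
  scale_model_by_factors(model, factors, mass_scale = anthro$mass / model$generic_mass)
}

## direct geometric scaling; exported for the synthetic generator which
## derives factors from anthropometry instead of a static trial
#' @rdname scale_model
#' @param factors Named per-segment scale factors.
#' @param mass_scale Multiplier applied to all segment masses.
#' @export
scale_model_by_factors <- function(model, factors, mass_scale = 1) {
  cfg <- model$config
  for (sn in segment_order) {
    f <- factors[[sn]]
    s <- cfg$segments[[sn]]
    s$com <- as.numeric(s$com) * f
    s$mass <- as.numeric(s$mass) * mass_scale
    if (!is.null(s$joint_location)) {
      fp <- factors[[s$parent]]
      s$joint_location <- as.numeric(s$joint_location) * fp
    }
    s$markers <- lapply(s$markers, function(p) as.numeric(p) * f)
    s$landmarks <- lapply(s$landmarks, function(p) as.numeric(p) * f)
    s$points <- lapply(s$points, function(p) as.numeric(p) * f)
    cfg$segments[[sn]] <- s
  }
  for (i in seq_along(cfg$muscles)) {
    cfg$muscles[[i]]$lopt <- NULL  # recalibrate on scaled geometry
    cfg$muscles[[i]]$path <- lapply(cfg$muscles[[i]]$path, function(p) {
      p$point <- as.numeric(p$point) * factors[[p$segment]]
      p
    })
  }
  m <- build_model(cfg)
  m$scale_factors <- factors
  m
}
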