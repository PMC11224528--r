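## End-to-end orchestration: simulate -> preprocess -> scale + IK ->
## redundancy solve -> joint reactions -> cycle-normalized statistics.

#' Default pipeline configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param n_subjects Cohort size (default 3 for the demo run).
#' @param n_reps Repetitions per condition (default 2 in the demo; the
#'   recording protocol uses 3).
#' @param out_dir Output directory (NULL: nothing written).
#' @param ik_stride Solve kinematics/activations every `ik_stride`-th
#'   100 Hz frame (default 10, i.e. an effective 10 Hz analysis grid for
#'   the 6 Hz low-passed signals).
#' @param ... Further entries overriding the defaults.
#' @return Named configuration list.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 3, n_reps = 2,
                            out_dir = NULL, ik_stride = 10, ...) {
  utils::modifyList(list(
    seed = seed, n_subjects = n_subjects, n_reps = n_reps,
    out_dir = out_dir, ik_stride = ik_stride,
    alpha = 0.05, n_perm = 10000, prune_threshold = 0.05,
    outcomes = c("gh_total", "gh_compression", "gh_shear_ap", "gh_shear_si",
                 "ac_total", "ac_compression", "ac_shear_ap", "ac_shear_si"),
    snpm_outcomes = c("gh_compression", "ac_compression"),
    noise = list(), solver_options = list(),
    max_gap_frames = 10, write_trials = FALSE
  ), list(...))
}

#' Run the full bench-press shoulder-load pipeline
#'
#' Generates a synthetic cohort over the 21 performed technique conditions,
#' preprocesses every trial, scales the generic model per subject from a
#' static trial, runs inverse kinematics and the muscle redundancy solver,
#' assembles cycle-normalized joint-reaction outcomes, and performs the
#' descriptive and two-level SnPM analyses.
#'
#' @param config List from [pipeline_config()].
#' @return Object of class `bp_pipeline_run`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- utils::modifyList(pipeline_config(), config)
  t_start <- Sys.time()
  timings <- c()
  tick <- function(nm, t0) {
    timings[nm] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }
  grid <- technique_grid()
  safe <- grid[grid$is_safe, ]
  generic <- load_model()

  subjects <- list(); models <- list(); calibs <- list()
  t0 <- Sys.time()
  for (i in seq_len(cfg$n_subjects)) {
    sub <- generate_subject(cfg$seed * 100 + i)
    static <- generate_static_markers(sub)
    models[[sub$subject_id]] <- scale_model(generic, sub, static)
    calibs[[sub$subject_id]] <- generate_scapula_calibration(
      sub, seed = cfg$seed)
    subjects[[sub$subject_id]] <- sub
  }
  tick("subjects", t0)

  norm_rows <- list()     # one row per rep x outcome: meta + 101 values
  peak_rows <- list()
  clean_trials <- list()
  excluded <- list()
  t0 <- Sys.time()
  for (sid in names(subjects)) {
    sub <- subjects[[sid]]
    model_s <- models[[sid]]
    for (ci in seq_len(nrow(safe))) {
      cond <- safe[ci, ]
      trial <- simulate_trial(sub, cond, n_reps = cfg$n_reps,
                              noise = cfg$noise, seed = cfg$seed)
      ct <- preprocess_trial(trial, calibs[[sid]],
                             options = list(max_gap_frames = cfg$max_gap_frames))
      if (ct$excluded) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          subject = sid, condition = cond$id, reason = ct$reason)
        next
      }
      pos <- inverse_kinematics(model_s, ct$markers, stride = cfg$ik_stride)
      sol <- rmr_solve(model_s, pos, ct$force, options = cfg$solver_options)
      clean_trials[[length(clean_trials) + 1L]] <- ct
      meta <- data.frame(subject = sid,
                         grip = as.character(cond$grip_width_baw),
                         abduction = as.character(cond$abduction_deg),
                         pose = cond$scapula_pose,
                         stringsAsFactors = FALSE)
      for (ri in seq_len(nrow(ct$partition$reps))) {
        for (oc in cfg$outcomes) {
          jn <- sub("_.*", "", oc)
          comp <- sub("^[^_]*_", "", oc)
          v <- sol$jrf[[jn]][, comp]
          nv <- time_normalize(v, ct$partition, ri,
                               sample_index = pos$sample_index)
          norm_rows[[length(norm_rows) + 1L]] <- c(
            list(subject = sid, grip = meta$grip,
                 abduction = meta$abduction, pose = meta$pose,
                 rep = ri, outcome = oc), as.list(nv))
        }
        r <- ct$partition$reps[ri, ]
        in_rep <- pos$sample_index >= r$start & pos$sample_index <= r$end
        pk <- apply(sol$activations[in_rep, , drop = FALSE], 2, max)
        peak_rows[[length(peak_rows) + 1L]] <- c(
          list(subject = sid, grip = meta$grip, abduction = meta$abduction,
               pose = meta$pose, rep = ri), as.list(pk))
      }
      if (!is.null(cfg$out_dir) && cfg$write_trials) {
        tdir <- file.path(cfg$out_dir, "trials", sid, cond$id)
        dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
        write_trc(ct$markers, file.path(tdir, "markers.trc"))
        write_sto(data.frame(time = ct$force$time,
                             lateral = ct$force$exerted_lateral),
                  file.path(tdir, "force.sto"))
        write_sto(data.frame(time = sol$time, sol$activations),
                  file.path(tdir, "activations.sto"))
      }
    }
  }
  tick("trials", t0)
  norm <- do.call(rbind, lapply(norm_rows, function(r)
    as.data.frame(r, col.names = c(names(r)[1:6], paste0("ph", 0:100)))))
  peaks <- do.call(rbind, lapply(peak_rows, as.data.frame))

  t0 <- Sys.time()
  force_stats <- descriptive_force_stats(clean_trials)
  activity <- peak_activity_summary(peaks)

  snpm <- list()
  for (oc in cfg$snpm_outcomes) {
    sel <- norm$outcome == oc
    Y_list <- list(); cond_list <- list()
    for (sid in names(subjects)) {
      rows <- norm[sel & norm$subject == sid, ]
      Y_list[[sid]] <- as.matrix(rows[, paste0("ph", 0:100)])
      cond_list[[sid]] <- data.frame(grip_width_baw = rows$grip,
                                     abduction_deg = rows$abduction,
                                     scapula_pose = rows$pose)
    }
    snpm[[oc]] <- prune_and_refit(Y_list, cond_list, alpha = cfg$alpha,
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, oc),
                                  prune_threshold = cfg$prune_threshold)
  }
  tick("stats", t0)

  ## consolidated cluster table over all outcomes and retained terms
  cl_rows <- list()
  for (oc in names(snpm)) {
    for (tm in names(snpm[[oc]]$results)) {
      r <- snpm[[oc]]$results[[tm]]
      if (!is.null(r$clusters)) {
        cc <- r$clusters
        cc$outcome <- oc; cc$term <- tm
        cl_rows[[length(cl_rows) + 1L]] <- cc
      }
    }
  }
  cluster_table <- if (length(cl_rows)) do.call(rbind, cl_rows) else
    data.frame(phase_start = integer(0), phase_end = integer(0),
               max_abs_t = numeric(0), sign = numeric(0), p = numeric(0),
               outcome = character(0), term = character(0))

  run <- structure(list(
    config = cfg, subjects = subjects,
    normalized = norm, peaks = peaks,
    force_stats = force_stats, activity = activity,
    snpm = snpm, cluster_table = cluster_table,
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
    manifest = list(
      package_version = as.character(utils::packageVersion("bpshoulder")),
      seed = cfg$seed, n_subjects = cfg$n_subjects, n_reps = cfg$n_reps,
      n_conditions = nrow(safe), n_excluded_trials = length(excluded),
      timings_s = as.list(timings),
      total_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 1))
  ), class = "bp_pipeline_run")

  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$normalized, file.path(out_dir, "normalized_outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(run$peaks, file.path(out_dir, "peak_activations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$force_stats$table, file.path(out_dir, "force_table.csv"),
                   row.names = FALSE)
  utils::write.csv(run$activity$table, file.path(out_dir, "activity_table.csv"),
                   row.names = FALSE)
  utils::write.csv(run$cluster_table, file.path(out_dir, "cluster_table.csv"),
                   row.names = FALSE)
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  audits <- lapply(run$snpm, `[[`, "audit")
  lines <- unlist(lapply(names(audits), function(oc)
    paste0("[", oc, "] ", audits[[oc]])))
  writeLines(as.character(lines), file.path(out_dir, "snpm_audit.log"))
  invisible(out_dir)
}

#' @export
print.bp_pipeline_run <- function(x, ...) {
  cat("Bench-press shoulder-load pipeline run\n")
  cat(sprintf("  %d subjects x %d conditions x %d reps (seed %d), %.1f s\n",
              x$config$n_subjects, 21, x$config$n_reps, x$config$seed,
              x$manifest$total_s))
  cat(sprintf("  excluded trials: %d\n", x$manifest$n_excluded_trials))
  cat(sprintf("  significant clusters found: %d\n", nrow(x$cluster_table)))
  invisible(x)
}

#' Render tables and figures for a completed run
#'
#' Writes Table-1-style (mediolateral force) and Table-2-style (peak
#' activity) summaries as CSV/markdown and, per technique factor, an
#' 8-panel figure (total, compression and the two shear components for the
#' glenohumeral and acromioclavicular joints) with mean traces per level
#' and a significance raster from the SnPM results, plus a supraspinatus
#' activity panel.
#'
#' @param run A `bp_pipeline_run`, or a directory written by
#'   [run_pipeline()].
#' @param out_dir Where to write the report (default `<run dir>/report`).
#' @return Invisibly, the report directory.
#' @export
pipeline_report <- function(run, out_dir = NULL) {
  if (is.character(run)) {
    dirp <- run
    report_dir <- out_dir %||% file.path(dirp, "report")
    norm <- tryCatch(utils::read.csv(file.path(dirp, "normalized_outcomes.csv"),
                                     colClasses = c(grip = "character",
                                                    abduction = "character")),
                     error = function(e) NULL)
    clus <- tryCatch(utils::read.csv(file.path(dirp, "cluster_table.csv")),
                     error = function(e) NULL)
    ftab <- tryCatch(utils::read.csv(file.path(dirp, "force_table.csv")),
                     error = function(e) NULL)
    atab <- tryCatch(utils::read.csv(file.path(dirp, "activity_table.csv")),
                     error = function(e) NULL)
  } else {
    report_dir <- out_dir %||% file.path(run$config$out_dir %||% tempdir(),
                                         "report")
    norm <- run$normalized; clus <- run$cluster_table
    ftab <- run$force_stats$table; atab <- run$activity$table
  }
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  absent <- character(0)

  md <- c("# Bench-press shoulder load report", "")
  if (!is.null(ftab)) {
    utils::write.csv(ftab, file.path(report_dir, "table1_forces.csv"),
                     row.names = FALSE)
    md <- c(md, "## Mediolateral hand forces (N): per-level mean +/- SD", "")
    for (i in seq_len(nrow(ftab))) {
      md <- c(md, sprintf("- %s = %s, %s: %.1f +/- %.1f",
                          ftab$factor[i], ftab$level[i], ftab$statistic[i],
                          ftab$mean[i], ftab$sd[i]))
    }
  } else absent <- c(absent, "force table")
  if (!is.null(atab)) {
    utils::write.csv(atab, file.path(report_dir, "table2_activity.csv"),
                     row.names = FALSE)
  } else absent <- c(absent, "activity table")

  outcomes <- c("gh_total", "gh_compression", "gh_shear_ap", "gh_shear_si",
                "ac_total", "ac_compression", "ac_shear_ap", "ac_shear_si")
  if (!is.null(norm)) {
    phcols <- paste0("ph", 0:100)
    for (fac in c("grip", "abduction", "pose")) {
      fn <- file.path(report_dir, paste0("jrf_", fac, ".png"))
      grDevices::png(fn, width = 1600, height = 800, res = 110)
      graphics::par(mfrow = c(2, 4), mar = c(3.5, 3.5, 2, 0.5),
                    mgp = c(2.2, 0.7, 0))
      for (oc in outcomes) {
        sel <- norm$outcome == oc
        levs <- sort(unique(norm[[fac]][sel]))
        cols <- c("blue", "black", "red")
        first <- TRUE
        for (li in seq_along(levs)) {
          rows <- norm[sel & norm[[fac]] == levs[li], phcols]
          m <- colMeans(as.matrix(rows))
          if (first) {
            graphics::plot(0:100, m, type = "l", col = cols[li],
                           xlab = "phase (%)", ylab = "force (N)", main = oc)
            first <- FALSE
          } else graphics::lines(0:100, m, col = cols[li])
        }
        if (!is.null(clus) && nrow(clus)) {
          cc <- clus[clus$outcome == oc, , drop = FALSE]
          for (k in seq_len(nrow(cc))) {
            graphics::rect(cc$phase_start[k], graphics::par("usr")[3],
                           cc$phase_end[k],
                           graphics::par("usr")[3] +
                             0.05 * diff(graphics::par("usr")[3:4]),
                           col = "grey70", border = NA)
          }
        }
        graphics::legend("topleft", legend = levs, col = cols[seq_along(levs)],
                         lty = 1, cex = 0.7, bty = "n")
      }
      grDevices::dev.off()
      md <- c(md, sprintf("![JRF by %s](jrf_%s.png)", fac, fac))
    }
  } else absent <- c(absent, "normalized outcomes")

  if (length(absent)) {
    md <- c(md, "", "## Missing stage outputs",
            paste0("- ", absent))
  }
  writeLines(md, file.path(report_dir, "report.md"))
  invisible(report_dir)
}
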