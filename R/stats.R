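## Cycle normalization, descriptive summaries and the two-level
## random-effects statistical non-parametric mapping (SnPM) analysis.

#' Normalize a per-frame outcome onto the 101-point press-phase grid
#'
#' Descent samples (phase 0-50, barbell top to lowest point) and ascent
#' samples (50-100) are linearly interpolated onto 51 nodes each, sharing
#' the bottom node, giving 101 values on the 0..100 percent grid.
#'
#' @param values Outcome values sampled at `sample_index`.
#' @param partition A `cycle_partition` from [segment_cycles()].
#' @param rep_index Which repetition to normalize.
#' @param sample_index Full-rate sample indices of `values` (default
#'   `seq_along(values)`, i.e. values are on the partition's own grid).
#' @return Numeric vector of length 101 (phase 0, 1, ..., 100).
#' @export
time_normalize <- function(values, partition, rep_index = 1,
                           sample_index = seq_along(values)) {
  r <- partition$reps[rep_index, ]
  ph <- partition$phase[sample_index]
  in_rep <- sample_index >= r$start & sample_index <= r$end & !is.na(ph)
  ## the sample at a shared rep boundary belongs to both repetitions; use
  ## the phase of THIS repetition
  ph_rep <- ph
  bsel <- sample_index >= r$start & sample_index <= r$bottom
  asel <- sample_index >= r$bottom & sample_index <= r$end
  tb <- partition$time
  ph_b <- 50 * (tb[sample_index] - tb[r$start]) / (tb[r$bottom] - tb[r$start])
  ph_a <- 50 + 50 * (tb[sample_index] - tb[r$bottom]) / (tb[r$end] - tb[r$bottom])
  desc <- which(bsel); asc <- which(asel)
  if (length(desc) < 2 || length(asc) < 2) {
    stop("time_normalize: repetition has too few samples")
  }
  d <- stats::approx(ph_b[desc], values[desc], xout = seq(0, 50, length.out = 51),
                     rule = 2)$y
  a <- stats::approx(ph_a[asc], values[asc], xout = seq(50, 100, length.out = 51),
                     rule = 2)$y
  c(d, a[-1])
}

#' Mediolateral hand-force descriptive statistics
#'
#' Median, 10th and 90th percentile of the per-hand mediolateral force are
#' computed per repetition, averaged over repetitions and trials within a
#' technique-component level within subject, and reported as mean and SD
#' over subjects (lateral positive).
#'
#' @param trials List of `clean_trial` objects.
#' @return List: `per_rep` (one row per repetition) and `table` (one row
#'   per factor level and statistic).
#' @export
descriptive_force_stats <- function(trials) {
  rows <- list()
  for (ct in trials) {
    for (ri in seq_len(nrow(ct$partition$reps))) {
      r <- ct$partition$reps[ri, ]
      lat <- ct$force$exerted_lateral[r$start:r$end]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ct$subject_id,
        grip = as.character(ct$condition$grip_width_baw),
        abduction = as.character(ct$condition$abduction_deg),
        pose = ct$condition$scapula_pose,
        rep = ri,
        median = stats::median(lat),
        p10 = unname(stats::quantile(lat, 0.10)),
        p90 = unname(stats::quantile(lat, 0.90)))
    }
  }
  per_rep <- do.call(rbind, rows)
  out <- list()
  for (fac in c("grip", "abduction", "pose")) {
    for (lev in unique(per_rep[[fac]])) {
      sub <- per_rep[per_rep[[fac]] == lev, ]
      for (st in c("median", "p10", "p90")) {
        by_subj <- tapply(sub[[st]], sub$subject, mean)
        out[[length(out) + 1L]] <- data.frame(
          factor = fac, level = lev, statistic = st,
          mean = mean(by_subj), sd = stats::sd(by_subj),
          n_subjects = length(by_subj))
      }
    }
  }
  list(per_rep = per_rep, table = do.call(rbind, out))
}

#' Peak muscle-activity summary
#'
#' Peak activation per bundle per repetition, averaged within
#' technique-component level within subject, reported as mean and SD over
#' subjects; the lowest mean per technique component per bundle is flagged.
#'
#' @param peaks Data frame with columns `subject`, `grip`, `abduction`,
#'   `pose`, `rep` and one column per bundle (per-repetition peak
#'   activations), as assembled by [run_pipeline()].
#' @param bundles Bundle column names (default: everything after `rep`).
#' @return List: `table` (factor x level x bundle) with `is_min` flags.
#' @export
peak_activity_summary <- function(peaks,
                                  bundles = setdiff(names(peaks),
                                                    c("subject", "grip",
                                                      "abduction", "pose",
                                                      "rep"))) {
  out <- list()
  for (fac in c("grip", "abduction", "pose")) {
    for (lev in unique(peaks[[fac]])) {
      sub <- peaks[peaks[[fac]] == lev, ]
      for (b in bundles) {
        by_subj <- tapply(sub[[b]], sub$subject, mean)
        out[[length(out) + 1L]] <- data.frame(
          factor = fac, level = lev, bundle = b,
          mean = mean(by_subj), sd = stats::sd(by_subj))
      }
    }
  }
  tab <- do.call(rbind, out)
  tab$is_min <- FALSE
  for (fac in unique(tab$factor)) {
    for (b in bundles) {
      sel <- tab$factor == fac & tab$bundle == b
      tab$is_min[sel] <- tab$mean[sel] == min(tab$mean[sel])
    }
  }
  list(table = tab)
}

#' First-level design matrix for the technique factors
#'
#' Intercept, two dummies per three-level factor (reference levels: grip
#' 1.5 BAW, abduction 70 degrees, scapula neutral), all 12 two-way and 8
#' three-way interaction columns - 27 columns in total.
#'
#' @param conditions Data frame with one row per observation and columns
#'   `grip_width_baw` (or `grip`), `abduction_deg` (or `abduction`),
#'   `scapula_pose` (or `pose`).
#' @return Numeric matrix with a `tier` attribute labelling columns as
#'   intercept, main, two_way or three_way.
#' @export
build_design <- function(conditions) {
  g <- as.character(conditions$grip_width_baw %||% conditions$grip)
  a <- as.character(conditions$abduction_deg %||% conditions$abduction)
  p <- as.character(conditions$scapula_pose %||% conditions$pose)
  chk <- function(x, levels, nm) {
    bad <- setdiff(unique(x), levels)
    if (length(bad)) stop("build_design: unseen ", nm, " level: ",
                          paste(bad, collapse = ", "))
  }
  chk(g, c("1", "1.5", "2"), "grip")
  chk(a, c("45", "70", "90"), "abduction")
  chk(p, c("neutral", "retracted", "released"), "scapula pose")
  main <- cbind(g1 = as.numeric(g == "1"), g2 = as.numeric(g == "2"),
                a45 = as.numeric(a == "45"), a90 = as.numeric(a == "90"),
                poseRT = as.numeric(p == "retracted"),
                poseRL = as.numeric(p == "released"))
  gcols <- c("g1", "g2"); acols <- c("a45", "a90"); pcols <- c("poseRT", "poseRL")
  two <- NULL; three <- NULL
  for (gg in gcols) for (aa in acols) {
    two <- cbind(two, main[, gg] * main[, aa])
    colnames(two)[ncol(two)] <- paste(gg, aa, sep = ":")
  }
  for (gg in gcols) for (pp in pcols) {
    two <- cbind(two, main[, gg] * main[, pp])
    colnames(two)[ncol(two)] <- paste(gg, pp, sep = ":")
  }
  for (aa in acols) for (pp in pcols) {
    two <- cbind(two, main[, aa] * main[, pp])
    colnames(two)[ncol(two)] <- paste(aa, pp, sep = ":")
  }
  for (gg in gcols) for (aa in acols) for (pp in pcols) {
    three <- cbind(three, main[, gg] * main[, aa] * main[, pp])
    colnames(three)[ncol(three)] <- paste(gg, aa, pp, sep = ":")
  }
  X <- cbind(intercept = 1, main, two, three)
  attr(X, "tier") <- stats::setNames(
    c("intercept", rep("main", 6), rep("two_way", 12), rep("three_way", 8)),
    colnames(X))
  X
}

#' Within-subject first-level regression at every phase node
#'
#' Ordinary least squares of the outcome on the design, fitted
#' independently at each of the 101 phase nodes.
#'
#' @param Y Observations x 101 outcome matrix (one subject).
#' @param X Design matrix from [build_design()] (or a column subset).
#' @param drop_aliased Drop rank-deficient columns (with an audit
#'   attribute) instead of erroring.
#' @return Coefficient matrix (columns of `X` x 101) with attribute
#'   `dropped` listing any aliased terms removed.
#' @export
first_level <- function(Y, X, drop_aliased = FALSE) {
  if (nrow(Y) != nrow(X)) stop("first_level: Y and X row mismatch")
  if (nrow(X) < ncol(X) && !drop_aliased) {
    stop("first_level: fewer observations (", nrow(X),
         ") than design columns (", ncol(X), ")")
  }
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (!drop_aliased) {
      stop("first_level: design is rank deficient; aliased terms: ",
           paste(aliased, collapse = ", "))
    }
    dropped <- aliased
    keep <- setdiff(colnames(X), aliased)
    tier <- attr(X, "tier")
    X <- X[, keep, drop = FALSE]
    attr(X, "tier") <- tier[keep]
    qx <- qr(X)
  }
  B <- qr.coef(qx, Y)
  rownames(B) <- colnames(X)
  attr(B, "dropped") <- dropped
  attr(B, "tier") <- attr(X, "tier")
  B
}

#' One-sample SnPM t-test on beta continuums
#'
#' Computes the across-subject t continuum at each phase node and a
#' sign-flipping permutation null. Family-wise control over the 101 nodes
#' uses the maximum-statistic distribution: a node is significant when its
#' |t| exceeds the (1 - alpha) quantile of the permutation max-|t|.
#' Sign patterns are enumerated exhaustively when `2^n <= 2^14`, otherwise
#' `n_perm` patterns are sampled with the mandatory seed.
#'
#' @param B Subjects x 101 matrix of beta continuums for one term.
#' @param alpha Significance level (default 0.05).
#' @param n_perm Number of sampled sign patterns when not exhaustive.
#' @param seed Seed for sampled permutations.
#' @param term Optional term label.
#' @return Object of class `snpm`: t continuum, critical value,
#'   significant nodes, cluster table with permutation p-values.
#' @export
snpm_one_sample <- function(B, alpha = 0.05, n_perm = 10000, seed = 1,
                            term = "term") {
  B <- as.matrix(B)
  n <- nrow(B)
  if (n < 2) stop("snpm_one_sample: need at least 2 subjects")
  nn <- ncol(B)
  exhaustive <- 2^n <= 2^14
  S <- if (exhaustive) {
    M <- 2^n
    vapply(seq_len(n), function(j)
      ifelse(bitwAnd(0:(M - 1), bitwShiftL(1L, j - 1L)) > 0, -1, 1),
      numeric(M))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           n_perm, n))
  }
  M <- nrow(S)
  ss <- colSums(B^2)
  tstat <- function(m) {
    v <- sweep(-(m^2), 2, ss / n, `+`) * n / (n - 1)   # per-flip variance
    v[v < 0] <- 0
    se <- sqrt(v / n)
    tt <- m / se
    tt[m == 0 & se == 0] <- 0
    tt
  }
  t_obs <- tstat(matrix(colMeans(B), 1))[1, ]
  Tp <- tstat(S %*% B / n)
  maxT <- apply(abs(Tp), 1, max)
  crit <- sort(maxT)[ceiling((1 - alpha) * M)]
  sig <- abs(t_obs) > crit
  ## contiguous significant runs with max-statistic permutation p-values
  clusters <- NULL
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cl <- which(r$values)
    clusters <- do.call(rbind, lapply(cl, function(ci) {
      nodes <- starts[ci]:ends[ci]
      tmax <- max(abs(t_obs[nodes]))
      data.frame(phase_start = nodes[1] - 1L,
                 phase_end = nodes[length(nodes)] - 1L,
                 max_abs_t = tmax,
                 sign = sign(t_obs[nodes[which.max(abs(t_obs[nodes]))]]),
                 p = mean(maxT >= tmax))
    }))
  }
  structure(list(term = term, t = t_obs, crit = crit, alpha = alpha,
                 n_perm = M, exhaustive = exhaustive, sig = sig,
                 clusters = clusters,
                 p_min = mean(maxT >= max(abs(t_obs))),
                 n_subjects = n, seed = seed),
            class = "snpm")
}

#' @export
print.snpm <- function(x, ...) {
  cat(sprintf("SnPM one-sample t-test [%s]: %d subjects, %d %s sign flips\n",
              x$term, x$n_subjects, x$n_perm,
              if (x$exhaustive) "exhaustive" else "sampled"))
  cat(sprintf("  max |t| = %.2f, critical (alpha=%.2f) = %.2f, min p = %.4g\n",
              max(abs(x$t)), x$alpha, x$crit, x$p_min))
  if (!is.null(x$clusters)) {
    cat("  significant clusters (phase %):\n")
    print(x$clusters, row.names = FALSE)
  } else cat("  no significant nodes\n")
  invisible(x)
}

#' @export
summary.snpm <- function(object, ...) {
  list(term = object$term, n_sig_nodes = sum(object$sig),
       clusters = object$clusters, p_min = object$p_min)
}

#' @export
plot.snpm <- function(x, ...) {
  ph <- 0:100
  graphics::plot(ph, x$t, type = "l", xlab = "bench press phase (%)",
                 ylab = "t", main = x$term, ...)
  graphics::abline(h = c(-x$crit, x$crit), lty = 2, col = 2)
  if (any(x$sig)) {
    graphics::points(ph[x$sig], x$t[x$sig], col = 2, pch = 16, cex = 0.5)
  }
  invisible(x)
}

#' Hierarchical interaction pruning and refitting
#'
#' Fits the full first-level model per subject, tests every term at the
#' second level, and prunes interaction tiers top-down: the three-way tier
#' is dropped when fewer than `prune_threshold` of its term-by-node results
#' are significant, then the two-way tier is assessed the same way. When a
#' two-way tier is retained, stratified main-effect analyses are run per
#' level of each factor involved in a significant interaction.
#'
#' @param Y_list Per-subject observations x 101 outcome matrices.
#' @param cond_list Per-subject condition data frames (one row per
#'   observation).
#' @param alpha,n_perm,seed Passed to [snpm_one_sample()].
#' @param prune_threshold Fraction of significant term x node results below
#'   which an interaction tier is dropped (default 0.05).
#' @param drop_aliased Passed to [first_level()] (required when the safe 21
#'   conditions leave interaction columns aliased).
#' @return List: `results` (snpm per retained term), `final_terms`,
#'   `audit` (character log), `stratified` (nested results or NULL).
#' @export
prune_and_refit <- function(Y_list, cond_list, alpha = 0.05, n_perm = 10000,
                            seed = 1, prune_threshold = 0.05,
                            drop_aliased = TRUE) {
  audit <- character(0)
  fit_tiers <- function(keep_tiers) {
    Bs <- list()
    for (si in seq_along(Y_list)) {
      X <- build_design(cond_list[[si]])
      tier <- attr(X, "tier")
      Xk <- X[, tier %in% keep_tiers, drop = FALSE]
      attr(Xk, "tier") <- tier[tier %in% keep_tiers]
      B <- first_level(Y_list[[si]], Xk, drop_aliased = drop_aliased)
      if (si == 1 && length(attr(B, "dropped"))) {
        audit <<- c(audit, paste("aliased terms dropped:",
                                 paste(attr(B, "dropped"), collapse = ", ")))
      }
      Bs[[si]] <- B
    }
    terms <- rownames(Bs[[1]])
    tier <- attr(Bs[[1]], "tier")
    names(tier) <- terms
    res <- list()
    for (tm in setdiff(terms, "intercept")) {
      Bm <- do.call(rbind, lapply(Bs, function(b) b[tm, ]))
      res[[tm]] <- snpm_one_sample(Bm, alpha = alpha, n_perm = n_perm,
                                   seed = derive_seed(seed, tm), term = tm)
    }
    list(res = res, tier = tier)
  }
  sig_frac <- function(res, tier, which_tier) {
    tms <- names(tier)[tier == which_tier]
    tms <- intersect(tms, names(res))
    if (length(tms) == 0) return(0)
    mean(unlist(lapply(res[tms], function(r) r$sig)))
  }

  tiers <- c("intercept", "main", "two_way", "three_way")
  fit <- fit_tiers(tiers)
  f3 <- sig_frac(fit$res, fit$tier, "three_way")
  audit <- c(audit, sprintf("three-way significant fraction: %.3f", f3))
  if (f3 < prune_threshold) {
    audit <- c(audit, "three-way tier pruned")
    tiers <- setdiff(tiers, "three_way")
    fit <- fit_tiers(tiers)
    f2 <- sig_frac(fit$res, fit$tier, "two_way")
    audit <- c(audit, sprintf("two-way significant fraction: %.3f", f2))
    if (f2 < prune_threshold) {
      audit <- c(audit, "two-way tier pruned")
      tiers <- setdiff(tiers, "two_way")
      fit <- fit_tiers(tiers)
    }
  }

  ## stratified analyses when interactions are retained
  stratified <- NULL
  if (any(c("two_way", "three_way") %in% tiers)) {
    inter_sig <- names(fit$res)[vapply(fit$res, function(r)
      grepl(":", r$term) && !is.null(r$clusters), logical(1))]
    facs <- unique(unlist(lapply(strsplit(inter_sig, ":"), function(parts) {
      vapply(parts, function(p) {
        if (grepl("^g", p)) "grip" else if (grepl("^a", p)) "abduction"
        else "pose"
      }, character(1))
    })))
    if (length(facs)) {
      stratified <- list()
      fac_col <- c(grip = "grip_width_baw", abduction = "abduction_deg",
                   pose = "scapula_pose")
      for (fc in facs) {
        col <- fac_col[[fc]]
        levs <- unique(as.character(cond_list[[1]][[col]]))
        for (lv in levs) {
          Yl <- list(); Cl <- list()
          for (si in seq_along(Y_list)) {
            sel <- as.character(cond_list[[si]][[col]]) == lv
            Yl[[si]] <- Y_list[[si]][sel, , drop = FALSE]
            Cl[[si]] <- cond_list[[si]][sel, , drop = FALSE]
          }
          Bs <- list()
          for (si in seq_along(Yl)) {
            X <- build_design(Cl[[si]])
            tier <- attr(X, "tier")
            keep <- tier == "main" | tier == "intercept"
            Xk <- X[, keep, drop = FALSE]
            ## within a stratum the stratifying factor's dummies are
            ## constant; drop them as aliased
            Bs[[si]] <- first_level(Yl[[si]], Xk, drop_aliased = TRUE)
          }
          res_l <- list()
          for (tm in setdiff(rownames(Bs[[1]]), "intercept")) {
            Bm <- do.call(rbind, lapply(Bs, function(b) b[tm, ]))
            res_l[[tm]] <- snpm_one_sample(
              Bm, alpha = alpha, n_perm = n_perm,
              seed = derive_seed(seed, fc, lv, tm), term = tm)
          }
          stratified[[paste(fc, lv, sep = "=")]] <- res_l
          audit <- c(audit, sprintf("stratified analysis: %s = %s", fc, lv))
        }
      }
    }
  }
  list(results = fit$res, final_terms = names(fit$res), audit = audit,
       stratified = stratified)
}
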