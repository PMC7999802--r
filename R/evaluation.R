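#' Stratified fold assignment
#'
#' Subjects are randomly assigned to folds with the number of subjects of
#' each class apportioned as equally as possible (per-fold class counts
#' differ by at most 1), with no mixing of a subject across folds.
#'
#' @param subject_id Subject identifiers.
#' @param label Class labels (`"control"` / `"PD"`), same length.
#' @param n_folds Number of folds.
#' @param seed Seed.
#' @return Integer vector of fold indices (`0 .. n_folds - 1`) named by
#'   subject.
#' @export
assign_folds <- function(subject_id, label, n_folds = 5L, seed = 1L) {
  stopifnot(length(subject_id) == length(label))
  fold <- integer(length(subject_id))
  names(fold) <- subject_id
  .with_seed(seed, {
    for (cl in unique(label)) {
      idx <- which(label == cl)
      if (length(idx) < n_folds)
        stop("class '", cl, "' has fewer subjects (", length(idx),
             ") than folds (", n_folds, ")")
      perm <- sample(idx)
      slots <- sample.int(n_folds) - 1L
      fold[perm] <- rep(slots, length.out = length(perm))
    }
  })
  fold
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) score pairs in which the positive
#' scores higher, ties counted 1/2.
#'
#' @param pos Scores of the positive (PD) group.
#' @param neg Scores of the negative (control) group.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos, neg) {
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0L || n2 == 0L) stop("both groups must be nonempty")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Step-ROC convention: over all thresholds (the observed scores plus
#' infinities, predicting positive for scores strictly above the
#' threshold), the maximum true-positive rate among operating points whose
#' empirical FPR does not exceed `fpr_target`. No interpolation and no
#' stochastic tie-breaking.
#'
#' @inheritParams auc
#' @param fpr_target Maximum admissible false-positive rate.
#' @return The sensitivity.
#' @export
sensitivity_at_fpr <- function(pos, neg, fpr_target) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both groups must be nonempty")
  thr <- c(-Inf, sort(unique(c(pos, neg))))
  best <- 0
  for (th in thr) {
    fpr <- mean(neg > th)
    if (fpr <= fpr_target) best <- max(best, mean(pos > th))
  }
  best
}

#' Two-sample significance tests on detection scores
#'
#' @inheritParams auc
#' @return A list: `p_t` (two-sided Welch t-test; NA when the variance is
#'   degenerate), `p_u` (two-sided Mann-Whitney U-test), `U` (the U
#'   statistic of the positive group).
#' @export
significance <- function(pos, neg) {
  p_t <- tryCatch(t.test(pos, neg)$p.value, error = function(e) NA_real_)
  w <- suppressWarnings(wilcox.test(pos, neg))
  list(p_t = p_t, p_u = w$p.value, U = unname(w$statistic))
}

#' Collect per-subject features into a cohort
#'
#' @param subject_features List of [extract_features()] results.
#' @return A `wpd_cohort_features` list.
#' @export
cohort_features <- function(subject_features) {
  stopifnot(all(vapply(subject_features, inherits, TRUE,
                       "wpd_subject_features")))
  ids <- vapply(subject_features, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicated subject_id in cohort")
  names(subject_features) <- ids
  structure(subject_features, class = "wpd_cohort_features")
}

# Component scores for one subject, optionally truncating the scored
# frames to those starting before cutoff_s (training is never truncated).
.subject_scores <- function(models, sf, cutoff_s = Inf) {
  gsel <- sf$gait$times < cutoff_s
  lsel <- sf$lm$times < cutoff_s
  days_eff <- min(cutoff_s / 86400, sf$days_observed)
  g1 <- if (any(gsel))
    score_multiframe(models$disp, sf$gait$disp[gsel, , drop = FALSE])
  else NA_real_
  l1 <- if (any(lsel))
    score_multiframe(models$eig, sf$lm$eig[lsel, , drop = FALSE])
  else NA_real_
  g2 <- score_incidence(models$ginc, sum(gsel) / days_eff)
  l2 <- score_incidence(models$linc, sum(lsel) / days_eff)
  c(S_G1 = g1, S_G2 = g2, S_LM1 = l1, S_LM2 = l2)
}

# Train the four feature-set model pairs on the training subjects.
.train_fold_models <- function(feats, train_ids, params, fold) {
  tr <- feats[train_ids]
  lab <- vapply(tr, `[[`, "", "label")
  stack <- function(field) {
    list(control = do.call(rbind, lapply(tr[lab == "control"],
                                         function(s) s[[field]][[2L]])),
         pd = do.call(rbind, lapply(tr[lab == "PD"],
                                    function(s) s[[field]][[2L]])))
  }
  inc <- function(which) {
    v <- vapply(tr, function(s) s$incidence[[which]], 0)
    list(control = matrix(v[lab == "control"], ncol = 1L),
         pd = matrix(v[lab == "PD"], ncol = 1L))
  }
  seeds <- derive_seeds(params$seed, paste0("gmm-fold-", fold), 4L)
  d <- stack("gait"); e <- stack("lm")
  gi <- inc("gait_frames_per_day"); li <- inc("lm_frames_per_day")
  list(disp = train_class_models(d$control, d$pd, params, seeds[1L]),
       eig = train_class_models(e$control, e$pd, params, seeds[2L]),
       ginc = train_class_models(gi$control, gi$pd, params, seeds[3L],
                                 use_pca = FALSE),
       linc = train_class_models(li$control, li$pd, params, seeds[4L],
                                 use_pca = FALSE))
}

# Exclude subjects with neither gait nor LM frames; returns kept features.
.apply_exclusions <- function(feats) {
  keep <- vapply(feats, function(s) s$n_gait_frames > 0 || s$n_lm_frames > 0,
                 TRUE)
  list(kept = feats[keep], excluded = names(feats)[!keep])
}

.score_grid <- function(scores_df, alpha) {
  combos <- score_combinations()
  rows <- lapply(seq_along(combos), function(ci) {
    v <- apply(scores_df[, c("S_G1", "S_G2", "S_LM1", "S_LM2")], 1L,
               function(s) fuse_scores(as.list(s), alpha, ci))
    ok <- !is.na(v)
    pos <- v[ok & scores_df$label == "PD"]
    neg <- v[ok & scores_df$label == "control"]
    by_sex <- function(sx) {
      p <- v[ok & scores_df$label == "PD" & scores_df$sex %in% sx]
      n <- v[ok & scores_df$label == "control" & scores_df$sex %in% sx]
      if (length(p) && length(n)) auc(p, n) else NA_real_
    }
    sig <- if (length(pos) >= 2L && length(neg) >= 2L) significance(pos, neg)
    else list(p_t = NA_real_, p_u = NA_real_, U = NA_real_)
    data.frame(combination = ci, scores = combos[ci],
               auc = auc(pos, neg),
               auc_male = by_sex("M"), auc_female = by_sex("F"),
               sens_fpr10 = sensitivity_at_fpr(pos, neg, 0.1),
               sens_fpr20 = sensitivity_at_fpr(pos, neg, 0.2),
               n = sum(ok), p_t = sig$p_t, p_u = sig$p_u)
  })
  do.call(rbind, rows)
}

# Subject-level feature summaries for effect sizes.
.subject_summaries <- function(feats) {
  lab <- vapply(feats, `[[`, "", "label")
  ginc <- vapply(feats, function(s) s$incidence$gait_frames_per_day, 0)
  linc <- vapply(feats, function(s) s$incidence$lm_frames_per_day, 0)
  disp <- t(vapply(feats, function(s)
    if (nrow(s$gait$disp)) colMeans(s$gait$disp) else rep(NA_real_, 3L),
    numeric(3L)))
  nev <- max(c(1L, vapply(feats, function(s) ncol(s$lm$eig), 0L)))
  eig <- t(vapply(feats, function(s)
    if (nrow(s$lm$eig)) colMeans(s$lm$eig) else rep(NA_real_, nev),
    numeric(nev)))
  list(label = lab, gait_incidence = ginc, lm_incidence = linc,
       dispersion = disp, eigenspectrum = eig)
}

#' Per-feature effect sizes (PD vs control)
#'
#' Cohen's d, sign convention PD minus control, on subject-level mean
#' features: gait and LM frame incidence, within-subject mean dispersion
#' per axis, and within-subject mean eigenspectrum per rank position.
#'
#' @param feats A [cohort_features()] object.
#' @param feat_params [feature_params()] (for eigenspectrum layout).
#' @return A list: `summary` data.frame (incidences and dispersion axes)
#'   and `eigenspectrum` data.frame (`scale`, `rank`, `d`).
#' @export
effect_sizes <- function(feats, feat_params = feature_params()) {
  s <- .subject_summaries(feats)
  pd <- s$label == "PD"; ct <- s$label == "control"
  d_of <- function(v) {
    ok <- !is.na(v)
    cohens_d(v[pd & ok], v[ct & ok])
  }
  summary <- data.frame(
    feature = c("gait_frame_incidence", "lm_frame_incidence",
                "dispersion_axis1", "dispersion_axis2", "dispersion_axis3"),
    activity = c("gait", "LM", "gait", "gait", "gait"),
    d = c(d_of(s$gait_incidence), d_of(s$lm_incidence),
          d_of(s$dispersion[, 1L]), d_of(s$dispersion[, 2L]),
          d_of(s$dispersion[, 3L])))
  per_scale <- feat_params$M * feat_params$N
  nscale <- length(feat_params$delay_scales)
  nev <- ncol(s$eigenspectrum)
  eig_d <- vapply(seq_len(nev), function(j) d_of(s$eigenspectrum[, j]), 0)
  if (nev == per_scale * nscale) {
    eig_df <- data.frame(
      scale = rep(feat_params$delay_scales, each = per_scale),
      rank = rep(seq_len(per_scale), nscale),
      d = eig_d)
  } else {
    # nonstandard layout (e.g. constructed test cohorts): generic positions
    eig_df <- data.frame(scale = NA_integer_, rank = seq_len(nev), d = eig_d)
  }
  list(summary = summary, eigenspectrum = eig_df)
}

#' Cross-validated evaluation of the detection pipeline
#'
#' Subjects with neither gait nor LM frames are excluded up front. The
#' remaining subjects are assigned to stratified folds; per fold, the
#' z-score transform, PCA, background GMM and MAP-adapted class models are
#' fitted on the training subjects only, and the held-out subjects'
#' component scores are computed. Test scores are pooled across folds and
#' the full combination grid (AUC overall and by sex, sensitivity at FPR
#' 0.1 and 0.2, significance tests) is reported, together with per-feature
#' effect sizes and per-fold diagnostics.
#'
#' @param feats A [cohort_features()] object.
#' @param config A [wpd_config()].
#' @return A `wpd_report` list: `scores` (pooled per-subject component
#'   scores), `grid` (the 8-row combination table), `effects`,
#'   `fold_auc` (per-fold AUC of the fully fused score), `excluded`,
#'   `folds`, and `models` (per-fold trained models, for reuse).
#' @export
run_cv <- function(feats, config = wpd_config()) {
  stopifnot(inherits(feats, "wpd_cohort_features"))
  mp <- config$model
  ex <- .apply_exclusions(feats)
  feats <- ex$kept
  ids <- names(feats)
  lab <- vapply(feats, `[[`, "", "label")
  sex <- vapply(feats, `[[`, "", "sex")
  folds <- assign_folds(ids, lab, mp$n_folds,
                        derive_seeds(mp$seed, "folds", 1L))
  models <- vector("list", mp$n_folds)
  rows <- vector("list", mp$n_folds)
  for (f in seq_len(mp$n_folds) - 1L) {
    test_ids <- ids[folds == f]
    train_ids <- ids[folds != f]
    m <- .train_fold_models(feats, train_ids, mp, f)
    models[[f + 1L]] <- m
    sc <- t(vapply(test_ids, function(id) .subject_scores(m, feats[[id]]),
                   numeric(4L)))
    rows[[f + 1L]] <- data.frame(subject_id = test_ids,
                                 label = lab[test_ids], sex = sex[test_ids],
                                 fold = f, sc)
  }
  scores <- do.call(rbind, rows)
  row.names(scores) <- NULL
  grid <- .score_grid(scores, mp$alpha)
  fold_auc <- vapply(seq_len(mp$n_folds) - 1L, function(f) {
    s <- scores[scores$fold == f, ]
    v <- apply(s[, c("S_G1", "S_G2", "S_LM1", "S_LM2")], 1L,
               function(x) fuse_scores(as.list(x), mp$alpha, 8L))
    ok <- !is.na(v)
    if (any(ok & s$label == "PD") && any(ok & s$label == "control"))
      auc(v[ok & s$label == "PD"], v[ok & s$label == "control"])
    else NA_real_
  }, 0)
  structure(list(scores = scores, grid = grid,
                 effects = effect_sizes(feats, config$feat),
                 fold_auc = fold_auc, excluded = ex$excluded,
                 folds = folds, models = models, feats = feats,
                 config = config),
            class = "wpd_report")
}

#' @export
print.wpd_report <- function(x, ...) {
  cat("<wpd_report>", length(x$feats), "subjects,",
      length(x$excluded), "excluded\n")
  print(x$grid[, c("scores", "auc", "sens_fpr10", "sens_fpr20", "n")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Detection accuracy as a function of days of data
#'
#' Models are trained per fold on the full recordings (folds unchanged
#' from [run_cv()]); only the scored frames are truncated to those
#' starting before each day cutoff, isolating the effect of test-data
#' quantity. Two subject sets are evaluated per cutoff: all subjects whose
#' required frames exist by day `d`, and the fixed set of subjects with
#' the required frames on day 1.
#'
#' @param report A [run_cv()] report (its per-fold models are reused).
#' @param day_range Day cutoffs to evaluate.
#' @param combinations Score-grid combinations to trace (defaults: gait
#'   fusion, LM fusion, all fused).
#' @return A data.frame: `day`, `subset` (`"all"` / `"day1"`),
#'   `combination`, `auc`, `n`.
#' @export
auc_by_days <- function(report, day_range = 1:7,
                        combinations = c(3L, 6L, 8L)) {
  feats <- report$feats
  folds <- report$folds
  mp <- report$config$model
  ids <- names(feats)
  lab <- vapply(feats, `[[`, "", "label")
  score_at <- function(cutoff_s) {
    t(vapply(ids, function(id)
      .subject_scores(report$models[[folds[id] + 1L]], feats[[id]],
                      cutoff_s), numeric(4L)))
  }
  day1 <- score_at(86400)
  out <- list()
  for (d in day_range) {
    sc <- if (d == 1) day1 else score_at(d * 86400)
    for (ci in combinations) {
      v <- apply(sc, 1L, function(s) fuse_scores(as.list(s), mp$alpha, ci))
      v1 <- apply(day1, 1L, function(s) fuse_scores(as.list(s), mp$alpha, ci))
      for (subset in c("all", "day1")) {
        ok <- if (subset == "all") !is.na(v) else !is.na(v) & !is.na(v1)
        pos <- v[ok & lab == "PD"]; neg <- v[ok & lab == "control"]
        out[[length(out) + 1L]] <- data.frame(
          day = d, subset = subset, combination = ci,
          auc = if (length(pos) && length(neg)) auc(pos, neg) else NA_real_,
          n = sum(ok))
      }
    }
  }
  do.call(rbind, out)
}
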