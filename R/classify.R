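CLASS_LEVELS <- c("benign", "malignant")

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Classifier configuration
#'
#' One point of the classifier x hyperparameter x PC-subset search space.
#'
#' @param family One of `"LDA"`, `"KNN"`, `"LSVM"`, `"GSVM"`, `"MLP"`.
#' @param K Number of neighbors (KNN only; study grid 1, 3, 5, 7).
#' @param C Margin factor (SVMs only; study grid 0 to 4 in steps of 0.1,
#'   with C = 0 unusable and therefore excluded).
#' @param mask Binary inclusion vector over the feature components (at
#'   least one 1).
#' @param mlp_size,mlp_maxit,mlp_decay MLP architecture: one hidden layer of
#'   `mlp_size` logistic units, iteration cap, weight decay.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(family, K = NULL, C = NULL, mask,
                              mlp_size = 10L, mlp_maxit = 2000L,
                              mlp_decay = 1e-4) {
  family <- match.arg(family, c("LDA", "KNN", "LSVM", "GSVM", "MLP"))
  mask <- as.integer(mask)
  stopifnot(all(mask %in% 0:1), sum(mask) >= 1L)
  if (family == "KNN") {
    if (is.null(K) || K < 1) stop("KNN requires K >= 1")
  } else if (!is.null(K)) stop("K is only meaningful for KNN")
  if (family %in% c("LSVM", "GSVM")) {
    if (is.null(C) || C <= 0) stop("SVMs require a margin factor C > 0")
  } else if (!is.null(C)) stop("C is only meaningful for SVMs")
  structure(list(family = family, K = K, C = C, mask = mask,
                 mlp_size = mlp_size, mlp_maxit = mlp_maxit,
                 mlp_decay = mlp_decay),
            class = "classifier_config")
}

as_class_factor <- function(labels) {
  f <- factor(as.character(labels), levels = CLASS_LEVELS)
  if (any(is.na(f))) stop("labels must be 'benign' or 'malignant'")
  f
}

# median-heuristic RBF kernel width
median_heuristic_gamma <- function(x) {
  d2 <- as.numeric(dist(x))^2
  m <- median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) return(1 / max(1L, ncol(x)))
  1 / (2 * m)
}

#' Train a classifier and score test lesions
#'
#' Fits the configured classifier on the masked training features and
#' returns a malignancy score in `[0, 1]` per test row: the Gaussian
#' posterior for LDA, the malignant fraction among the K nearest training
#' lesions for KNN, a Platt-calibrated sigmoid of the decision margin for
#' the SVMs (calibration fitted on training folds only), and the output
#' activation of the multilayer perceptron.
#'
#' @param config A [classifier_config()].
#' @param train_x,train_y Training feature matrix and labels (both classes
#'   must be present).
#' @param test_x Test feature matrix (same columns as `train_x`).
#' @param seed Seed for the stochastic learners (SVM calibration folds, MLP
#'   weight initialization).
#' @return Numeric vector of malignancy scores, one per test row.
#' @export
train_and_score <- function(config, train_x, train_y, test_x, seed = 1L) {
  stopifnot(inherits(config, "classifier_config"))
  y <- as_class_factor(train_y)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  sel <- which(config$mask == 1L)
  train_x <- as.matrix(train_x)[, sel, drop = FALSE]
  test_x <- matrix(as.matrix(test_x)[, sel], ncol = length(sel))

  score <- switch(
    config$family,
    LDA = {
      fit <- MASS::lda(train_x, grouping = y)
      as.numeric(predict(fit, test_x)$posterior[, "malignant"])
    },
    KNN = {
      k <- min(config$K, nrow(train_x))
      apply(test_x, 1L, function(q) {
        d <- sqrt(colSums((t(train_x) - q)^2))
        mean(y[order(d)[seq_len(k)]] == "malignant")
      })
    },
    LSVM = ,
    GSVM = {
      gam <- if (config$family == "GSVM") median_heuristic_gamma(train_x)
             else 1 / ncol(train_x)
      fit <- with_seed(seed, e1071::svm(
        train_x, y, kernel = if (config$family == "GSVM") "radial" else "linear",
        cost = config$C, gamma = gam, probability = TRUE, scale = FALSE))
      pr <- predict(fit, test_x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "malignant"])
    },
    MLP = {
      y01 <- as.numeric(y == "malignant")
      fit <- with_seed(seed, nnet::nnet(
        x = train_x, y = y01, size = config$mlp_size, entropy = TRUE,
        decay = config$mlp_decay, maxit = config$mlp_maxit, trace = FALSE))
      as.numeric(predict(fit, test_x))
    }
  )
  pmin(pmax(score, 0), 1)
}

#' Bundle lesion data for cross-validated evaluation
#'
#' A feature source is either cube-based (the honest setting: the 3D-PCA is
#' refit on the training lesions of every fold and held-out lesions are
#' projected) or feature-based (a fixed feature matrix; used where the PCA
#' step is out of scope or already applied).
#'
#' @param labels Lesion class labels (`"benign"` / `"malignant"`).
#' @param cubes List of `reflectivity_cube`s (cube-based source).
#' @param features Feature matrix (feature-based source).
#' @param ids Lesion identifiers.
#' @param subtypes,sites Optional metadata vectors aligned with `labels`.
#' @param k_final,threshold,target_depth_samples 3D-PCA settings for
#'   cube-based sources.
#' @return Object of class `feature_source`.
#' @export
feature_source <- function(labels, cubes = NULL, features = NULL, ids = NULL,
                           subtypes = NULL, sites = NULL, k_final = 6L,
                           threshold = 0.80, target_depth_samples = 20L) {
  labels <- as_class_factor(labels)
  if (is.null(cubes) == is.null(features))
    stop("supply exactly one of cubes or features")
  n <- length(labels)
  if (!is.null(cubes) && length(cubes) != n)
    stop("cubes and labels lengths differ")
  if (!is.null(features) && nrow(features) != n)
    stop("features and labels lengths differ")
  if (is.null(ids)) ids <- sprintf("L%03d", seq_len(n))
  structure(list(labels = labels, cubes = cubes,
                 features = if (is.null(features)) NULL else as.matrix(features),
                 ids = ids, subtypes = subtypes, sites = sites,
                 k_final = k_final, threshold = threshold,
                 target_depth_samples = target_depth_samples),
            class = "feature_source")
}

n_lesions <- function(source) length(source$labels)

#' Per-fold train/test features for leave-one-out evaluation
#'
#' For cube-based sources each fold refits the full two-stage 3D-PCA on the
#' training lesions and projects the held-out lesion with the training
#' loadings only, so no test information leaks into the feature extraction.
#' `leak_pca = TRUE` deliberately fits the PCA on all lesions first — a
#' diagnostic mode used to demonstrate that the guard matters, never for
#' reported results.
#'
#' @param source A [feature_source()].
#' @param leak_pca Diagnostic leaky variant (cube sources only).
#' @return List of folds, each `list(train_x, train_y, test_x)`.
#' @export
fold_features <- function(source, leak_pca = FALSE) {
  stopifnot(inherits(source, "feature_source"))
  n <- n_lesions(source)
  if (n < 3L) stop("need at least 3 lesions")
  if (is.null(source$cubes) || leak_pca) {
    feats <- if (!is.null(source$features)) source$features else
      extract_features(source$cubes, k_final = source$k_final,
                       threshold = source$threshold,
                       target_depth_samples = source$target_depth_samples)$features
    return(lapply(seq_len(n), function(i) {
      list(train_x = feats[-i, , drop = FALSE],
           train_y = source$labels[-i],
           test_x = feats[i, , drop = FALSE])
    }))
  }
  lapply(seq_len(n), function(i) {
    model <- extract_features(source$cubes[-i], k_final = source$k_final,
                              threshold = source$threshold,
                              target_depth_samples = source$target_depth_samples)
    list(train_x = model$features, train_y = source$labels[-i],
         test_x = project_features(model, source$cubes[i]))
  })
}

#' Leave-one-out cross-validated malignancy scores
#'
#' One fold per lesion: the 3D-PCA (for cube sources) and the classifier are
#' fit on the remaining lesions and the held-out lesion is scored. Folds
#' whose training set contains a single class are recorded and skipped with
#' a warning.
#'
#' @param config A [classifier_config()].
#' @param source A [feature_source()].
#' @param seed Base seed; per-fold seeds are derived from it.
#' @param folds Optional precomputed [fold_features()] (reused across
#'   configurations during searches).
#' @param leak_pca Diagnostic leaky variant, see [fold_features()].
#' @return Object of class `cv_result`: data frame `scores` with one row
#'   per lesion (`id`, `label`, `score`, `fold`), plus the config.
#' @export
loocv <- function(config, source, seed = 1L, folds = NULL, leak_pca = FALSE) {
  stopifnot(inherits(source, "feature_source"))
  n <- n_lesions(source)
  if (length(unique(source$labels)) < 2L)
    stop("both classes must be present")
  if (is.null(folds)) folds <- fold_features(source, leak_pca = leak_pca)
  score <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    fo <- folds[[i]]
    if (length(unique(fo$train_y)) < 2L) {
      skipped <- c(skipped, i)
      next
    }
    score[i] <- train_and_score(config, fo$train_x, fo$train_y, fo$test_x,
                                seed = seed + i)
  }
  if (length(skipped))
    warning(sprintf("%d fold(s) had single-class training sets and were skipped",
                    length(skipped)))
  structure(
    list(scores = data.frame(id = source$ids, label = source$labels,
                             score = score, fold = seq_len(n),
                             stringsAsFactors = FALSE),
         config = config, skipped = skipped),
    class = "cv_result"
  )
}

result_scores <- function(result) {
  if (inherits(result, "cv_result")) result$scores$score else as.numeric(result)
}
result_labels <- function(result, labels = NULL) {
  if (inherits(result, "cv_result")) result$scores$label
  else as_class_factor(labels)
}

#' Confusion counts and sensitivity/specificity at a score cutoff
#'
#' A lesion is called positive when its malignancy score strictly exceeds
#' the cutoff. Sensitivity is `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`; either is `NA` when its class is absent.
#'
#' @param result A `cv_result` or numeric score vector.
#' @param labels Class labels (ignored for `cv_result`).
#' @param cutoff Malignancy cutoff (default 0.5, positive when score > 0.5).
#' @return List with `TP`, `FP`, `TN`, `FN`, `sensitivity`, `specificity`.
#' @export
confusion_at_cutoff <- function(result, labels = NULL, cutoff = 0.5) {
  scores <- result_scores(result)
  y <- result_labels(result, labels)
  stopifnot(length(scores) == length(y))
  pos <- scores > cutoff
  mal <- y == "malignant"
  tp <- sum(pos & mal); fn <- sum(!pos & mal)
  fp <- sum(pos & !mal); tn <- sum(!pos & !mal)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Receiver operating characteristic curve and AUC
#'
#' Thresholds at every distinct score plus the extremes, giving a curve with
#' endpoints (0, 0) and (1, 1); the AUC is computed by the trapezoidal rule
#' and equals the pairwise concordance probability with ties counted one
#' half.
#'
#' @param result A `cv_result` or numeric score vector.
#' @param labels Class labels (ignored for `cv_result`).
#' @return Object of class `roc_curve`: data frame `points` (`threshold`,
#'   `sensitivity`, `fpr`) and `auc`.
#' @export
roc_curve <- function(result, labels = NULL) {
  scores <- result_scores(result)
  y <- result_labels(result, labels)
  mal <- y == "malignant"
  n1 <- sum(mal); n0 <- sum(!mal)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(thr, function(t) mean(scores[mal] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!mal] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  structure(
    list(points = data.frame(threshold = thr, sensitivity = sens, fpr = fpr),
         auc = auc),
    class = "roc_curve"
  )
}

# rank-based AUC (identical to the trapezoid value; used in bootstraps)
auc_rank <- function(scores, mal) {
  n1 <- sum(mal); n0 <- sum(!mal)
  r <- rank(scores)
  (sum(r[mal]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimum ROC operating point by the Youden index
#'
#' Maximizes sensitivity + specificity - 1; ties are broken toward the
#' point with higher sensitivity.
#'
#' @param roc A [roc_curve()].
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
optimum_point <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  youden <- p$sensitivity - p$fpr
  best <- which(youden == max(youden))
  best <- best[which.max(p$sensitivity[best])]
  list(threshold = p$threshold[best], sensitivity = p$sensitivity[best],
       specificity = 1 - p$fpr[best], youden = youden[best])
}

all_masks <- function(k) {
  stopifnot(k >= 1L, k <= 8L)
  m <- as.matrix(expand.grid(rep(list(0:1), k)))[-1, , drop = FALSE]
  m[, rev(seq_len(k)), drop = FALSE]   # PC1 varies slowest
}

mask_string <- function(mask) paste0(mask, collapse = "")

# sd of sensitivity/specificity over stratified bootstrap resamples of the
# LOO scores (the reported "+/-" uncertainty)
boot_operating_sd <- function(scores, labels, cutoff, n_boot = 200L,
                              seed = 1L) {
  mal <- labels == "malignant"
  i1 <- which(mal); i0 <- which(!mal)
  with_seed(seed, {
    stats <- vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      cm <- confusion_at_cutoff(scores[idx], labels[idx], cutoff)
      c(cm$sensitivity, cm$specificity)
    }, numeric(2))
    c(sens_sd = sd(stats[1, ]), spec_sd = sd(stats[2, ]))
  })
}

#' Exhaustive classifier x PC-subset search under LOO-CV
#'
#' Evaluates every nonempty component mask for every classifier family and
#' hyperparameter value by leave-one-out AUC, and returns the best
#' configuration per family (ties broken by fewer components, then
#' lexicographic mask), ranked by AUC. The per-fold features are computed
#' once and shared across all configurations.
#'
#' @param source A [feature_source()].
#' @param families Classifier families to search.
#' @param k_grid KNN neighbor counts.
#' @param c_grid SVM margin factors (the full study grid is
#'   `seq(0.1, 4, by = 0.1)`).
#' @param seed Base seed.
#' @param folds Optional precomputed [fold_features()].
#' @param boot_sd Also attach bootstrap standard deviations of the optimum
#'   sensitivity/specificity.
#' @return Data frame with one row per family: `family`, `hyper`, `mask`,
#'   `n_pcs`, `auc`, `sensitivity`, `specificity` (at the Youden point),
#'   optionally `sens_sd`, `spec_sd`.
#' @export
search_pc_combinations <- function(source,
                                   families = c("LDA", "KNN", "LSVM",
                                                "GSVM", "MLP"),
                                   k_grid = c(1, 3, 5, 7),
                                   c_grid = seq(0.1, 4, by = 0.1),
                                   seed = 1L, folds = NULL, boot_sd = TRUE) {
  if (length(families) == 0L) stop("at least one classifier family required")
  stopifnot(inherits(source, "feature_source"))
  if (is.null(folds)) folds <- fold_features(source)
  k_final <- ncol(folds[[1]]$train_x)
  if (k_final > 8L) stop("exhaustive mask search requires <= 8 components")
  masks <- all_masks(k_final)

  best_rows <- lapply(families, function(fam) {
    hypers <- switch(fam, LDA = list(NULL), MLP = list(NULL),
                     KNN = as.list(k_grid), LSVM = as.list(c_grid),
                     GSVM = as.list(c_grid))
    best <- NULL
    for (h in hypers) {
      for (m in seq_len(nrow(masks))) {
        mask <- masks[m, ]
        config <- classifier_config(
          fam, K = if (fam == "KNN") h else NULL,
          C = if (fam %in% c("LSVM", "GSVM")) h else NULL, mask = mask)
        res <- loocv(config, source, seed = seed, folds = folds)
        auc <- roc_curve(res)$auc
        cand <- list(config = config, auc = auc, res = res,
                     n_pcs = sum(mask), mask = mask_string(mask),
                     hyper = if (is.null(h)) NA_real_ else h)
        if (is.null(best) ||
            auc > best$auc + 1e-12 ||
            (abs(auc - best$auc) <= 1e-12 &&
             (cand$n_pcs < best$n_pcs ||
              (cand$n_pcs == best$n_pcs && cand$mask < best$mask))))
          best <- cand
      }
    }
    opt <- optimum_point(roc_curve(best$res))
    row <- data.frame(family = fam, hyper = best$hyper, mask = best$mask,
                      n_pcs = best$n_pcs, auc = best$auc,
                      sensitivity = opt$sensitivity,
                      specificity = opt$specificity,
                      stringsAsFactors = FALSE)
    if (boot_sd) {
      bsd <- boot_operating_sd(best$res$scores$score, best$res$scores$label,
                               cutoff = opt$threshold, seed = seed)
      row$sens_sd <- bsd[["sens_sd"]]
      row$spec_sd <- bsd[["spec_sd"]]
    }
    row
  })
  out <- do.call(rbind, best_rows)
  out[order(-out$auc, out$n_pcs, out$mask), , drop = FALSE]
}

#' Percent correct classifications per diagnosis subtype
#'
#' Malignant subtypes count as correct when the malignancy score exceeds
#' the cutoff, benign subtypes when it does not. Percentages are rounded to
#' integers (half away from zero). Subtypes with no lesions are reported as
#' missing.
#'
#' @param result A `cv_result` or score vector.
#' @param subtypes Subtype label per lesion.
#' @param labels Class labels (ignored for `cv_result`).
#' @param cutoff Malignancy cutoff.
#' @return Data frame: `subtype`, `class`, `n`, `n_correct`, `pct_correct`.
#' @export
per_class_accuracy <- function(result, subtypes, labels = NULL,
                               cutoff = 0.5) {
  scores <- result_scores(result)
  y <- result_labels(result, labels)
  stopifnot(length(subtypes) == length(scores))
  correct <- ifelse(y == "malignant", scores > cutoff, scores <= cutoff)
  out <- do.call(rbind, lapply(unique(subtypes), function(st) {
    sel <- subtypes == st
    n <- sum(sel)
    nc <- sum(correct[sel])
    data.frame(subtype = st, class = as.character(y[sel][1]), n = n,
               n_correct = nc,
               pct_correct = if (n > 0) round_half_away(100 * nc / n)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a power-law learning curve to error rates
#'
#' Least-squares fit of `e(n) = a + b * n^(-alpha)` with the asymptotic
#' error `a` constrained nonnegative; `a` is the extrapolated error for
#' arbitrarily large cohorts. Fitted by multi-start profile initialization
#' over `alpha` followed by bound-constrained quasi-Newton refinement.
#'
#' @param n Training-set sizes.
#' @param e Mean error rate at each size.
#' @return List with `a`, `b`, `alpha`, `fitted`, `rss`, `converged`.
#' @export
fit_learning_curve <- function(n, e) {
  stopifnot(length(n) == length(e), length(n) >= 3L, all(n > 0))
  obj <- function(par) sum((e - (par[1] + par[2] * n^(-par[3])))^2)
  starts <- lapply(c(0.25, 0.5, 1, 1.5, 2), function(al) {
    z <- n^(-al)
    fit <- stats::lm.fit(cbind(1, z), e)
    a <- max(0, fit$coefficients[1])
    b <- if (fit$coefficients[1] < 0)
      sum(e * z) / sum(z^2) else fit$coefficients[2]
    c(a, b, al)
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0, obj, method = "L-BFGS-B",
            lower = c(0, -Inf, 0.05), upper = c(Inf, Inf, 3)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(list(a = NA_real_, b = NA_real_, alpha = NA_real_,
                fitted = rep(NA_real_, length(n)), rss = NA_real_,
                converged = FALSE))
  # parsimony guard: on a flat curve (a, b, alpha) are unidentifiable
  # (n^-alpha is nearly constant over the observed range) and the power law
  # happily extrapolates sampling noise; keep it only when it beats the
  # constant model by an F-test on its two extra parameters
  rss_const <- sum((e - mean(e))^2)
  df2 <- length(n) - 3L
  f_stat <- if (best$value <= 0 || df2 < 1L) Inf
            else ((rss_const - best$value) / 2) / (best$value / df2)
  if (is.finite(f_stat) && f_stat < stats::qf(0.95, 2, df2))
    return(list(a = max(0, mean(e)), b = 0, alpha = NA_real_,
                fitted = rep(mean(e), length(n)), rss = rss_const,
                converged = TRUE))
  list(a = best$par[1], b = best$par[2], alpha = best$par[3],
       fitted = best$par[1] + best$par[2] * n^(-best$par[3]),
       rss = best$value, converged = TRUE)
}

#' Learning-curve extrapolation by random repeated sampling
#'
#' Estimates the mean leave-one-out error rate at several training-set
#' sizes by stratified random repeated subsampling, fits the power law
#' `e(n) = a + b n^(-alpha)`, and reports the extrapolated asymptotic error
#' `a`.
#'
#' @param config A [classifier_config()].
#' @param source A [feature_source()].
#' @param subset_sizes At least 3 sizes below the cohort size.
#' @param reps Subsamples per size (>= 10).
#' @param seed Seed; the whole procedure is deterministic given it.
#' @param cutoff Malignancy cutoff defining the error rate.
#' @return List with `curve` (data frame `n`, `error`), `fit`, and
#'   `extrapolated_error` (= fitted `a`).
#' @export
rrs_extrapolate <- function(config, source, subset_sizes, reps = 20L,
                            seed = 1L, cutoff = 0.5) {
  n <- n_lesions(source)
  subset_sizes <- sort(unique(as.integer(subset_sizes)))
  if (length(subset_sizes) < 3L || any(subset_sizes >= n))
    stop("need >= 3 subset sizes below the cohort size")
  if (reps < 10L) stop("reps must be >= 10")
  mal <- which(source$labels == "malignant")
  ben <- which(source$labels == "benign")
  frac_mal <- length(mal) / n
  with_seed(seed, {
    errs <- vapply(subset_sizes, function(ns) {
      mean(vapply(seq_len(reps), function(r) {
        n1 <- max(2L, min(length(mal) , round(ns * frac_mal)))
        n0 <- max(2L, min(length(ben), ns - n1))
        idx <- c(sample(mal, n1), sample(ben, n0))
        sub <- subset_source(source, idx)
        res <- loocv(config, sub, seed = sample.int(2^30, 1L))
        sc <- res$scores
        ok <- !is.na(sc$score)
        mean((sc$score[ok] > cutoff) != (sc$label[ok] == "malignant"))
      }, numeric(1)))
    }, numeric(1))
    fit <- fit_learning_curve(subset_sizes, errs)
    list(curve = data.frame(n = subset_sizes, error = errs), fit = fit,
         extrapolated_error = fit$a)
  })
}

# restrict a feature source to a subset of lesions
subset_source <- function(source, idx) {
  feature_source(
    labels = source$labels[idx],
    cubes = if (!is.null(source$cubes)) source$cubes[idx] else NULL,
    features = if (!is.null(source$features))
      source$features[idx, , drop = FALSE] else NULL,
    ids = source$ids[idx],
    subtypes = source$subtypes[idx], sites = source$sites[idx],
    k_final = source$k_final, threshold = source$threshold,
    target_depth_samples = source$target_depth_samples)
}

#' Bootstrap comparison of two AUCs
#'
#' Stratified bootstrap of the AUC difference between two scored lesion
#' sets; two-sided p-value. When the two results cover the same lesions
#' (equal length and identical labels) the resampling is paired, so a
#' result compared with itself gives p = 1.
#'
#' @param scores_a,labels_a,scores_b,labels_b The two scored sets.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed.
#' @param paired Force paired/independent resampling; `NULL` decides
#'   automatically.
#' @return List with `p_value`, `auc_a`, `auc_b`, `diff`, `paired`.
#' @export
compare_roc <- function(scores_a, labels_a, scores_b, labels_b,
                        n_boot = 2000L, seed = 1L, paired = NULL) {
  la <- as_class_factor(labels_a); lb <- as_class_factor(labels_b)
  mal_a <- la == "malignant"; mal_b <- lb == "malignant"
  if (!any(mal_a) || all(mal_a) || !any(mal_b) || all(mal_b))
    stop("both classes must be present in each result")
  if (is.null(paired))
    paired <- length(la) == length(lb) && all(la == lb)
  auc_a <- auc_rank(scores_a, mal_a)
  auc_b <- auc_rank(scores_b, mal_b)
  i1a <- which(mal_a); i0a <- which(!mal_a)
  i1b <- which(mal_b); i0b <- which(!mal_b)
  d <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    if (paired) {
      s1 <- sample(i1a, replace = TRUE); s0 <- sample(i0a, replace = TRUE)
      idx <- c(s1, s0)
      m <- c(rep(TRUE, length(s1)), rep(FALSE, length(s0)))
      auc_rank(scores_a[idx], m) - auc_rank(scores_b[idx], m)
    } else {
      ia <- c(sample(i1a, replace = TRUE), sample(i0a, replace = TRUE))
      ib <- c(sample(i1b, replace = TRUE), sample(i0b, replace = TRUE))
      ma <- c(rep(TRUE, length(i1a)), rep(FALSE, length(i0a)))
      mb <- c(rep(TRUE, length(i1b)), rep(FALSE, length(i0b)))
      auc_rank(scores_a[ia], ma) - auc_rank(scores_b[ib], mb)
    }
  }, numeric(1)))
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  list(p_value = p, auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b,
       paired = paired)
}

#' Per-frequency reproducibility variance across repeated sweeps
#'
#' For repeated measurements of one skin site, computes the relative
#' variance of the magnitude spectrum at each frequency (variance as a
#' percent of the squared mean), its maximum over frequency, and the
#' stability of the spectral-minimum position across repeats.
#'
#' @param signals List of `uwb_signal`s (>= 2 repeats on one grid).
#' @return List with `freq_ghz`, `rel_var_pct`, `max_pct`,
#'   `min_positions_ghz` (global-minimum abscissa per repeat), and
#'   `min_position_sd_ghz`.
#' @export
reproducibility_variance <- function(signals) {
  if (length(signals) < 2L) stop("need at least 2 repeated sweeps")
  f <- signals[[1]]$freq_ghz
  for (s in signals)
    if (length(s$freq_ghz) != length(f) || any(abs(s$freq_ghz - f) > 1e-9))
      stop("repeats must share one frequency grid")
  mags <- vapply(signals, function(s) abs(s$s11), numeric(length(f)))
  mu <- rowMeans(mags)
  rel <- 100 * apply(mags, 1L, var) / mu^2
  mins <- f[apply(mags, 2L, which.min)]
  list(freq_ghz = f, rel_var_pct = rel, max_pct = max(rel),
       min_positions_ghz = mins, min_position_sd_ghz = sd(mins))
}
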