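mk_labels <- function(n1, n0) {
  factor(rep(c("malignant", "benign"), c(n1, n0)),
         levels = c("benign", "malignant"))
}

test_that("classifier configs validate their hyperparameters", {
  expect_error(classifier_config("KNN", mask = c(1, 1)), "K")
  expect_error(classifier_config("LDA", K = 3, mask = c(1, 1)), "only")
  expect_error(classifier_config("LSVM", mask = c(1, 1)), "C > 0")
  expect_error(classifier_config("LDA", mask = c(0, 0)), "mask")
})

test_that("all five families separate linearly separated training data", {
  set.seed(51)
  train_x <- cbind(c(rnorm(20, 3, 0.3), rnorm(20, -3, 0.3)), rnorm(40))
  train_y <- mk_labels(20, 20)
  test_x <- rbind(c(3, 0), c(-3, 0))
  for (fam in c("LDA", "KNN", "LSVM", "GSVM", "MLP")) {
    cfg <- classifier_config(fam, K = if (fam == "KNN") 3 else NULL,
                             C = if (fam %in% c("LSVM", "GSVM")) 1 else NULL,
                             mask = c(1, 1))
    sc <- train_and_score(cfg, train_x, train_y, test_x, seed = 5)
    expect_gt(sc[1], 0.5)
    expect_lt(sc[2], 0.5)
    expect_true(all(sc >= 0 & sc <= 1))
  }
  expect_error(train_and_score(classifier_config("LDA", mask = c(1, 1)),
                               train_x, rep("benign", 40), test_x),
               "both classes")
})

test_that("a K=1 neighbor coincident with a benign lesion scores zero", {
  train_x <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  train_y <- factor(c("benign", "malignant"), levels = c("benign", "malignant"))
  cfg <- classifier_config("KNN", K = 1, mask = c(1, 1))
  expect_equal(train_and_score(cfg, train_x, train_y, matrix(c(0, 0), 1)), 0)
  expect_equal(train_and_score(cfg, train_x, train_y, matrix(c(5, 5), 1)), 1)
})

test_that("LDA posterior approximates the closed-form Bayes posterior", {
  set.seed(52)
  n <- 500
  xt <- matrix(c(-1.5, -0.5, 0, 0.5, 1.5), ncol = 1)
  train_y <- mk_labels(n, n)
  # expected posterior over training draws of n = 500 per class
  sc <- rowMeans(vapply(1:10, function(r) {
    train_x <- matrix(c(rnorm(n, 1), rnorm(n, -1)), ncol = 1)
    train_and_score(classifier_config("LDA", mask = 1),
                    train_x, train_y, xt)
  }, numeric(5)))
  bayes <- stats::plogis(2 * xt[, 1])   # unit variance, means +/-1
  expect_lt(max(abs(sc - bayes)), 0.02)
})

test_that("leave-one-out produces one fold per lesion, deterministically", {
  src <- small_cohort_source(contrast = 0.3, seed = 53L, nb = 5L, nm = 5L,
                             k_final = 3L)
  cfg <- classifier_config("LDA", mask = rep(1, 3))
  r1 <- loocv(cfg, src, seed = 2L)
  r2 <- loocv(cfg, src, seed = 2L)
  expect_equal(nrow(r1$scores), 10L)
  expect_equal(r1$scores$fold, 1:10)
  expect_false(any(is.na(r1$scores$score)))
  expect_identical(r1, r2)
})

test_that("the leakage guard changes held-out scores", {
  src <- small_cohort_source(contrast = 0.1, seed = 54L, nb = 5L, nm = 5L,
                             k_final = 3L)
  cfg <- classifier_config("LDA", mask = rep(1, 3))
  honest <- loocv(cfg, src, seed = 2L)
  leaky <- loocv(cfg, src, seed = 2L, leak_pca = TRUE)
  expect_gt(max(abs(honest$scores$score - leaky$scores$score)), 1e-6)
})

test_that("confusion counts follow the strict cutoff and a counting oracle", {
  cm <- confusion_at_cutoff(c(0.9, 0.1), mk_labels(1, 1))
  expect_equal(unlist(cm[c("TP", "FP", "TN", "FN")]),
               c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  # all scores equal to the cutoff: strict > gives zero positives
  cm0 <- confusion_at_cutoff(rep(0.5, 6), mk_labels(3, 3))
  expect_equal(cm0$TP + cm0$FP, 0L)
  # random case vs. brute-force loop
  set.seed(55)
  sc <- runif(50); y <- mk_labels(20, 30)[sample(50)]
  cm1 <- confusion_at_cutoff(sc, y, cutoff = 0.4)
  tp <- fp <- tn <- fn <- 0L
  for (i in 1:50) {
    if (sc[i] > 0.4 && y[i] == "malignant") tp <- tp + 1L
    if (sc[i] > 0.4 && y[i] == "benign") fp <- fp + 1L
    if (sc[i] <= 0.4 && y[i] == "benign") tn <- tn + 1L
    if (sc[i] <= 0.4 && y[i] == "malignant") fn <- fn + 1L
  }
  expect_equal(unlist(cm1[c("TP", "FP", "TN", "FN")]),
               c(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_equal(cm1$TP + cm1$FP + cm1$TN + cm1$FN, 50L)
})

test_that("ROC endpoints, perfect and null AUC behave as expected", {
  y <- mk_labels(10, 10)
  perfect <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  roc <- roc_curve(perfect, y)
  expect_equal(roc$auc, 1)
  p <- roc$points
  expect_equal(c(p$sensitivity[1], p$fpr[1]), c(0, 0))
  expect_equal(c(p$sensitivity[nrow(p)], p$fpr[nrow(p)]), c(1, 1))
  set.seed(56)
  n <- 400
  ynull <- mk_labels(n / 2, n / 2)[sample(n)]
  auc_null <- roc_curve(runif(n), ynull)$auc
  se <- sqrt((n / 2 + n / 2 + 1) / (12 * (n / 2)^2))
  expect_lt(abs(auc_null - 0.5), 3 * se)
  expect_error(roc_curve(runif(5), factor(rep("benign", 5),
                                          levels = c("benign", "malignant"))),
               "both classes")
})

test_that("trapezoid AUC equals brute-force pairwise concordance with ties", {
  set.seed(57)
  sc <- round(runif(20), 1)               # duplicates force ties
  y <- mk_labels(8, 12)[sample(20)]
  auc <- roc_curve(sc, y)$auc
  mal <- which(y == "malignant"); ben <- which(y == "benign")
  conc <- 0
  for (i in mal) for (j in ben)
    conc <- conc + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  expect_equal(auc, conc / (length(mal) * length(ben)), tolerance = 1e-12)
})

test_that("the optimum point maximizes Youden with ties toward sensitivity", {
  y <- mk_labels(5, 5)
  perfect <- c(rep(0.9, 5), rep(0.1, 5))
  opt <- optimum_point(roc_curve(perfect, y))
  expect_equal(c(opt$sensitivity, opt$specificity), c(1, 1))
  # constant scores: all Youden zero; tie rule picks the all-positive end
  flat <- optimum_point(roc_curve(rep(0.5, 10), y))
  expect_equal(flat$sensitivity, 1)
  expect_equal(flat$youden, 0)
  # enumeration oracle on a small random curve
  set.seed(58)
  sc <- runif(14); yy <- mk_labels(6, 8)[sample(14)]
  opt2 <- optimum_point(roc_curve(sc, yy))
  best <- -Inf; best_sens <- -Inf
  for (t in c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)) {
    sens <- mean(sc[yy == "malignant"] >= t)
    spec <- mean(sc[yy == "benign"] < t)
    j <- sens + spec - 1
    if (j > best + 1e-12 || (abs(j - best) <= 1e-12 && sens > best_sens)) {
      best <- j; best_sens <- sens
    }
  }
  expect_equal(opt2$youden, best, tolerance = 1e-12)
  expect_equal(opt2$sensitivity, best_sens, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(59)
  sc <- runif(30); y <- mk_labels(12, 18)[sample(30)]
  a1 <- roc_curve(sc, y)$auc
  a2 <- roc_curve(stats::qlogis(sc * 0.98 + 0.01), y)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("the subset search finds the planted informative component", {
  set.seed(60)
  n <- 40
  y <- mk_labels(n / 2, n / 2)
  x <- matrix(rnorm(n * 3), n)
  x[, 2] <- x[, 2] + ifelse(y == "malignant", 2.4, -2.4)   # signal in PC2
  src <- feature_source(labels = y, features = x)
  tab <- search_pc_combinations(src, k_grid = 3, c_grid = 1, seed = 3L,
                                boot_sd = FALSE)
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$family, c("LDA", "KNN", "LSVM", "GSVM", "MLP"))
  expect_true(all(substr(tab$mask, 2, 2) == "1"))
  expect_true(all(tab$auc > 0.9))
})

test_that("per-subtype accuracies round half away from zero", {
  subtypes <- c(rep("squamous cell carcinoma", 8), rep("melanocytic nevus", 4))
  y <- mk_labels(8, 4)
  sc <- c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.2,   # 7/8 correct
          0.1, 0.1, 0.1, 0.1)                       # 4/4 correct
  acc <- per_class_accuracy(sc, subtypes, y)
  scc <- acc[acc$subtype == "squamous cell carcinoma", ]
  expect_equal(scc$pct_correct, 88)                  # 87.5 rounds to 88
  expect_equal(acc[acc$subtype == "melanocytic nevus", "pct_correct"], 100)
  # brute-force per-subtype loop oracle
  set.seed(61)
  n <- 60
  sub <- sample(c("a", "b", "c"), n, replace = TRUE)
  y2 <- mk_labels(30, 30)[sample(n)]
  sc2 <- runif(n)
  acc2 <- per_class_accuracy(sc2, sub, y2)
  for (s in unique(sub)) {
    sel <- sub == s
    correct <- sum(ifelse(y2[sel] == "malignant", sc2[sel] > 0.5,
                          sc2[sel] <= 0.5))
    expect_equal(acc2$n_correct[acc2$subtype == s], correct)
    expect_equal(acc2$pct_correct[acc2$subtype == s],
                 floor(100 * correct / sum(sel) + 0.5))
  }
})

test_that("learning-curve fits recover planted power-law parameters", {
  n <- c(20, 30, 45, 70, 100, 150, 220, 330)
  set.seed(62)
  for (truth in list(c(a = 0.08, b = 2.0, alpha = 0.7),
                     c(a = 0.15, b = 1.2, alpha = 0.5),
                     c(a = 0.05, b = 3.0, alpha = 1.0))) {
    e <- truth["a"] + truth["b"] * n^(-truth["alpha"]) + rnorm(length(n), 0, 0.004)
    fit <- fit_learning_curve(n, e)
    expect_true(fit$converged)
    expect_lt(abs(fit$a - truth["a"]) / truth["a"], 0.20)
  }
})

test_that("RRS extrapolation plateaus on size-independent error", {
  set.seed(63)
  n <- 80
  y <- mk_labels(n / 2, n / 2)
  x <- matrix(rnorm(n * 3), n)               # pure noise: error ~ 0.5
  src <- feature_source(labels = y, features = x)
  cfg <- classifier_config("LDA", mask = rep(1, 3))
  rrs <- rrs_extrapolate(cfg, src, subset_sizes = c(16, 24, 36, 54), reps = 10,
                         seed = 4L)
  expect_true(all(abs(rrs$curve$error - 0.5) < 0.15))
  expect_lt(abs(rrs$extrapolated_error - mean(rrs$curve$error)), 0.1)
  expect_lt(abs(rrs$fit$b), 0.1)
  rrs2 <- rrs_extrapolate(cfg, src, subset_sizes = c(16, 24, 36, 54),
                          reps = 10, seed = 4L)
  expect_identical(rrs, rrs2)
  expect_error(rrs_extrapolate(cfg, src, subset_sizes = c(16, 24), reps = 10),
               "3 subset sizes")
  expect_error(rrs_extrapolate(cfg, src, subset_sizes = c(16, 24, 36),
                               reps = 5), "reps")
})

test_that("ROC comparison: self-comparison gives p = 1, separation rejects", {
  set.seed(64)
  y <- mk_labels(20, 20)
  good <- c(runif(20, 0.7, 1), runif(20, 0, 0.3))
  self <- compare_roc(good, y, good, y, n_boot = 500, seed = 5L)
  expect_true(self$paired)
  expect_equal(self$p_value, 1)
  null_sc <- runif(40)
  cmp <- compare_roc(good, y, null_sc, y[sample(40)], n_boot = 1000, seed = 6L)
  expect_lt(cmp$p_value, 0.01)
  cmp2 <- compare_roc(good, y, null_sc, y[sample(40)], n_boot = 1000, seed = 6L)
  expect_equal(cmp$p_value, cmp2$p_value)
})

test_that("reproducibility variance is zero for identical repeats and scale-free", {
  f <- seq(12, 110, length.out = 60)
  mk <- function(s11) structure(list(freq_ghz = f, s11 = s11),
                                class = "uwb_signal")
  base <- mk(0.5 * exp(-1i * f / 9))
  same <- reproducibility_variance(list(base, base, base))
  expect_equal(same$max_pct, 0)
  set.seed(65)
  reps <- lapply(1:10, function(i)
    mk(base$s11 + complex(real = rnorm(60, 0, 0.01),
                          imaginary = rnorm(60, 0, 0.01))))
  rv <- reproducibility_variance(reps)
  scaled <- lapply(reps, function(s) { s$s11 <- 2 * s$s11; s })
  rv2 <- reproducibility_variance(scaled)
  expect_equal(rv$rel_var_pct, rv2$rel_var_pct, tolerance = 1e-12)
  expect_error(reproducibility_variance(reps[1]), "at least 2")
})

test_that("known injected noise is recovered from 50 repeats", {
  f <- seq(12, 110, length.out = 255)
  s_comp <- 0.02                     # per-component noise sd on unit signal
  set.seed(66)
  reps <- lapply(1:50, function(i)
    structure(list(freq_ghz = f,
                   s11 = 1 + complex(real = rnorm(255, 0, s_comp),
                                     imaginary = rnorm(255, 0, s_comp))),
              class = "uwb_signal"))
  rv <- reproducibility_variance(reps)
  # |1 + eps| ~ 1 + Re(eps): relative variance ~ s_comp^2
  expected <- 100 * s_comp^2
  expect_lt(abs(mean(rv$rel_var_pct) - expected) / expected, 0.3)
})
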