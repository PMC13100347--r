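toy_clinical <- function() {
  data.frame(er_status = 1, er_percent = 80, pr_status = 0,
             pr_percent = 5, cep17 = 2.1, her2_cep17_ratio = 4.4,
             pcr = 1, ris_cm = 0)
}

test_that("feature assembly produces the documented 99-vector", {
  tta <- simulate_tta_image(recovery_config(), 1L, seed = 2L)
  sna <- extract_sna_features(build_tissue_graph(tta, "STROMA"))
  dlps <- aggregate_dlps(c(0.3, 0.6), c("STROMA", "STROMA"))
  v <- assemble_features(sna, dlps, toy_clinical(), "STROMA")
  expect_length(v, 99L)
  expect_equal(names(v), patient_feature_names())
  expect_equal(unname(v["DLPS_mean"]), 0.45)
  expect_equal(unname(v["her2_cep17_ratio"]), 4.4)
  expect_false(attr(v, "dlps_missing"))
  # all-zero SNA from an empty graph is still a valid vector
  empty_sna <- extract_sna_features(
    build_tissue_graph(tta_image(matrix("S", 2, 2), "p"), "ITIL"))
  v0 <- assemble_features(empty_sna, dlps, toy_clinical(), "STROMA")
  expect_true(all(v0[1:91] == 0))
  # CSV round trip preserves column order and values
  path <- file.path(tempdir(), "feat.csv")
  utils::write.csv(t(v), path, row.names = FALSE)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(unlist(back[1, ]), v, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a missing clinical field is named in the error", {
  sna <- setNames(rep(0, 91), sna_feature_names())
  clin <- toy_clinical()
  clin$cep17 <- NULL
  expect_error(assemble_features(sna, NULL, clin, "TUMOR"), "cep17")
})

test_that("LASSO selection shrinks fully at huge penalties and finds
           planted signal", {
  set.seed(10)
  n <- 80L
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  y <- as.integer(plogis(2 * X[, 3] - 1.5 * X[, 7]) > runif(n))
  Xs <- scale(X)
  # full shrinkage at lambda -> infinity
  full <- lasso_select(Xs, y, model_config(lasso_lambda = c(50, 20, 10)))
  expect_true(all(full$coefficients == 0))
  expect_length(full$selected, 0L)
  sel <- lasso_select(Xs, y, model_config(seed = 2L))
  expect_true(all(c(3L, 7L) %in% sel$selected))
  expect_equal(unname(sign(sel$coefficients[3])), 1)
  expect_equal(unname(sign(sel$coefficients[7])), -1)
})

test_that("constant columns are forced to zero with a warning", {
  set.seed(11)
  X <- cbind(sig = rnorm(60), flat = rep(2, 60))
  y <- as.integer(X[, 1] > 0)
  X[, 1] <- scale(X[, 1])
  expect_warning(res <- lasso_select(X, y, model_config()), "flat")
  expect_equal(unname(res$coefficients["flat"]), 0)
})

test_that("duplicated informative columns keep total coefficient mass", {
  set.seed(12)
  n <- 100L
  x <- rnorm(n)
  y <- as.integer(plogis(3 * x) > runif(n))
  X1 <- scale(cbind(a = x, b = x, n1 = rnorm(n), n2 = rnorm(n)))
  X2 <- X1[, c(2, 1, 3, 4)]    # swap the duplicates
  r1 <- lasso_select(X1, y, model_config(seed = 5L))
  r2 <- lasso_select(X2, y, model_config(seed = 5L))
  mass1 <- sum(abs(r1$coefficients[c("a", "b")]))
  mass2 <- sum(abs(r2$coefficients[c("a", "b")]))
  expect_equal(mass1, mass2, tolerance = 1e-6)
  expect_gt(mass1, 0)
})

test_that("evaluation metrics match hand-computed cases", {
  # perfectly separated
  ev <- evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ev$auc, 1); expect_equal(ev$f1, 1)
  # all scores tied
  expect_equal(evaluate(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  # 3 of 4 concordant pairs
  expect_equal(evaluate(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(evaluate(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("rank AUC equals the Mann-Whitney statistic route", {
  set.seed(14)
  for (rep in 1:10) {
    y <- rep(c(0, 1), c(12, 9))
    s <- round(runif(21), 2)   # induces ties
    U <- unname(suppressWarnings(stats::wilcox.test(
      s[y == 1], s[y == 0], exact = FALSE)$statistic))
    expect_equal(evaluate(s, y)$auc, U / (9 * 12), tolerance = 1e-12)
  }
})

test_that("the DeLong test is symmetric and degenerate-safe", {
  set.seed(15)
  y <- rep(c(0, 1), each = 20)
  a <- plogis(y + rnorm(40)); b <- plogis(0.5 * y + rnorm(40))
  expect_warning(same <- delong_test(a, a, y), "identical")
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  ab <- delong_test(a, b, y); ba <- delong_test(b, a, y)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  # self-comparison p is exactly 1 (zero-variance guard)
  expect_warning(expect_equal(delong_test(b, b, y)$p, 1))
})

test_that("univariate screening: route choice, constants, BH ordering", {
  set.seed(16)
  g <- rep(c(0, 1), each = 10)
  feats <- data.frame(
    sep = c(rnorm(10), rnorm(10) + 10),     # fully separated
    noise = rnorm(20),
    flat = rep(1, 20),
    bin = c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8)))
  res <- univariate_tests(feats, g)
  expect_equal(res$test[res$feature == "sep"], "mann_whitney")
  expect_equal(res$test[res$feature == "bin"], "chisq")
  expect_equal(res$p_raw[res$feature == "flat"], 1)
  # fully separated groups attain the minimal normal-approximation p
  expect_lt(res$p_raw[res$feature == "sep"], 2e-4)
  # BH never lowers below raw and is monotone in the sorted order
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
})

test_that("Spearman association recovers monotone signals and flags
           constants", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(spearman_with_ris(x, x^2)$rho, 1)
  expect_equal(spearman_with_ris(x, -x)$rho, -1)
  expect_true(spearman_with_ris(rep(1, 5), x)$constant)
  # ties: matches the direct average-rank formula
  a <- c(1, 2, 2, 4, 7, 7); b <- c(3, 1, 4, 4, 9, 6)
  expect_equal(spearman_with_ris(a, b)$rho,
               stats::cor(rank(a), rank(b)), tolerance = 1e-12)
})

test_that("the classifier grid search separates separable toy data and
           stays near chance on shuffled labels", {
  set.seed(17)
  n <- 60L
  X <- cbind(a = c(rnorm(n / 2), rnorm(n / 2) + 3),
             b = c(rnorm(n / 2), rnorm(n / 2) - 3))
  y <- rep(c(0, 1), each = n / 2)
  cfg <- model_config(mlp_grid = list(hidden = list(16L), l2 = 1e-3),
                      mlp_epochs = 300L, seed = 3L)
  clf <- train_compartment_classifier(X, y, cfg)
  expect_gte(clf$cv_auc, 0.95)
  set.seed(18)
  clf0 <- train_compartment_classifier(X, sample(y), cfg)
  expect_gte(clf0$cv_auc, 0.3)
  expect_lte(clf0$cv_auc, 0.7)
  # repeated run with the same seed picks identical hyperparameters
  clf2 <- train_compartment_classifier(X, y, cfg)
  expect_identical(clf$hidden, clf2$hidden)
  expect_identical(clf$l2, clf2$l2)
  expect_equal(clf$cv_auc, clf2$cv_auc, tolerance = 1e-12)
})

test_that("fitting, predicting, methods and the manifest work end to end", {
  coh <- simulate_cohort(40L, recovery_config(), seed = 21L)
  sp <- split_cohort(coh, 0.25, seed = 22L)
  fit <- suppressWarnings(fit_response_model(
    sp$train, "STROMA", c("sna", "clinical"),
    config = light_config(seed = 2L)))
  expect_s3_class(fit, "pcr_model")
  expect_length(fit$feature_names, 97L)    # 91 SNA + 6 clinical
  p <- predict(fit, sp$test)
  expect_length(p, length(sp$test$patients))
  expect_true(all(p >= 0 & p <= 1))
  # matrix route equals cohort route
  Xte <- cbind(cohort_sna_matrix(sp$test, "STROMA", fit$gparams,
                                 fit$sparams),
               cohort_clinical_matrix(sp$test))
  expect_equal(unname(predict(fit, Xte)), unname(p), tolerance = 1e-12)
  expect_output(print(fit), "pcr_model")
  expect_named(coef(fit))
  expect_equal(length(residuals(fit)), fit$n)
  man <- file.path(tempdir(), "model.json")
  write_model_manifest(fit, man)
  j <- jsonlite::read_json(man)
  expect_equal(j$compartment, "STROMA")
  expect_true(length(j$lasso$selected) >= 1L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the sensitivity grid covers 9 cells and finds planted signal", {
  coh <- simulate_cohort(60L, recovery_config(), seed = 11L)
  sg <- suppressWarnings(sensitivity_grid(coh, compartments = "STROMA"))
  expect_equal(nrow(sg), 9L)
  expect_equal(nrow(unique(sg[, c("K", "P")])), 9L)
  expect_gt(mean(sg$mean_auc), 0.5)
  expect_true(all(sg$mean_auc > 0.4))
})

test_that("ablation evaluates every feasible fraction on the fixed
           held-out cohort", {
  coh <- simulate_cohort(80L, recovery_config(), seed = 31L)
  sp <- split_cohort(coh, 0.25, seed = 32L)
  ab <- suppressWarnings(ablation_run(
    sp$train, sp$test, fractions = c(0.5, 1.0),
    config = light_config(seed = 4L), seed = 33L))
  expect_equal(nrow(ab), 2L)
  expect_true(all(ab$auc >= 0 & ab$auc <= 1))
  expect_equal(ab$n_train[ab$fraction == 1], length(sp$train$patients))
  # full-fraction refit reproduces the direct fit bit for bit
  fit <- suppressWarnings(fit_response_model(
    sp$train, "STROMA", c("sna", "clinical"),
    config = light_config(seed = 4L)))
  direct <- evaluate(predict(fit, sp$test), cohort_labels(sp$test))
  expect_equal(ab$auc[ab$fraction == 1], direct$auc, tolerance = 1e-12)
})
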