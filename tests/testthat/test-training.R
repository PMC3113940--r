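# Dataset filtering, fitting, reduction and the evaluation statistics

mk_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(structure_id = "x", chain = "A", resnum = "1",
               s_w = r[[1]], s_m = r[[2]], ddG_M = as.numeric(r[[3]]),
               heme_protein = isTRUE(r$heme),
               pseudo_wild_type = isTRUE(r$pwt))))
}

test_that("filtering applies the proline, 5 kcal/mol and metadata rules", {
  recs <- mk_records(list("A", "G", -1.0),
                     list("A", "P", 0.2),
                     list("P", "A", 0.2),
                     list("A", "G", 5.1),
                     list("A", "G", 5.0),
                     list("A", "G", 0.1, heme = TRUE),
                     list("A", "G", 0.1, pwt = TRUE))
  out <- filter_dataset(recs)
  expect_equal(nrow(out$retained), 2)   # -1.0 and 5.0 (5.0 is not > 5)
  expect_equal(unname(out$report[c("proline", "ddG_above_5", "heme_protein",
                                   "pseudo_wild_type")]),
               c(2, 1, 1, 1))
  expect_true(all(out$excluded$rule[out$excluded$ddG_M == 5.1] ==
                    "ddG_above_5"))
})

test_that("mutant datasets round-trip through the tab-separated format", {
  ds <- fixture_dataset()[1:25, ]
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_mutant_dataset(ds, tf)
  back <- read_mutant_dataset(tf)
  expect_equal(back$ddG_M, ds$ddG_M)            # full-precision text
  expect_equal(back$resnum, ds$resnum)
  expect_equal(back$s_w, ds$s_w)
  expect_false(any(back$heme_protein))
})

test_that("evaluate computes R and sigma, and trimming never hurts sigma", {
  ev <- evaluate(c(0, 1, 2), c(0, 2, 4))
  expect_equal(ev$R, 1.0)
  ev2 <- evaluate(1:5, 1:5)
  expect_equal(ev2$R, 1.0); expect_equal(ev2$sigma, 0)
  set.seed(3)
  for (rep in 1:10) {
    p <- rnorm(60); m <- p + rnorm(60)
    expect_lte(evaluate(p, m, 0.10)$sigma, evaluate(p, m)$sigma)
  }
  flat <- evaluate(rep(1, 5), rnorm(5))
  expect_true(is.na(flat$R)); expect_equal(flat$flag, "zero-variance")
})

test_that("a single-record dataset is fit exactly", {
  ds <- fixture_dataset()[5, , drop = FALSE]
  tr <- fixture_truth()
  fit <- fit_parameters(ds, tr$structures, tr$potentials, restarts = 1,
                        maxit = 50)
  expect_lt(fit$sigma_train, 1e-9)
})

test_that("sigma_train equals the objective recomputed from the params", {
  ds <- fixture_dataset()[1:300, ]
  feats <- list(X = fixture_features()$X[1:300, ],
                A = fixture_features()$A[1:300])
  fit <- fit_parameters(ds, NULL, NULL, restarts = 2, maxit = 200,
                        features = feats)
  pr <- predict_dataset(ds, NULL, NULL, fit$params, features = feats)
  expect_equal(fit$sigma_train, sqrt(mean((pr - ds$ddG_M)^2)),
               tolerance = 1e-9)
  expect_true(all(diff(fit$history) <= 0))   # accepted objective monotone
  expect_warning(
    fit_parameters(ds[1:30, ], NULL, NULL, restarts = 1, maxit = 5,
                   features = list(X = feats$X[1:30, ], A = feats$A[1:30])),
    "< 10x")
})

test_that("fitting recovers the noise floor on noisy synthetic data", {
  truth <- fixture_truth()
  ds <- with_noise <- simulate_mutant_dataset(
    structure(modifyList(unclass(truth), list(noise_sd = 0.5)),
              class = "ground_truth_model"), 1200, seed = 8)
  feats <- compute_features(ds, truth$structures, truth$potentials)
  fit <- fit_parameters(ds, NULL, NULL, restarts = 2, maxit = 500,
                        features = feats)
  expect_gt(fit$sigma_train, 0.4)
  expect_lt(fit$sigma_train, 0.6)
})

test_that("parameter reduction honours the threshold and shrinks the mask", {
  ds <- fixture_dataset()[1:400, ]
  feats <- list(X = fixture_features()$X[1:400, ],
                A = fixture_features()$A[1:400])
  fit <- fit_parameters(ds, NULL, NULL, restarts = 1, maxit = 200,
                        features = feats)
  same <- reduce_parameters(ds, NULL, NULL, fit, n_resamples = 3,
                            cv_threshold = Inf, features = feats)
  expect_identical(same$active, fit$params$active)   # no freeze at Inf
  red <- reduce_parameters(ds, NULL, NULL, fit, n_resamples = 6,
                           cv_threshold = 1.0, maxit = 100,
                           features = feats)
  expect_lt(sum(red$active), sum(fit$params$active))
  trace <- attr(red, "trace")
  n_active <- vapply(trace, function(x) x$n_active, numeric(1))
  expect_true(all(diff(n_active) < 0))               # strictly decreasing
})

test_that("coefficients that are truly constant in A tend to be frozen", {
  # ground truth with four coefficients flat in accessibility (f = 0)
  truth <- fixture_truth()
  th <- default_truth_params()$theta
  flat <- c(3, 6, 9, 12)
  th[flat, "f"] <- 0
  th[flat, "b"] <- 0.3
  truth2 <- structure(modifyList(unclass(truth), list(
    params = model_parameters(c = th[, "c"], r = th[, "r"], f = th[, "f"],
                              b = th[, "b"]),
    noise_sd = 0.2)), class = "ground_truth_model")
  ds <- simulate_mutant_dataset(truth2, 500, seed = 13)
  feats <- compute_features(ds, truth$structures, truth$potentials)
  fit <- fit_parameters(ds, NULL, NULL, restarts = 2, maxit = 300,
                        features = feats)
  red <- reduce_parameters(ds, NULL, NULL, fit, n_resamples = 8,
                           cv_threshold = 1.0, maxit = 100,
                           features = feats)
  frozen_cr <- which(!(red$active[, "c"] & red$active[, "r"]))
  expect_gt(length(intersect(frozen_cr, flat)), 0)
})

test_that("cross-validation partitions exactly and reports the protocol", {
  ds <- fixture_dataset()[1:400, ]
  feats <- list(X = fixture_features()$X[1:400, ],
                A = fixture_features()$A[1:400])
  cv <- cross_validate(ds, NULL, NULL, k = 4, seed = 5, restarts = 1,
                       maxit = 200, features = feats)
  expect_equal(sort(unique(cv$fold)), 1:4)
  expect_equal(length(cv$fold), 400)              # each record in one fold
  expect_equal(nrow(cv$metrics), 5)               # 4 runs + Average 1
  expect_equal(cv$metrics$run[5], "Average 1")
  expect_error(cross_validate(ds, NULL, NULL, k = 1, features = feats),
               "k must be")
  cv2 <- cross_validate(ds, NULL, NULL, k = 4, seed = 5, restarts = 1,
                        maxit = 200, features = feats,
                        group_by_protein = TRUE)
  tab <- table(ds$structure_id, cv2$fold)
  expect_true(all(rowSums(tab > 0) == 1))         # one fold per protein
})

test_that("second-round retraining drops the intersection outlier set", {
  ds <- fixture_dataset()[1:300, ]
  feats <- list(X = fixture_features()$X[1:300, ],
                A = fixture_features()$A[1:300])
  cv <- cross_validate(ds, NULL, NULL, k = 3, seed = 5, restarts = 1,
                       maxit = 150, features = feats)
  cutoff <- 0.35   # small cutoff so some records qualify on clean data
  cv2 <- retrain_without_training_outliers(cv, cutoff = cutoff)
  err <- abs(cv$pred_runs - ds$ddG_M)
  expect_equal(cv2$outliers,
               which(apply(err > cutoff, 1, all)))  # intersection over runs
  expect_equal(cv2$metrics$run[nrow(cv2$metrics)], "Average 2")
  expect_equal(cv2$metrics2$n_valid, as.vector(table(cv$fold)))  # unchanged
  cvInf <- retrain_without_training_outliers(cv, cutoff = Inf)
  expect_equal(length(cvInf$outliers), 0)
  expect_equal(cvInf$metrics2$sigma_c, cv$metrics$sigma_c[1:3],
               tolerance = 1e-9)   # no drop: identical refits
})

test_that("binned RMSE partitions the pairs and dismisses small bins", {
  set.seed(2)
  p <- rnorm(200); m <- p + rnorm(200, 0, 0.5)
  tab <- binned_rmse(p, m, axis = "predicted", width = 0.25, min_count = 10)
  expect_equal(sum(tab$n), 200)                   # partition covers all
  expect_true(all(is.na(tab$sigma[!tab$retained])))
  expect_true(all(tab$n[!tab$retained] < 10))
  # data confined to a single grid-aligned bin reproduces the global RMSE
  p2 <- p + 100; m2 <- m + 100          # bins anchored at multiples of width
  one <- binned_rmse(p2, m2, width = 1000, min_count = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$sigma, sqrt(mean((p2 - m2)^2)), tolerance = 1e-12)
})

test_that("stabilizing specificity counts true stabilizers", {
  pred <- c(-2, -1.5, -1.2, -0.8, -0.7, -0.6, -0.55, -0.52, -0.51, -0.505,
            1, 2)
  meas <- c(-1, -1, -1, -1, -1, -1, -1, 0.5, 0.5, 0.5, 1, -3)
  out <- stabilizing_specificity(pred, meas, -0.5)
  expect_equal(out$fraction, 0.7)
  expect_equal(out$n_selected, 10)
  none <- stabilizing_specificity(pred, meas, -10)
  expect_true(is.na(none$fraction)); expect_equal(none$flag, "undefined")
})

test_that("baseline identities hold", {
  set.seed(31)
  y <- rnorm(500, 1, 1.3)
  b <- baselines(y, seed = 1)
  expect_equal(b$constant_mean$sigma, sqrt(mean((y - mean(y))^2)),
               tolerance = 1e-12)
  Rs <- vapply(1:300, function(s) baselines(y, seed = s)$random_shuffle$R,
               numeric(1))
  expect_lt(abs(mean(Rs)), 0.05)
  s2 <- vapply(1:300, function(s)
    baselines(y, seed = s)$random_shuffle$sigma^2, numeric(1))
  expect_equal(mean(s2), 2 * mean((y - mean(y))^2), tolerance = 0.1)
})

test_that("validation error shrinks with the simulated noise level", {
  truth <- fixture_truth()
  sig <- vapply(c(1.0, 0.5, 0.1), function(sd) {
    tr <- structure(modifyList(unclass(truth), list(noise_sd = sd)),
                    class = "ground_truth_model")
    ds <- simulate_mutant_dataset(tr, 500, seed = 17)
    feats <- compute_features(ds, truth$structures, truth$potentials)
    cv <- cross_validate(ds, NULL, NULL, k = 3, seed = 2, restarts = 1,
                         maxit = 150, features = feats)
    cv$metrics$sigma_c[4]
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
})
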