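# Fitting the 64 sigmoid parameters to a mutant dataset by mean-square
# error minimization, bootstrap-based parameter reduction, and the
# cross-validation / evaluation harness.

#' Read a mutant dataset
#'
#' Tab-separated with header: `structure_id chain resnum wt mut ddG_M
#' flags`.  The flags column holds `-` or a comma-separated subset of
#' `heme_protein`, `pseudo_wild_type`.
#'
#' @param path File path.
#' @return Data frame of mutant records with logical flag columns.
#' @export
read_mutant_dataset <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = list(resnum = "character",
                                             chain = "character"))
  data.frame(structure_id = tab$structure_id, chain = tab$chain,
             resnum = as.character(tab$resnum), s_w = tab$wt, s_m = tab$mut,
             ddG_M = tab$ddG_M,
             heme_protein = grepl("heme_protein", tab$flags),
             pseudo_wild_type = grepl("pseudo_wild_type", tab$flags),
             stringsAsFactors = FALSE)
}

#' Write a mutant dataset
#'
#' @param records Data frame of mutant records (see
#'   [read_mutant_dataset()] for the columns).
#' @param path Output file.
#' @export
write_mutant_dataset <- function(records, path) {
  flags <- apply(cbind(ifelse(records$heme_protein, "heme_protein", ""),
                       ifelse(records$pseudo_wild_type, "pseudo_wild_type",
                              "")), 1L,
                 function(x) {
                   x <- x[nzchar(x)]
                   if (length(x) == 0L) "-" else paste(x, collapse = ",")
                 })
  tab <- data.frame(structure_id = records$structure_id,
                    chain = records$chain, resnum = records$resnum,
                    wt = records$s_w, mut = records$s_m,
                    ddG_M = sprintf("%.17g", records$ddG_M), flags = flags)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the training-set filtering rules
#'
#' Removes records that involve proline (either side of the mutation),
#' destabilize by more than 5 kcal/mol, or carry the `heme_protein` /
#' `pseudo_wild_type` metadata flags.  A record failing several rules is
#' counted under the first matching rule, in that order.
#'
#' @param records Data frame of mutant records.
#' @return List: `retained` (data frame), `excluded` (data frame with a
#'   `rule` column), `report` (named exclusion counts).
#' @export
filter_dataset <- function(records) {
  rule <- rep(NA_character_, nrow(records))
  rule[is.na(rule) & (records$s_w == "P" | records$s_m == "P")] <- "proline"
  rule[is.na(rule) & records$ddG_M > 5] <- "ddG_above_5"
  rule[is.na(rule) & records$heme_protein] <- "heme_protein"
  rule[is.na(rule) & records$pseudo_wild_type] <- "pseudo_wild_type"
  keep <- is.na(rule)
  excluded <- records[!keep, , drop = FALSE]
  excluded$rule <- rule[!keep]
  report <- c(proline = sum(rule == "proline", na.rm = TRUE),
              ddG_above_5 = sum(rule == "ddG_above_5", na.rm = TRUE),
              heme_protein = sum(rule == "heme_protein", na.rm = TRUE),
              pseudo_wild_type = sum(rule == "pseudo_wild_type",
                                     na.rm = TRUE),
              retained = sum(keep))
  list(retained = records[keep, , drop = FALSE], excluded = excluded,
       report = report)
}

#' Compute the 16 model features for every record
#'
#' Resolves each record's position in its structure and evaluates the 13
#' potential energy differences, the two volume terms and the constant
#' feature, plus the wild-type accessibility used by the sigmoid weights.
#'
#' @param records Data frame of mutant records.
#' @param structures List of annotated `protein_structure` objects whose
#'   ids cover `records$structure_id`.
#' @param potentials A `potential_set`.
#' @return List: `X` (n x 16 feature matrix), `A` (accessibility vector,
#'   percent).
#' @export
compute_features <- function(records, structures, potentials) {
  ids <- vapply(structures, function(s) s$id, character(1L))
  names(structures) <- ids
  missing <- setdiff(unique(records$structure_id), ids)
  if (length(missing) > 0L)
    stop("structures not provided for: ", paste(missing, collapse = ", "))
  caches <- lapply(structures, structure_tuples,
                   scheme = potentials$scheme)
  n <- nrow(records)
  X <- matrix(0, n, 16L, dimnames = list(NULL, COEFFICIENT_NAMES))
  A <- numeric(n)
  for (i in seq_len(n)) {
    s <- structures[[records$structure_id[i]]]
    k <- resolve_position(s, list(chain = records$chain[i],
                                  resnum = records$resnum[i]))
    X[i, ] <- .mutation_features(s, k, records$s_w[i], records$s_m[i],
                                 potentials, caches[[records$structure_id[i]]])
    A[i] <- s$residues$a[k]
  }
  list(X = X, A = A)
}

# predicted ddG for a feature set under given parameters
.predict_features <- function(params, X, A) {
  alpha <- coefficient_weights(params, A)
  if (is.null(dim(alpha))) alpha <- matrix(alpha, 1L)
  rowSums(alpha * X)
}

#' Predict ddG for a set of records
#'
#' @inheritParams compute_features
#' @param params A `model_parameters` object.
#' @param features Optional precomputed [compute_features()] result.
#' @return Numeric vector of predicted ddG values, kcal/mol.
#' @export
predict_dataset <- function(records, structures, potentials, params,
                            features = NULL) {
  if (is.null(features))
    features <- compute_features(records, structures, potentials)
  .predict_features(params, features$X, features$A)
}

# ---- variable-projection nonlinear least squares --------------------------

# Inner step: with the nonlinear (c, r) slots fixed, the model is linear
# in (f, b); solve those by least squares (frozen slots contribute a fixed
# offset).  Returns beta (full 32-vector: f then b) and fitted values.
.inner_linear <- function(theta, active, X, A, y) {
  G <- 1 / (1 + exp(-sweep(outer(A, theta[, "c"], "-"), 2L,
                           theta[, "r"], "*")))
  Phi <- cbind(X * G, X)                      # columns: f_1..f_16, b_1..b_16
  free <- c(active[, "f"], active[, "b"])
  beta <- c(theta[, "f"], theta[, "b"])
  offset <- if (any(!free)) Phi[, !free, drop = FALSE] %*% beta[!free]
            else rep(0, length(y))
  if (any(free)) {
    fit <- stats::lm.fit(Phi[, free, drop = FALSE], y - offset)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    beta[free] <- cf
  }
  yhat <- as.numeric(Phi %*% beta)
  list(beta = beta, yhat = yhat, G = G)
}

# concentrated objective sigma^2 and its analytic gradient over the free
# (c, r) entries; by the envelope theorem the inner optimum makes the
# partial derivative at fixed beta exact
.make_objective <- function(theta0, active, X, A, y, tracker = NULL) {
  free_c <- which(active[, "c"])
  free_r <- which(active[, "r"])
  n <- length(y)
  last <- new.env(parent = emptyenv())
  unpack <- function(par) {
    th <- theta0
    th[free_c, "c"] <- par[seq_along(free_c)]
    th[free_r, "r"] <- par[length(free_c) + seq_along(free_r)]
    th
  }
  evaluate <- function(par) {
    key <- paste(par, collapse = ",")
    if (!is.null(last$key) && identical(last$key, key)) return(last$val)
    th <- unpack(par)
    inn <- .inner_linear(th, active, X, A, y)
    e <- y - inn$yhat
    th[, "f"] <- inn$beta[1:16]
    th[, "b"] <- inn$beta[17:32]
    val <- list(obj = mean(e^2), e = e, G = inn$G, theta = th)
    last$key <- key; last$val <- val
    if (!is.null(tracker)) {
      if (is.null(tracker$best) || val$obj < tracker$best) {
        tracker$best <- val$obj
        tracker$history <- c(tracker$history, val$obj)
      }
    }
    val
  }
  fn <- function(par) evaluate(par)$obj
  gr <- function(par) {
    v <- evaluate(par)
    th <- v$theta
    dg <- v$G * (1 - v$G)                     # n x 16
    g_c <- g_r <- numeric(16L)
    for (i in seq_len(16L)) {
      w <- v$e * X[, i] * dg[, i]
      g_c[i] <- (2 / n) * th[i, "r"] * th[i, "f"] * sum(w)
      g_r[i] <- -(2 / n) * th[i, "f"] * sum(w * (A - th[i, "c"]))
    }
    c(g_c[free_c], g_r[free_r])
  }
  list(fn = fn, gr = gr, unpack = unpack, evaluate = evaluate,
       n_free = length(free_c) + length(free_r),
       free_c = free_c, free_r = free_r)
}

# one optimizer run from a given start
.fit_once <- function(theta_start, theta0, active, X, A, y, maxit, tracker) {
  ob <- .make_objective(theta0, active, X, A, y, tracker)
  par0 <- c(theta_start[ob$free_c, "c"], theta_start[ob$free_r, "r"])
  if (length(par0) == 0L) {
    v <- ob$evaluate(numeric(0))
    return(list(theta = v$theta, obj = v$obj, convergence = 0L))
  }
  lower <- c(rep(0, length(ob$free_c)), rep(-5, length(ob$free_r)))
  upper <- c(rep(100, length(ob$free_c)), rep(5, length(ob$free_r)))
  # c (percent) and r (per percent) live on very different scales;
  # parscale conditions the quasi-Newton steps
  pscale <- c(rep(25, length(ob$free_c)), rep(0.1, length(ob$free_r)))
  opt <- stats::optim(par0, ob$fn, ob$gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 1e3,
                                     parscale = pscale))
  v <- ob$evaluate(opt$par)
  list(theta = v$theta, obj = v$obj, convergence = opt$convergence)
}

#' Fit the sigmoid parameters to a mutant dataset
#'
#' Minimizes the root-mean-square error
#' \deqn{\sigma = \sqrt{\frac 1N \sum_m (\Delta\Delta G_{M,m} -
#'   \Delta\Delta G_{P,m})^2}}
#' over the active parameters by variable-projection nonlinear least
#' squares: the inflections `c` and slopes `r` are optimized by L-BFGS-B
#' (bounds c in [0, 100] percent, r in [-5, 5] per percent) with an
#' analytic gradient, while the scalings `f` and shifts `b` -- linear
#' given (c, r) -- are solved exactly at every step.  The best of
#' `restarts` seeded initializations is returned; everything is
#' deterministic given `init_seed`.
#'
#' @inheritParams compute_features
#' @param init_seed Integer seed for the restart initializations.
#' @param restarts Number of random initializations (default 8).
#' @param params0 Starting `model_parameters`; frozen slots keep its
#'   values.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param features Optional precomputed [compute_features()] result.
#' @return Object of class `fit_result`: `params`, `sigma_train`
#'   (kcal/mol), `history` (objective at each accepted improvement),
#'   `seed`, `converged`.
#' @export
fit_parameters <- function(records, structures, potentials, init_seed = 1,
                           restarts = 8L, params0 = NULL, maxit = 1000L,
                           features = NULL) {
  if (is.null(features))
    features <- compute_features(records, structures, potentials)
  X <- features$X; A <- features$A; y <- records$ddG_M
  if (is.null(params0)) params0 <- model_parameters(c = 15, r = 0.1)
  active <- params0$active
  n_active <- sum(active)
  if (nrow(records) < 10L * n_active)
    warning("only ", nrow(records), " records for ", n_active,
            " active parameters (< 10x)", call. = FALSE)

  tracker <- new.env(parent = emptyenv())
  tracker$best <- NULL; tracker$history <- numeric(0)
  starts <- with_seed(init_seed, {
    lapply(seq_len(max(1L, restarts)), function(s) {
      th <- params0$theta
      if (s > 1L) {
        th[, "c"] <- stats::runif(16L, 5, 60)
        th[, "r"] <- stats::runif(16L, -1, 1)
      }
      th
    })
  })
  best <- NULL
  for (th in starts) {
    run <- .fit_once(th, params0$theta, active, X, A, y, maxit, tracker)
    if (is.null(best) || run$obj < best$obj) best <- run
  }
  params <- model_parameters(c = best$theta[, "c"], r = best$theta[, "r"],
                             f = best$theta[, "f"], b = best$theta[, "b"],
                             active = active)
  structure(list(params = params, sigma_train = sqrt(best$obj),
                 history = tracker$history, seed = init_seed,
                 converged = best$convergence == 0L,
                 n = length(y)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: n = %d, sigma_train = %.4f kcal/mol, %s (%d improvements)\n",
              x$n, x$sigma_train,
              if (x$converged) "converged" else "NOT converged",
              length(x$history)))
  invisible(x)
}

#' Iterative bootstrap parameter reduction
#'
#' Refits the model on bootstrap resamples of the dataset, measures each
#' active parameter's dispersion across resamples relative to its mean
#' magnitude (a bootstrap coefficient of variation), and freezes the most
#' uncertain parameter whenever it exceeds `cv_threshold`: a frozen `f`
#' is set to 0 (collapsing that sigmoid to the constant `b`, so the now
#' inert `c` and `r` of the same coefficient are frozen too), frozen
#' `c`/`r`/`b` keep their bootstrap mean.  The model is refit after every
#' freeze; the loop stops when no active parameter exceeds the threshold.
#' The active count strictly decreases at every iteration.
#'
#' @inheritParams fit_parameters
#' @param fit A `fit_result` from [fit_parameters()].
#' @param n_resamples Bootstrap resamples per iteration (default 20).
#' @param cv_threshold Relative-dispersion threshold (default 1.0).
#' @param seed Seed for the bootstrap resampling.
#' @return A `model_parameters` object with the enlarged frozen mask,
#'   refit on the full dataset; the reduction trace is attached as
#'   attribute `"trace"`.
#' @export
reduce_parameters <- function(records, structures, potentials, fit,
                              n_resamples = 20L, cv_threshold = 1.0,
                              seed = 1, maxit = 100L, features = NULL) {
  if (is.null(features))
    features <- compute_features(records, structures, potentials)
  params <- fit$params
  trace <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (!any(params$active)) break
    boots <- with_seed(seed + iter, {
      lapply(seq_len(n_resamples), function(b) {
        idx <- sample.int(nrow(records), replace = TRUE)
        f <- fit_parameters(records[idx, , drop = FALSE], structures,
                            potentials, init_seed = 1, restarts = 1L,
                            params0 = params, maxit = maxit,
                            features = list(X = features$X[idx, ,
                                                           drop = FALSE],
                                            A = features$A[idx]))
        f$params$theta
      })
    })
    cv <- matrix(NA_real_, 16L, 4L, dimnames = dimnames(params$theta))
    mean_v <- cv
    for (i in seq_len(16L)) for (j in seq_len(4L)) {
      if (!params$active[i, j]) next
      v <- vapply(boots, function(th) th[i, j], numeric(1L))
      mean_v[i, j] <- mean(v)
      cv[i, j] <- stats::sd(v) / max(abs(mean(v)), 1e-8)
    }
    worst <- which(cv == max(cv, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    if (max(cv, na.rm = TRUE) <= cv_threshold) break
    i <- worst[1L]; j <- worst[2L]
    th <- params$theta; act <- params$active
    if (colnames(th)[j] == "f") {
      th[i, "f"] <- 0
      act[i, c("c", "r", "f")] <- FALSE      # inert sigmoid: freeze c, r too
    } else {
      th[i, j] <- mean_v[i, j]
      act[i, j] <- FALSE
    }
    params <- model_parameters(c = th[, "c"], r = th[, "r"], f = th[, "f"],
                               b = th[, "b"], active = act)
    trace[[iter]] <- list(frozen = paste0(rownames(th)[i], ".",
                                          colnames(th)[j]),
                          cv = unname(cv[i, j]),
                          n_active = sum(act))
    refit <- fit_parameters(records, structures, potentials, init_seed = 1,
                            restarts = 1L, params0 = params, maxit = maxit,
                            features = features)
    params <- refit$params
  }
  attr(params, "trace") <- trace
  params
}

# ---- evaluation -----------------------------------------------------------

#' Pearson correlation and RMS error, with optional outlier trimming
#'
#' @param pred,meas Predicted and measured ddG vectors, kcal/mol.
#' @param trim_fraction Fraction of pairs with the largest absolute error
#'   removed before computing the metrics (ceiling of `trim * N` pairs;
#'   0 or 0.10 in the standard protocol).
#' @return List: `R` (Pearson, `NA` with `flag = "zero-variance"` when
#'   either vector is constant), `sigma` (RMSE, kcal/mol), `n_used`,
#'   `n_trimmed`.
#' @export
evaluate <- function(pred, meas, trim_fraction = 0) {
  stopifnot(length(pred) == length(meas), length(pred) >= 3L)
  n <- length(pred)
  drop_n <- ceiling(trim_fraction * n)
  keep <- seq_len(n)
  if (drop_n > 0L) {
    keep <- order(abs(pred - meas), decreasing = TRUE)[-seq_len(drop_n)]
  }
  p <- pred[keep]; m <- meas[keep]
  flag <- NULL
  R <- if (stats::sd(p) == 0 || stats::sd(m) == 0) {
    flag <- "zero-variance"
    NA_real_
  } else stats::cor(p, m)
  list(R = R, sigma = sqrt(mean((p - m)^2)), n_used = length(keep),
       n_trimmed = drop_n, flag = flag)
}

#' Seeded k-fold cross-validation of the predictor
#'
#' Partitions the records into `k` random folds (seeded; optionally
#' grouped so that all mutants of one structure share a fold), fits the
#' model on each training set and evaluates on the held-out part.
#' Reports, per fold and averaged, the Pearson correlation and RMSE on
#' the training (`R_d`, `sigma_d`) and validation (`R_c`, `sigma_c`)
#' sets, with and without exclusion of 10% outliers.
#'
#' @inheritParams fit_parameters
#' @param k Number of folds (>= 2).
#' @param seed Partition / fitting seed.
#' @param group_by_protein Keep all records of a structure in one fold.
#' @return Object of class `crossval_result`: `metrics` (per-fold rows
#'   plus an `Average 1` row), `fold` (assignment per record), `pred_runs`
#'   (n x k matrix of every run's predictions for every record), `fits`,
#'   and the data needed for [retrain_without_training_outliers()].
#' @export
cross_validate <- function(records, structures, potentials, k = 5L,
                           seed = 1, restarts = 2L, maxit = 500L,
                           group_by_protein = FALSE, features = NULL) {
  if (k < 2L) stop("k must be >= 2")
  n <- nrow(records)
  if (is.null(features))
    features <- compute_features(records, structures, potentials)
  fold <- with_seed(seed, {
    if (group_by_protein) {
      ids <- unique(records$structure_id)
      gf <- sample(rep_len(seq_len(k), length(ids)))
      gf[match(records$structure_id, ids)]
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
  if (min(table(factor(fold, levels = seq_len(k)))) < 2L)
    stop("a fold has fewer than 2 records")
  y <- records$ddG_M
  pred_runs <- matrix(NA_real_, n, k)
  fits <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fits[[f]] <- fit_parameters(records[tr, , drop = FALSE], structures,
                                potentials, init_seed = seed * 100L + f,
                                restarts = restarts, maxit = maxit,
                                features = list(X = features$X[tr, ,
                                                               drop = FALSE],
                                                A = features$A[tr]))
    pred_runs[, f] <- .predict_features(fits[[f]]$params, features$X,
                                        features$A)
    rows[[f]] <- .fold_metrics(sprintf("Run %d", f), pred_runs[tr, f], y[tr],
                               pred_runs[!tr, f], y[!tr])
  }
  metrics <- do.call(rbind, rows)
  metrics <- rbind(metrics, .average_row("Average 1", metrics))
  res <- structure(list(metrics = metrics, fold = fold,
                        pred_runs = pred_runs, fits = fits, k = k,
                        seed = seed, features = features, records = records,
                        restarts = restarts, maxit = maxit),
                   class = "crossval_result")
  res
}

.fold_metrics <- function(label, pred_d, y_d, pred_c, y_c) {
  e_d <- evaluate(pred_d, y_d); e_c <- evaluate(pred_c, y_c)
  t_d <- evaluate(pred_d, y_d, 0.10); t_c <- evaluate(pred_c, y_c, 0.10)
  data.frame(run = label, R_d = e_d$R, R_c = e_c$R,
             sigma_d = e_d$sigma, sigma_c = e_c$sigma,
             R_d_trim = t_d$R, R_c_trim = t_c$R,
             sigma_d_trim = t_d$sigma, sigma_c_trim = t_c$sigma,
             n_train = length(y_d), n_valid = length(y_c),
             stringsAsFactors = FALSE)
}

.average_row <- function(label, metrics) {
  num <- metrics[, !(names(metrics) %in% c("run", "n_train", "n_valid")),
                 drop = FALSE]
  out <- cbind(data.frame(run = label), as.data.frame(t(colMeans(num))),
               data.frame(n_train = round(mean(metrics$n_train)),
                          n_valid = round(mean(metrics$n_valid))))
  out
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  m <- x$metrics
  cat(sprintf("%-10s %11s %17s %11s %17s\n", "", "R_d/R_c",
              "sigma_d/sigma_c", "R (10% out)", "sigma (10% out)"))
  for (i in seq_len(nrow(m))) {
    fmt <- function(a, b) {
      fa <- if (is.na(a)) "-" else sprintf("%.2f", a)
      fb <- if (is.na(b)) "-" else sprintf("%.2f", b)
      paste0(fa, "/", fb)
    }
    cat(sprintf("%-10s %11s %17s %11s %17s\n", m$run[i],
                fmt(m$R_d[i], m$R_c[i]), fmt(m$sigma_d[i], m$sigma_c[i]),
                fmt(m$R_d_trim[i], m$R_c_trim[i]),
                fmt(m$sigma_d_trim[i], m$sigma_c_trim[i])))
  }
  invisible(x)
}

#' Second-round retraining without persistent training outliers
#'
#' Identifies the records whose absolute prediction error exceeds
#' `cutoff` in every one of the initial cross-validation runs (the
#' intersection over runs of the per-run outlier sets), removes them from
#' the training folds only, refits each fold, and re-evaluates on the
#' unchanged validation folds.  The new averaged validation metrics are
#' appended as an `Average 2` row.
#'
#' @param cv A `crossval_result`.
#' @param cutoff Outlier threshold in kcal/mol (default 1.5).
#' @return The `crossval_result` with `metrics` gaining an `Average 2`
#'   row, plus `outliers` (record indices dropped from training) and
#'   `metrics2` (the per-fold second-round rows).
#' @export
retrain_without_training_outliers <- function(cv, cutoff = 1.5) {
  stopifnot(inherits(cv, "crossval_result"))
  y <- cv$records$ddG_M
  err <- abs(cv$pred_runs - y)
  outliers <- which(rowSums(err > cutoff) == cv$k)   # in every initial run
  rows <- vector("list", cv$k)
  for (f in seq_len(cv$k)) {
    tr <- which(cv$fold != f)
    tr2 <- setdiff(tr, outliers)
    va <- which(cv$fold == f)
    fit2 <- fit_parameters(cv$records[tr2, , drop = FALSE], NULL, NULL,
                           init_seed = cv$seed * 100L + f,
                           restarts = cv$restarts, maxit = cv$maxit,
                           features = list(X = cv$features$X[tr2, ,
                                                             drop = FALSE],
                                           A = cv$features$A[tr2]))
    pr <- .predict_features(fit2$params, cv$features$X, cv$features$A)
    rows[[f]] <- .fold_metrics(sprintf("Run %d (2)", f), pr[tr2], y[tr2],
                               pr[va], y[va])
  }
  metrics2 <- do.call(rbind, rows)
  avg2 <- .average_row("Average 2", metrics2)
  avg2$R_d <- avg2$sigma_d <- avg2$R_d_trim <- avg2$sigma_d_trim <- NA_real_
  cv$metrics <- rbind(cv$metrics, avg2)
  cv$metrics2 <- metrics2
  cv$outliers <- outliers
  cv$outlier_cutoff <- cutoff
  cv
}

#' RMSE binned along the predicted or measured axis
#'
#' Divides the pairs into non-overlapping bins of `width` kcal/mol along
#' the chosen axis and reports the RMSE per bin; bins holding fewer than
#' `min_count` pairs are dismissed (kept in the table with `retained =
#' FALSE` and `sigma = NA`).
#'
#' @inheritParams evaluate
#' @param axis `"predicted"` or `"measured"`.
#' @param width Bin width, kcal/mol (default 0.25).
#' @param min_count Minimal pairs per retained bin (default 10).
#' @return Data frame: `bin_lo`, `bin_hi`, `n`, `sigma`, `retained`.
#' @export
binned_rmse <- function(pred, meas, axis = c("predicted", "measured"),
                        width = 0.25, min_count = 10L) {
  axis <- match.arg(axis)
  v <- if (axis == "predicted") pred else meas
  err2 <- (pred - meas)^2
  lo <- floor(min(v) / width) * width
  bin <- floor((v - lo) / width + 1e-12)   # half-open [lo+b*w, lo+(b+1)*w)
  bins <- sort(unique(bin))
  out <- do.call(rbind, lapply(bins, function(b) {
    sel <- bin == b
    data.frame(bin_lo = lo + b * width, bin_hi = lo + (b + 1) * width,
               n = sum(sel),
               sigma = if (sum(sel) >= min_count) sqrt(mean(err2[sel]))
                       else NA_real_,
               retained = sum(sel) >= min_count)
  }))
  rownames(out) <- NULL
  out
}

#' Specificity toward stabilizing mutations
#'
#' Of the mutations predicted below `pred_threshold`, the fraction that
#' are measured as stabilizing (ddG_M < 0).
#'
#' @inheritParams evaluate
#' @param pred_threshold Predicted-ddG selection threshold, kcal/mol
#'   (e.g. -0.5 for mildly, -1.0 for strongly stabilizing).
#' @return List: `fraction` (`NA` with `flag = "undefined"` when no
#'   prediction falls below the threshold), `n_selected`, `n_true`.
#' @export
stabilizing_specificity <- function(pred, meas, pred_threshold) {
  sel <- pred < pred_threshold
  if (!any(sel))
    return(list(fraction = NA_real_, n_selected = 0L, n_true = 0L,
                flag = "undefined"))
  list(fraction = mean(meas[sel] < 0), n_selected = sum(sel),
       n_true = sum(meas[sel] < 0), flag = NULL)
}

#' Random-shuffle and constant-mean baseline predictors
#'
#' The random baseline scores a seeded permutation of the measured values
#' against the originals; the constant baseline predicts the dataset mean
#' for every mutant, whose RMSE equals the population standard deviation
#' of the measurements.
#'
#' @param meas Measured ddG vector (>= 3 values), kcal/mol.
#' @param seed Integer seed for the permutation.
#' @return List: `random_shuffle` (`R`, `sigma`), `constant_mean`
#'   (`sigma`).
#' @export
baselines <- function(meas, seed = 1) {
  stopifnot(length(meas) >= 3L)
  shuffled <- with_seed(seed, sample(meas))
  ev <- evaluate(shuffled, meas)
  list(random_shuffle = list(R = ev$R, sigma = ev$sigma),
       constant_mean = list(sigma = sqrt(mean((meas - mean(meas))^2))))
}

#' Write a cross-validation report
#'
#' Plain-text table with one row per run plus the average rows.
#'
#' @param cv A `crossval_result`.
#' @param path Output file.
#' @export
write_crossval_report <- function(cv, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sink(con)
  print(cv)
  sink()
  invisible(path)
}
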