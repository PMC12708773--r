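# Gradient-boosted tree classifiers (XGBoost), one per fingerprint
# scheme, selected by grid search on validation accuracy under an
# overfit-spread constraint: candidate hyperparameter points whose
# train/validation accuracy difference exceeds 5 points are discarded
# before selection.  The test partition is never consulted during
# selection; its spread is reported post hoc.

#' Default hyperparameter grid axes
#'
#' The search space: `n_estimators` from 5 to 200 (discretised to
#' 7 values), `max_depth` every integer 2 to 10, `learning_rate` in
#' \{0.001, 0.01, 0.1\}, `colsample_bytree` in \{0.5, 0.7, 0.9\},
#' `reg_lambda` in \{0, 0.001, 0.01, 0.1, 1\} and `min_child_weight`
#' in \{7, 9, 11, 13\}.
#'
#' @return Named list of value vectors, one per axis.
#' @export
default_grid_axes <- function() {
  list(
    n_estimators = c(5L, 10L, 25L, 50L, 100L, 150L, 200L),
    max_depth = 2:10,
    learning_rate = c(0.001, 0.01, 0.1),
    colsample_bytree = c(0.5, 0.7, 0.9),
    reg_lambda = c(0, 0.001, 0.01, 0.1, 1),
    min_child_weight = c(7, 9, 11, 13)
  )
}

#' Reduced hyperparameter grid axes
#'
#' A small 18-point subset of [default_grid_axes()] for routine
#' analyses and simulation studies: it spans weak (5 trees, depth 2,
#' learning rate 0.001) to strong (100 trees, depth 6, learning rate
#' 0.1) learners so the overfit-spread constraint always has satisfiable
#' candidates, at a small fraction of the full grid's cost.
#'
#' @return Named list of value vectors, one per axis.
#' @export
reduced_grid_axes <- function() {
  list(
    n_estimators = c(5L, 25L, 100L),
    max_depth = c(2L, 3L, 6L),
    learning_rate = c(0.001, 0.1),
    colsample_bytree = 0.9,
    reg_lambda = 0.01,
    min_child_weight = 7
  )
}

.GRID_DOMAIN <- list(
  n_estimators = function(v) all(v >= 5 & v <= 200 & v == as.integer(v)),
  max_depth = function(v) all(v >= 2 & v <= 10 & v == as.integer(v)),
  learning_rate = function(v) all(v %in% c(0.001, 0.01, 0.1)),
  colsample_bytree = function(v) all(v %in% c(0.5, 0.7, 0.9)),
  reg_lambda = function(v) all(v %in% c(0, 0.001, 0.01, 0.1, 1)),
  min_child_weight = function(v) all(v %in% c(7, 9, 11, 13))
)

#' Enumerate the hyperparameter grid
#'
#' Full Cartesian product of the axis value sets in deterministic
#' order.  With the default axes this is 11,340 points.
#'
#' @param axes Named list of value vectors as in [default_grid_axes()];
#'   each axis may be restricted but must stay within its declared
#'   domain and must be non-empty.
#' @return data.frame with one row per hyperparameter point.
#' @export
enumerate_grid <- function(axes = default_grid_axes()) {
  need <- names(.GRID_DOMAIN)
  miss <- setdiff(need, names(axes))
  if (length(miss)) stop("missing grid axes: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (ax in need) {
    v <- axes[[ax]]
    if (length(v) == 0L) stop("empty grid axis: ", ax, call. = FALSE)
    if (!.GRID_DOMAIN[[ax]](v)) {
      stop("values out of domain for axis ", ax, call. = FALSE)
    }
  }
  grid <- expand.grid(axes[need], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$n_estimators <- as.integer(grid$n_estimators)
  grid$max_depth <- as.integer(grid$max_depth)
  grid
}

# fit one booster; reproducible via the R RNG (colsample draws)
.fit_booster <- function(x, y, point, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y, nthread = 1)
  params <- list(
    objective = "binary:logistic",
    eta = point$learning_rate,
    max_depth = point$max_depth,
    colsample_bytree = point$colsample_bytree,
    lambda = point$reg_lambda,
    min_child_weight = point$min_child_weight,
    nthread = 1
  )
  .with_seed(seed, xgboost::xgb.train(params = params, data = dtrain,
                                      nrounds = point$n_estimators,
                                      verbose = 0))
}

.booster_prob <- function(booster, x) {
  as.numeric(stats::predict(booster, xgboost::xgb.DMatrix(x, nthread = 1)))
}

.truth_vector <- function(labels) {
  if (any(!labels %in% c("active", "inactive"))) {
    stop("labels must be active/inactive", call. = FALSE)
  }
  labels == "active"
}

#' Train one classifier under the overfit-spread constraint
#'
#' Fits one booster per grid point on the training partition, discards
#' points whose train/validation accuracy spread exceeds `max_spread`,
#' and among the survivors selects the point with the highest
#' validation accuracy (ties broken by higher validation AUC, then
#' fewer estimators, then lower depth).  The selection log records
#' every point's accuracies and disposition.
#'
#' @param mols Curated, labelled molecule library.
#' @param split A [stratified_split()] assignment over `mols`.
#' @param scheme Fingerprint scheme to encode under.
#' @param grid Hyperparameter grid (data.frame from
#'   [enumerate_grid()]); defaults to the full grid.
#' @param seed Integer training seed.
#' @param max_spread Maximum allowed |train − validation| accuracy
#'   difference (default 0.05).
#' @return List with `model` (an `xo_classifier`) and `log` (the
#'   per-point selection data.frame).
#' @export
train_with_constraint <- function(mols, split, scheme,
                                  grid = enumerate_grid(), seed = 1L,
                                  max_spread = 0.05) {
  .check_library(mols)
  stopifnot(inherits(split, "split_assignment"), is.data.frame(grid),
            nrow(grid) >= 1L)
  scheme <- .as_scheme(scheme)
  fps <- encode_fingerprints(mols, scheme)
  truth <- .truth_vector(mols$label)
  names(truth) <- mols$id
  idx <- function(ids) match(ids, mols$id)
  tr <- idx(split$train_ids); va <- idx(split$validation_ids)
  if (anyNA(tr) || anyNA(va)) {
    stop("split ids not found in library", call. = FALSE)
  }
  if (length(unique(truth[tr])) < 2L) {
    stop("training partition must contain both classes", call. = FALSE)
  }
  x_tr <- fps[tr, , drop = FALSE]; y_tr <- truth[tr]
  x_va <- fps[va, , drop = FALSE]; y_va <- truth[va]

  n <- nrow(grid)
  acc_tr <- acc_va <- auc_va <- numeric(n)
  boosters <- vector("list", n)
  for (i in seq_len(n)) {
    b <- .fit_booster(x_tr, as.numeric(y_tr), grid[i, ], seed)
    boosters[[i]] <- b
    p_tr <- .booster_prob(b, x_tr)
    p_va <- .booster_prob(b, x_va)
    acc_tr[i] <- mean((p_tr >= 0.5) == y_tr)
    acc_va[i] <- mean((p_va >= 0.5) == y_va)
    auc_va[i] <- auc_rank(y_va, p_va)
  }
  spread <- abs(acc_tr - acc_va)
  ok <- spread <= max_spread
  if (!any(ok)) {
    stop("no grid point satisfies the accuracy-spread constraint (",
         max_spread, "); consider relaxing it or widening the grid",
         call. = FALSE)
  }
  ord <- order(-acc_va, -auc_va, grid$n_estimators, grid$max_depth,
               seq_len(n))
  best <- ord[ok[ord]][1]
  log <- cbind(grid,
               data.frame(acc_train = acc_tr, acc_validation = acc_va,
                          auc_validation = auc_va, spread = spread,
                          constraint_ok = ok,
                          selected = seq_len(n) == best))
  model <- structure(list(
    scheme = scheme$id,
    params = as.list(grid[best, ]),
    raw = xgboost::xgb.save.raw(boosters[[best]]),
    decision_threshold = 0.5,
    training_seed = as.integer(seed)
  ), class = "xo_classifier")
  list(model = model, log = log)
}

#' @export
print.xo_classifier <- function(x, ...) {
  cat("<xo_classifier>", x$scheme, "\n")
  cat("  params:", paste(names(x$params), unlist(x$params), sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

#' Predict activity probabilities
#'
#' @param object An `xo_classifier`.
#' @param newdata Molecule library or fingerprint matrix under the
#'   model's scheme.
#' @param type `"prob"` for probabilities, `"class"` for
#'   `"active"`/`"inactive"` at the model's decision threshold.
#' @param ... Unused.
#' @return Numeric probabilities or character classes, named by id.
#' @export
predict.xo_classifier <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  fps <- if (is.matrix(newdata)) {
    sc <- attr(newdata, "scheme")
    if (!is.null(sc) && !identical(sc, object$scheme)) {
      stop("fingerprint scheme mismatch: model ", object$scheme,
           ", data ", sc, call. = FALSE)
    }
    newdata
  } else {
    encode_fingerprints(newdata, object$scheme)
  }
  booster <- xgboost::xgb.load.raw(object$raw)
  p <- .booster_prob(booster, fps)
  names(p) <- rownames(fps)
  if (type == "prob") return(p)
  ifelse(p >= object$decision_threshold, "active", "inactive")
}

#' Evaluate a classifier on a labelled set
#'
#' Confusion counts at the model's decision threshold plus accuracy,
#' precision, recall, F1 and rank-statistic AUC (midrank ties).  With a
#' single-class set the AUC is reported as `NA` and the other metrics
#' are still computed.
#'
#' @param model An `xo_classifier`.
#' @param mols Labelled molecule library.
#' @param orientation Metric orientation, see
#'   [classification_metrics()].
#' @return A `metrics_report`.
#' @export
evaluate <- function(model, mols, orientation = "standard") {
  .check_library(mols)
  if (nrow(mols) == 0L) stop("empty evaluation set", call. = FALSE)
  truth <- .truth_vector(mols$label)
  prob <- predict(model, mols)
  .metrics_report(truth, prob, model$decision_threshold, orientation)
}

#' Train/validation/test accuracy spread
#'
#' The model-stability view: accuracy of one model on each partition,
#' with the pairwise spreads.  Computed post hoc; the test column plays
#' no role in model selection.
#'
#' @param model An `xo_classifier`.
#' @param mols Labelled molecule library.
#' @param split The split assignment used in training.
#' @return data.frame with one row: train/validation/test accuracies
#'   and the maximum pairwise spread.
#' @export
stability_report <- function(model, mols, split) {
  .check_library(mols)
  stopifnot(inherits(split, "split_assignment"))
  acc <- function(ids) {
    sub <- mols[mols$id %in% ids, , drop = FALSE]
    evaluate(model, sub)$accuracy
  }
  a <- c(train = acc(split$train_ids),
         validation = acc(split$validation_ids),
         test = acc(split$test_ids))
  data.frame(scheme = model$scheme,
             acc_train = a[["train"]],
             acc_validation = a[["validation"]],
             acc_test = a[["test"]],
             max_spread = max(dist(a)))
}

#' Stratified k-fold cross-validation
#'
#' Splits the library into `k` label-stratified folds; each fold is
#' evaluated by a model trained on the other `k − 1` folds with fixed
#' hyperparameters.  Fold assignment is deterministic given the seed.
#'
#' @param mols Labelled molecule library; every class needs at least
#'   `k` members.
#' @param scheme Fingerprint scheme.
#' @param params One hyperparameter point (single-row data.frame or
#'   list with the six axis values).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment and training.
#' @return List with `folds` (per-fold `metrics_report`s), `mean` and
#'   `sd` (named vectors over accuracy/precision/recall/f1/auc).
#' @export
cross_validate <- function(mols, scheme, params, k = 10L, seed = 1L) {
  .check_library(mols)
  scheme <- .as_scheme(scheme)
  params <- as.list(params)
  truth <- .truth_vector(mols$label)
  tab <- table(mols$label)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " members", call. = FALSE)
  }
  n <- nrow(mols)
  fold <- integer(n)
  .with_seed(seed, {
    for (cl in names(tab)) {
      i <- which(mols$label == cl)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
  })
  fps <- encode_fingerprints(mols, scheme)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    b <- .fit_booster(fps[tr, , drop = FALSE], as.numeric(truth[tr]),
                      params, seed)
    p <- .booster_prob(b, fps[!tr, , drop = FALSE])
    reports[[f]] <- .metrics_report(truth[!tr], p)
  }
  keys <- c("accuracy", "precision", "recall", "f1", "auc")
  mat <- sapply(reports, function(r) unlist(r[keys]))
  list(folds = reports,
       mean = rowMeans(mat, na.rm = TRUE),
       sd = apply(mat, 1, stats::sd, na.rm = TRUE),
       fold_assignment = fold)
}
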