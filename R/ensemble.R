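#' Base-learner configuration
#'
#' @param family One of `"gbm"` (gradient boosting via xgboost), `"svm_rbf"`
#'   (RBF support vector machine via e1071), `"extra_trees"` (extremely
#'   randomized trees via ranger).
#' @param ... Named hyperparameters overriding the family defaults.
#' @return A `base_config` object.
#' @export
base_config <- function(family = c("gbm", "svm_rbf", "extra_trees"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    gbm = list(learning_rate = 0.05, n_estimators = 400L, max_depth = 7L,
               subsample = 0.8),
    svm_rbf = list(gamma = 0.018, cost = 19),
    extra_trees = list(n_trees = 100L, min_split = 2L, min_leaf = 1L))
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameters for ", family, ": ",
         paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(list(family = family, params = defaults), class = "base_config")
}

#' @export
print.base_config <- function(x, ...) {
  cat(x$family, ": ",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Default base-learner configurations
#'
#' The three base learners of the stacked classifier with their fixed
#' hyperparameters: gradient boosting (learning rate 0.05, 400 rounds, max
#' depth 7, row subsample 0.8), RBF SVM (kernel coefficient gamma = 0.018,
#' penalty C = 19, probability outputs enabled), and extremely randomized
#' trees (100 trees, minimum split size 2, minimum leaf size 1).
#'
#' @return Named list of three [base_config()] objects, in the column order
#'   used throughout (`gbm`, `svm`, `ert`).
#' @export
default_base_configs <- function() {
  list(gbm = base_config("gbm"),
       svm = base_config("svm_rbf"),
       ert = base_config("extra_trees"))
}

#' Assign samples to k cross-validation folds
#'
#' Folds are disjoint, exhaustive, and their sizes differ by at most one.
#' When labels are supplied the assignment is stratified by class (each class
#' spread evenly across folds), which prevents single-class folds on balanced
#' data.
#'
#' @param ids Character vector of sample IDs (or anything of length n).
#' @param k Number of folds (default 10); requires n >= k.
#' @param seed Integer seed.
#' @param labels Optional 0/1 labels enabling stratification; `NULL` gives
#'   plain random folds.
#' @return Integer vector of fold indices in 1..k, named by `ids`.
#' @export
make_folds <- function(ids, k = 10L, seed = 1L, labels = NULL) {
  n <- length(ids)
  if (n < k) stop("need at least k = ", k, " samples, got ", n)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(labels)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    stopifnot(length(labels) == n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  }
  names(fold) <- as.character(ids)
  fold
}

# --- base-learner fitting ---------------------------------------------------
# Each fit returns list(config, model, predict_prob = function(newx) -> p1).
# All learners are pinned to one thread and an explicit seed so that repeated
# fits with the same inputs are bit-identical.

.fit_base <- function(config, x, y, seed) {
  stopifnot(inherits(config, "base_config"))
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; use stratified folds or ",
         "undersample before fitting")
  p <- config$params
  set.seed(seed)
  if (config$family == "gbm") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    params <- list(objective = "binary:logistic", eta = p$learning_rate,
                   max_depth = p$max_depth, subsample = p$subsample,
                   nthread = 1, seed = seed)
    model <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = p$n_estimators, verbose = 0)
    feat <- colnames(x)
    pred <- function(newx)
      as.numeric(stats::predict(model, xgboost::xgb.DMatrix(newx[, feat, drop = FALSE])))
  } else if (config$family == "svm_rbf") {
    yf <- factor(y, levels = c(0L, 1L))
    model <- e1071::svm(x = x, y = yf, kernel = "radial", gamma = p$gamma,
                        cost = p$cost, probability = TRUE, scale = TRUE)
    pred <- function(newx) {
      pr <- stats::predict(model, newx, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    }
  } else {
    yf <- factor(y, levels = c(0L, 1L))
    model <- ranger::ranger(x = x, y = yf, num.trees = p$n_trees,
                            splitrule = "extratrees", num.random.splits = 1L,
                            min.node.size = p$min_leaf, probability = TRUE,
                            seed = seed, num.threads = 1L,
                            respect.unordered.factors = FALSE)
    pred <- function(newx)
      as.numeric(stats::predict(model, data = newx,
                                num.threads = 1L)$predictions[, "1"])
  }
  list(config = config, model = model, predict_prob = pred)
}

#' Out-of-fold base-model probabilities
#'
#' For every sample i and base family m, the positive-class probability
#' predicted by family m trained on all folds EXCEPT the fold containing i.
#' This is the leakage-free input to the meta-model: entry (i, m) never
#' depends on sample i's own label.
#'
#' @param table Labelled [feature_table()].
#' @param configs Named list of [base_config()]s (default
#'   [default_base_configs()]).
#' @param folds Integer fold assignment from [make_folds()].
#' @param seed Integer seed; each (fold, family) fit derives its own
#'   sub-seed.
#' @return n x length(configs) matrix of probabilities in \[0, 1\], columns
#'   named by config, rows by sample ID.
#' @export
generate_oof <- function(table, configs = default_base_configs(), folds,
                         seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("out-of-fold training needs labels")
  k <- max(folds)
  oof <- matrix(NA_real_, nrow = nrow(table$x), ncol = length(configs),
                dimnames = list(table$ids, names(configs)))
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- folds == f
    if (!any(te)) next
    if (length(unique(table$labels[tr])) < 2L)
      stop("fold ", f, " leaves single-class training data; undersample or ",
           "use stratified folds")
    for (m in seq_along(configs)) {
      fit <- .fit_base(configs[[m]], table$x[tr, , drop = FALSE],
                       table$labels[tr], seed = seed + 1000L * f + m)
      oof[te, m] <- fit$predict_prob(table$x[te, , drop = FALSE])
    }
  }
  oof
}

#' Fit the two-layer stacked classifier
#'
#' The core estimator. Layer 1: the training table is split into k
#' stratified folds; gradient boosting, an RBF SVM and extremely randomized
#' trees each produce out-of-fold (OOF) positive-class probabilities.
#' Layer 2: a logistic-regression meta-model is fit on the n x 3 OOF matrix
#' against the labels. For inference, each base family is refit on the full
#' training table and its probabilities are passed through the meta-model.
#'
#' @param table Labelled [feature_table()] (typically undersampled to
#'   balance).
#' @param configs Named list of [base_config()]s; default the three standard
#'   bases.
#' @param k Number of folds (default 10); requires n >= k.
#' @param seed Integer seed controlling folds and every base fit.
#' @param stratify Stratify folds by class (default `TRUE`).
#' @param threshold Probability threshold for label decisions (default 0.5).
#' @return A `pssm_stack` object with components `configs`, `folds`, `oof`,
#'   `base_models`, `meta` (a `glm`), `feature_names`, `labels`, `seed`,
#'   `threshold`. Supports [predict()], [print()], [summary()], [coef()],
#'   [plot()], [residuals()] and [fitted()].
#' @export
fit_stack <- function(table, configs = default_base_configs(), k = 10L,
                      seed = 1L, stratify = TRUE, threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("fit_stack needs labels")
  if (nrow(table$x) < k)
    stop("need at least k = ", k, " samples, got ", nrow(table$x))
  folds <- make_folds(table$ids, k = k, seed = seed,
                      labels = if (stratify) table$labels)
  oof <- generate_oof(table, configs, folds, seed = seed)
  meta_df <- data.frame(oof, check.names = TRUE)
  meta_df$.y <- table$labels
  meta <- suppressWarnings(
    stats::glm(.y ~ ., data = meta_df, family = stats::binomial(),
               control = stats::glm.control(maxit = 100L)))
  base_models <- lapply(seq_along(configs), function(m)
    .fit_base(configs[[m]], table$x, table$labels, seed = seed + m))
  names(base_models) <- names(configs)
  structure(list(configs = configs, folds = folds, oof = oof,
                 base_models = base_models, meta = meta,
                 feature_names = colnames(table$x), labels = table$labels,
                 seed = seed, threshold = threshold, k = k,
                 call = match.call()),
            class = "pssm_stack")
}

# Align a prediction input with the stack's training features (by name).
.align_features <- function(object, newdata) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) || length(extra))
    stop("feature mismatch with the trained stack",
         if (length(missing)) paste0("; missing: ",
                                     paste(utils::head(missing, 5), collapse = ", "),
                                     if (length(missing) > 5) ", ..."),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(utils::head(extra, 5), collapse = ", "),
                                   if (length(extra) > 5) ", ..."))
  x[, object$feature_names, drop = FALSE]
}

#' Predict from a fitted stack
#'
#' @param object A `pssm_stack` from [fit_stack()].
#' @param newdata A [feature_table()] or numeric matrix whose columns match
#'   the stack's training features (order is corrected by name; missing or
#'   extra features are an error).
#' @param type `"prob"` for the meta-model positive-class probability,
#'   `"label"` for 0/1 labels at the stack's threshold, `"base"` for the
#'   n x 3 base-model probability matrix.
#' @param ... Unused.
#' @return Numeric vector (prob), integer vector (label), or matrix (base).
#' @export
predict.pssm_stack <- function(object, newdata,
                               type = c("prob", "label", "base"), ...) {
  type <- match.arg(type)
  x <- .align_features(object, newdata)
  base_p <- vapply(object$base_models, function(b) b$predict_prob(x),
                   numeric(nrow(x)))
  base_p <- matrix(base_p, nrow = nrow(x),
                   dimnames = list(rownames(x), names(object$base_models)))
  if (type == "base") return(base_p)
  nd <- data.frame(base_p, check.names = TRUE)
  prob <- as.numeric(stats::predict(object$meta, nd, type = "response"))
  if (type == "prob") prob else as.integer(prob >= object$threshold)
}

#' @export
print.pssm_stack <- function(x, ...) {
  cat("Two-layer stacked classifier (", length(x$base_models),
      " base learners -> logistic meta-model)\n", sep = "")
  cat("  training samples: ", length(x$labels), " (",
      sum(x$labels == 1L), " pos / ", sum(x$labels == 0L), " neg), features: ",
      length(x$feature_names), ", folds: ", x$k, ", seed: ", x$seed,
      "\n  bases:\n", sep = "")
  for (nm in names(x$configs)) {
    cat("    ", format(nm, width = 4), " ")
    print(x$configs[[nm]])
  }
  invisible(x)
}

#' @export
summary.pssm_stack <- function(object, ...) {
  oof_acc <- vapply(colnames(object$oof), function(m)
    mean((object$oof[, m] >= object$threshold) == (object$labels == 1L)),
    numeric(1))
  stack_prob <- as.numeric(stats::fitted(object$meta))
  cc <- confusion(object$labels, as.integer(stack_prob >= object$threshold))
  out <- list(oof_base_accuracy = oof_acc,
              stack_oof_metrics = classification_metrics(cc),
              stack_oof_auc = roc_auc(object$labels, stack_prob)$auc,
              meta_coefficients = stats::coef(object$meta))
  class(out) <- "summary.pssm_stack"
  out
}

#' @export
print.summary.pssm_stack <- function(x, ...) {
  cat("Out-of-fold base accuracies:\n")
  print(round(x$oof_base_accuracy, 4))
  m <- x$stack_oof_metrics
  cat(sprintf("Stacked (out-of-fold): ACC %.2f%%  SN %.3f  SP %.3f  MCC %.3f  AUC %.3f\n",
              m$ACC, m$SN, m$SP, m$MCC, x$stack_oof_auc))
  cat("Meta-model coefficients:\n")
  print(round(x$meta_coefficients, 4))
  invisible(x)
}

#' @export
coef.pssm_stack <- function(object, ...) stats::coef(object$meta)

#' @export
fitted.pssm_stack <- function(object, ...) as.numeric(stats::fitted(object$meta))

#' @export
residuals.pssm_stack <- function(object, ...)
  object$labels - fitted(object)

#' ROC curve of the stack's out-of-fold predictions
#'
#' @param x A `pssm_stack`.
#' @param ... Passed to `plot.default`.
#' @export
plot.pssm_stack <- function(x, ...) {
  prob <- fitted(x)
  r <- roc_auc(x$labels, prob)
  plot(r$points$fpr, r$points$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("Out-of-fold ROC (AUC = %.3f)", r$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(r)
}

#' Combine base-model probabilities by voting
#'
#' @param prob_matrix n x m matrix of positive-class probabilities (one
#'   column per model).
#' @param mode `"hard"`: majority of per-model labels at 0.5 (ties, possible
#'   with an even model count, resolve by the mean probability); `"soft"`:
#'   mean probability thresholded at 0.5.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 labels, with the soft-vote mean probability attached
#'   as attribute `"prob"`.
#' @export
vote_combine <- function(prob_matrix, mode = c("hard", "soft"),
                         threshold = 0.5) {
  mode <- match.arg(mode)
  prob_matrix <- as.matrix(prob_matrix)
  mean_p <- rowMeans(prob_matrix)
  if (mode == "soft") {
    lab <- as.integer(mean_p >= threshold)
  } else {
    votes <- rowSums(prob_matrix >= threshold)
    m <- ncol(prob_matrix)
    lab <- ifelse(votes * 2L == m, as.integer(mean_p >= threshold),
                  as.integer(votes * 2L > m))
  }
  structure(as.integer(lab), prob = mean_p)
}

#' Majority-voting baseline classifier
#'
#' Fits the base learners on the full training table (no stacking, no
#' meta-model) and combines their probabilities on new data by hard or soft
#' voting — the baseline the stacked model is compared against.
#'
#' @param train Labelled [feature_table()].
#' @param newdata [feature_table()] or matrix to predict (default: the
#'   training table).
#' @param configs Named list of [base_config()]s.
#' @param mode `"hard"` or `"soft"` voting (see [vote_combine()]).
#' @param seed Integer seed.
#' @return List with `label` (0/1), `prob` (mean base probability) and
#'   `base_probs` (n x m matrix).
#' @export
voting_predict <- function(train, newdata = train,
                           configs = default_base_configs(),
                           mode = c("hard", "soft"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "feature_table"))
  x_new <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  fits <- lapply(seq_along(configs), function(m)
    .fit_base(configs[[m]], train$x, train$labels, seed = seed + m))
  base_p <- vapply(fits, function(b) b$predict_prob(x_new), numeric(nrow(x_new)))
  base_p <- matrix(base_p, nrow = nrow(x_new),
                   dimnames = list(rownames(x_new), names(configs)))
  lab <- vote_combine(base_p, mode)
  list(label = as.integer(lab), prob = attr(lab, "prob"), base_probs = base_p)
}

#' Exhaustive grid search over base configurations
#'
#' Evaluates each candidate configuration by k-fold cross-validated accuracy
#' and returns the best; ties break toward the earliest config in the
#' declared order.
#'
#' @param config_space List of [base_config()] candidates.
#' @param table Labelled [feature_table()].
#' @param cv Number of CV folds (default 5).
#' @param seed Integer seed (folds and fits).
#' @return List with `best` (the winning `base_config`), `accuracy` (its mean
#'   CV accuracy) and `results` (per-config accuracies).
#' @export
grid_search <- function(config_space, table, cv = 5L, seed = 1L) {
  stopifnot(length(config_space) >= 1L, inherits(table, "feature_table"))
  folds <- make_folds(table$ids, k = cv, seed = seed, labels = table$labels)
  acc <- vapply(seq_along(config_space), function(ci) {
    mean(vapply(seq_len(cv), function(f) {
      tr <- folds != f
      fit <- .fit_base(config_space[[ci]], table$x[tr, , drop = FALSE],
                       table$labels[tr], seed = seed + 100L * ci + f)
      p <- fit$predict_prob(table$x[!tr, , drop = FALSE])
      mean((p >= 0.5) == (table$labels[!tr] == 1L))
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)   # which.max takes the first maximum: stable ties
  list(best = config_space[[best]], accuracy = acc[best], results = acc)
}

#' Persist / restore a fitted stack
#'
#' Saves the complete stack (configs, folds, OOF matrix, base models, meta
#' model, seed, feature names) to a single versioned RDS archive. The
#' gradient-boosting booster is converted to its raw serialized form so the
#' archive survives R sessions.
#'
#' @param stack A `pssm_stack`.
#' @param path Archive file path.
#' @return `save_stack` returns `path` invisibly; `load_stack` returns the
#'   restored `pssm_stack`, whose predictions are identical to the original's.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "pssm_stack"))
  obj <- stack
  obj$base_models <- lapply(stack$base_models, function(b) {
    if (b$config$family == "gbm")
      list(config = b$config, raw = xgboost::xgb.save.raw(b$model))
    else list(config = b$config, model = b$model)
  })
  saveRDS(list(format = "pssm_stack_archive", version = 1L, stack = obj), path)
  invisible(path)
}

#' @rdname save_stack
#' @export
load_stack <- function(path) {
  arc <- readRDS(path)
  if (!identical(arc$format, "pssm_stack_archive"))
    stop("not a stack archive: ", path)
  stack <- arc$stack
  feat <- stack$feature_names
  stack$base_models <- lapply(stack$base_models, function(b) {
    if (b$config$family == "gbm") {
      model <- xgboost::xgb.load.raw(b$raw)
      pred <- function(newx)
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(newx[, feat, drop = FALSE])))
      list(config = b$config, model = model, predict_prob = pred)
    } else if (b$config$family == "svm_rbf") {
      model <- b$model
      pred <- function(newx) {
        pr <- stats::predict(model, newx, probability = TRUE)
        as.numeric(attr(pr, "probabilities")[, "1"])
      }
      list(config = b$config, model = model, predict_prob = pred)
    } else {
      model <- b$model
      pred <- function(newx)
        as.numeric(stats::predict(model, data = newx,
                                  num.threads = 1L)$predictions[, "1"])
      list(config = b$config, model = model, predict_prob = pred)
    }
  })
  stack
}
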