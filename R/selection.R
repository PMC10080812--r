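#' Feature-label relevance
#'
#' Absolute Pearson correlation between each feature column and the numeric
#' 0/1 label vector; constant features get relevance 0 (never NaN).
#'
#' @param table A labelled [feature_table()] with at least 2 samples per
#'   class.
#' @return Named numeric vector, one value in \[0, 1\] per feature.
#' @export
mrmd_relevance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("relevance needs labels")
  if (min(table(table$labels)) < 2L)
    stop("relevance needs at least 2 samples per class")
  y <- as.numeric(table$labels)
  r <- suppressWarnings(abs(as.vector(stats::cor(table$x, y))))
  r[!is.finite(r)] <- 0
  names(r) <- colnames(table$x)
  r
}

# Pairwise distance between z-scored columns, expressed through the Pearson
# correlation r of the raw columns (z-scoring makes all three metrics
# functions of r alone):
#   euclidean: ||u - v|| / sqrt(n-1) = sqrt(2 (1 - r))   in [0, 2]
#   cosine:    1 - cos(u, v)        = 1 - r              in [0, 2]
#   tanimoto:  1 - u.v/(u.u + v.v - u.v) = 1 - r/(2 - r) in [0, 4/3]
# The sqrt(n-1) normalization keeps euclidean distances commensurate with the
# [0,1] relevance term so the default weight 1 is meaningful.
.dist_from_cor <- function(r, metric) {
  switch(metric,
    euclidean = sqrt(pmax(2 * (1 - r), 0)),
    cosine = 1 - r,
    tanimoto = 1 - r / (2 - r))
}

#' Feature-feature distance (redundancy) term
#'
#' For each feature, the mean pairwise distance between its z-scored column
#' and every other feature's z-scored column; higher means less redundant.
#' Constant (zero-variance) columns cannot be standardized: they receive
#' distance 0 and are excluded from the other features' means.
#'
#' @param table A [feature_table()] with >= 2 features.
#' @param metric One of `"euclidean"` (default; normalized by `sqrt(n-1)`),
#'   `"cosine"`, `"tanimoto"`.
#' @return Named numeric vector, one value >= 0 per feature.
#' @export
mrmd_distance <- function(table, metric = c("euclidean", "cosine", "tanimoto")) {
  stopifnot(inherits(table, "feature_table"))
  metric <- match.arg(metric)
  d <- ncol(table$x)
  if (d < 2L) stop("distance needs at least 2 features")
  sds <- apply(table$x, 2, stats::sd)
  ok <- is.finite(sds) & sds > 0
  out <- stats::setNames(numeric(d), colnames(table$x))
  if (sum(ok) >= 2L) {
    r <- suppressWarnings(stats::cor(table$x[, ok, drop = FALSE]))
    r[!is.finite(r)] <- 0
    dm <- .dist_from_cor(r, metric)
    diag(dm) <- 0
    out[ok] <- rowSums(dm) / (sum(ok) - 1L)
  }
  out
}

#' MRMD feature ranking
#'
#' Max-relevance-max-distance score per feature:
#' `score = relevance + weight * distance`, where relevance is the absolute
#' feature-label Pearson correlation and distance is the mean pairwise
#' distance to all other standardized features. Features are ranked by
#' descending score; ties break by original column index (stable).
#'
#' @inheritParams mrmd_distance
#' @param weight Non-negative multiplier on the distance term (default 1).
#' @return An `mrmd_ranking` object: data frame with `name`, `relevance`,
#'   `distance`, `score`, `rank`, plus the `order` permutation (column indices
#'   by descending score) and the weight/metric used.
#' @export
mrmd_rank <- function(table, weight = 1, metric = "euclidean") {
  rel <- mrmd_relevance(table)
  dist <- mrmd_distance(table, metric)
  score <- rel + weight * dist
  ord <- order(-score, seq_along(score))   # stable index tie-break
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  structure(list(
    table = data.frame(name = colnames(table$x), relevance = unname(rel),
                       distance = unname(dist), score = unname(score),
                       rank = rank, stringsAsFactors = FALSE),
    order = ord, weight = weight, metric = metric),
    class = "mrmd_ranking")
}

#' @export
print.mrmd_ranking <- function(x, n = 10L, ...) {
  cat("MRMD ranking (weight = ", x$weight, ", metric = ", x$metric, "), ",
      nrow(x$table), " features; top ", min(n, nrow(x$table)), ":\n", sep = "")
  top <- x$table[x$order[seq_len(min(n, nrow(x$table)))], ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an MRMD ranking as TSV
#'
#' @param ranking An `mrmd_ranking`.
#' @param path Output path. Rows sorted by descending score.
#' @export
write_mrmd_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "mrmd_ranking"))
  utils::write.table(ranking$table[ranking$order, ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep the k highest-ranked features
#'
#' @param table A [feature_table()].
#' @param ranking An `mrmd_ranking` for the same features.
#' @param k Number of features to keep, 1 <= k <= d.
#' @return A `feature_table` restricted to the k top-ranked features, with
#'   their original relative column order preserved.
#' @export
select_top_k <- function(table, ranking, k) {
  stopifnot(inherits(table, "feature_table"), inherits(ranking, "mrmd_ranking"))
  d <- ncol(table$x)
  if (k < 1L || k > d) stop("k must be in [1, ", d, "], got ", k)
  keep <- sort(ranking$order[seq_len(k)])
  feature_table(table$x[, keep, drop = FALSE], table$ids, table$labels)
}

#' Choose the subset size by cross-validation (one-standard-error rule)
#'
#' Evaluates k-fold cross-validated accuracy of an estimator at each candidate
#' subset size and returns the smallest size whose mean accuracy is within one
#' standard error of the best.
#'
#' @param table Labelled [feature_table()].
#' @param ranking An `mrmd_ranking` for the table.
#' @param k_grid Integer vector of candidate subset sizes, each in \[1, d\].
#' @param estimator_factory Function `(train_table) -> function(test_table) ->
#'   numeric positive-class scores`. Default: ridge-free logistic regression
#'   via `glm`.
#' @param cv_folds Number of CV folds (default 5).
#' @param seed Integer seed controlling fold assignment.
#' @return List with `k` (chosen size), `table` (the selected
#'   `feature_table`), and `cv` (data frame of per-size mean/SE accuracy).
#' @export
select_auto <- function(table, ranking, k_grid,
                        estimator_factory = glm_estimator,
                        cv_folds = 5L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (length(k_grid) == 0L) stop("k_grid must not be empty")
  d <- ncol(table$x)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L | k_grid > d))
    stop("k_grid values must lie in [1, ", d, "]")
  folds <- make_folds(table$ids, k = cv_folds, seed = seed,
                      labels = table$labels)
  res <- lapply(k_grid, function(k) {
    sub <- select_top_k(table, ranking, k)
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- ft_rows(sub, folds != f)
      te <- ft_rows(sub, folds == f)
      scores <- estimator_factory(tr)(te)
      mean((scores >= 0.5) == (te$labels == 1L))
    }, numeric(1))
    c(mean = mean(acc), se = stats::sd(acc) / sqrt(cv_folds))
  })
  cv <- data.frame(k = k_grid,
                   mean_acc = vapply(res, `[[`, 0, "mean"),
                   se = vapply(res, `[[`, 0, "se"))
  best <- which.max(cv$mean_acc)
  threshold <- cv$mean_acc[best] - cv$se[best]
  k_star <- cv$k[which(cv$mean_acc >= threshold)[1]]
  list(k = k_star, table = select_top_k(table, ranking, k_star), cv = cv)
}

#' Logistic-regression estimator factory
#'
#' Default estimator for [select_auto()]: fits `glm(binomial)` on the training
#' table and returns a function producing positive-class probabilities.
#'
#' @param train A labelled [feature_table()].
#' @return Function mapping a `feature_table` to numeric scores in \[0, 1\].
#' @export
glm_estimator <- function(train) {
  df <- data.frame(y = train$labels, train$x, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  function(test) {
    nd <- data.frame(test$x, check.names = TRUE)
    as.numeric(suppressWarnings(stats::predict(fit, nd, type = "response")))
  }
}
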