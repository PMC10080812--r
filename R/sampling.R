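#' Random undersampling of the majority class
#'
#' Keeps every minority-class sample and draws `round(ratio * n_minority)`
#' majority-class samples without replacement; the resulting rows are shuffled
#' deterministically by the seed. Intended for the TRAINING portion only — an
#' independent test set should keep its natural imbalance.
#'
#' @param table Labelled [feature_table()] containing both classes.
#' @param ratio Majority-to-minority ratio after sampling (default 1, i.e.
#'   balanced).
#' @param seed Integer seed.
#' @return A `feature_table` with all minority rows plus the sampled majority
#'   rows.
#' @export
random_undersample <- function(table, ratio = 1.0, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("undersampling needs labels")
  counts <- table(factor(table$labels, levels = c(0L, 1L)))
  if (any(counts == 0L)) stop("both classes must be present")
  if (ratio <= 0) stop("ratio must be > 0")
  minority <- if (counts["1"] <= counts["0"]) 1L else 0L
  n_min <- min(counts)
  n_keep <- round(ratio * n_min)
  maj_idx <- which(table$labels != minority)
  if (n_keep > length(maj_idx))
    stop("ratio ", ratio, " needs ", n_keep, " majority samples but only ",
         length(maj_idx), " exist")
  set.seed(seed)
  keep <- c(which(table$labels == minority), sample(maj_idx, n_keep))
  keep <- sample(keep)   # deterministic shuffle
  ft_rows(table, keep)
}

#' Stratified train/test split
#'
#' Splits a labelled table into disjoint train and test tables, preserving
#' class proportions to within one sample per class.
#'
#' @param table Labelled [feature_table()].
#' @param test_fraction Fraction of each class assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with `train` and `test` feature tables (disjoint IDs).
#' @export
stratified_split <- function(table, test_fraction, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("stratified split needs labels")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  set.seed(seed)
  test_idx <- unlist(lapply(unique(table$labels), function(cl) {
    idx <- which(table$labels == cl)
    sample(idx, round(test_fraction * length(idx)))
  }))
  list(train = ft_rows(table, setdiff(seq_along(table$ids), test_idx)),
       test = ft_rows(table, sort(test_idx)))
}
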