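#' Merge a scaled PSSM onto a reduced 10-letter alphabet
#'
#' Column s of the output is the row-wise arithmetic mean of the member
#' columns of group s, so an L x 20 matrix in (0,1) becomes an L x 10 matrix
#' in (0,1).
#'
#' @param scaled A `scaled_pssm` from [sigmoid_scale()].
#' @param scheme A [reduction_scheme()]; defaults to
#'   [default_reduction_scheme()].
#' @return A `reduced_pssm` object with an L x 10 `values` matrix whose
#'   columns are labelled by group membership.
#' @export
reduce_pssm <- function(scaled, scheme = default_reduction_scheme()) {
  stopifnot(inherits(scaled, "scaled_pssm"), inherits(scheme, "reduction_scheme"))
  v <- scaled$values
  out <- vapply(scheme$groups, function(g) {
    cols <- v[, g, drop = FALSE]
    rowMeans(cols)
  }, numeric(nrow(v)))
  out <- matrix(out, nrow = nrow(v), ncol = 10L,
                dimnames = list(NULL, scheme$labels))
  structure(list(id = scaled$id, values = out, scheme = scheme),
            class = "reduced_pssm")
}

#' Pseudo-composition terms of a reduced PSSM
#'
#' For each of the 10 reduced columns, the population variance of the column:
#' D_s = (1/L) * sum_i (p_is - mean_s)^2. Captures how variable the
#' substitution preference for group s is along the sequence.
#'
#' @param reduced A `reduced_pssm` from [reduce_pssm()].
#' @return Numeric vector of length 10, each entry >= 0.
#' @export
rpssm_ds <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_pssm"))
  v <- reduced$values
  L <- nrow(v)
  means <- colMeans(v)
  colSums((v - rep(means, each = L))^2) / L
}

#' Dipeptide pseudo-composition terms of a reduced PSSM
#'
#' For every ordered pair of reduced groups (s, t),
#' D_st = (1/(L-1)) * sum_{i=1}^{L-1} (p_is - p_{i+1,t})^2 / 2 —
#' a local sequence-order term over adjacent rows. Returned in row-major
#' order (s outer, t inner); the diagonal of an all-identical-rows matrix
#' is exactly zero.
#'
#' @inheritParams rpssm_ds
#' @return Numeric vector of length 100, each entry >= 0.
#' @export
rpssm_dst <- function(reduced) {
  stopifnot(inherits(reduced, "reduced_pssm"))
  v <- reduced$values
  L <- nrow(v)
  if (L < 2L) stop("dipeptide terms need L >= 2, got L = ", L)
  a <- v[-L, , drop = FALSE]   # rows 1..L-1
  b <- v[-1L, , drop = FALSE]  # rows 2..L
  # direct squared differences; the expanded crossprod form cancels
  # catastrophically when adjacent reduced values nearly coincide
  d <- matrix(0, 10L, 10L)
  for (t in 1:10)
    d[, t] <- colSums((a - b[, t])^2 / 2) / (L - 1)
  as.vector(t(d))                     # row-major: s outer, t inner
}

#' Extract the 110-dimensional RPSSM feature vector
#'
#' Concatenates the 10 column-variance terms ([rpssm_ds()]) and the 100
#' adjacent-row dipeptide terms ([rpssm_dst()]) computed on the reduced
#' (L x 10) matrix.
#'
#' @inheritParams reduce_pssm
#' @return Named numeric vector of length 110 (`rpssm_D_<s>`,
#'   `rpssm_Dst_<s>_<t>`).
#' @export
extract_rpssm <- function(scaled, scheme = default_reduction_scheme()) {
  red <- reduce_pssm(scaled, scheme)
  ds <- rpssm_ds(red)
  dst <- rpssm_dst(red)
  names(ds) <- paste0("rpssm_D_", 1:10)
  names(dst) <- paste0("rpssm_Dst_", rep(1:10, each = 10), "_", rep(1:10, 10))
  c(ds, dst)
}

#' Amino-acid composition of a scaled PSSM (AAC-PSSM)
#'
#' Column means of the scaled matrix: x_j = (1/L) * sum_i p_ij for each of the
#' 20 amino-acid columns — the average evolutionary propensity to mutate to
#' amino acid j.
#'
#' @inheritParams reduce_pssm
#' @return Named numeric vector of length 20, entries in (0, 1).
#' @export
aac_pssm <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_pssm"))
  x <- colMeans(scaled$values)
  names(x) <- paste0("aac_", pssm_aa_order)
  x
}

#' Dipeptide composition of a scaled PSSM (DPC-PSSM)
#'
#' Adjacent-row cross products:
#' y_ij = (1/(L-1)) * sum_{k=1}^{L-1} p_ki * p_{k+1,j} for all 400 ordered
#' column pairs (i, j), in row-major order.
#'
#' @inheritParams reduce_pssm
#' @return Named numeric vector of length 400, entries in (0, 1) for scaled
#'   input.
#' @export
dpc_pssm <- function(scaled) {
  stopifnot(inherits(scaled, "scaled_pssm"))
  v <- scaled$values
  L <- nrow(v)
  if (L < 2L) stop("DPC terms need L >= 2, got L = ", L)
  y <- crossprod(v[-L, , drop = FALSE], v[-1L, , drop = FALSE]) / (L - 1)
  out <- as.vector(t(y))
  names(out) <- paste0("dpc_", rep(pssm_aa_order, each = 20), "_",
                       rep(pssm_aa_order, 20))
  out
}

#' Extract the 420-dimensional AADP-PSSM feature vector
#'
#' AAC-PSSM (20) followed by DPC-PSSM (400).
#'
#' @inheritParams reduce_pssm
#' @return Named numeric vector of length 420.
#' @export
extract_aadp <- function(scaled) {
  c(aac_pssm(scaled), dpc_pssm(scaled))
}

#' Extract the combined 530-dimensional feature vector
#'
#' RPSSM (110) followed by AADP-PSSM (420). Name prefixes (`rpssm_`, `aac_`,
#' `dpc_`) distinguish the families; ordering is fixed so serialized tables
#' are stable across runs.
#'
#' @inheritParams reduce_pssm
#' @return Named numeric vector of length 530.
#' @export
extract_all <- function(scaled, scheme = default_reduction_scheme()) {
  c(extract_rpssm(scaled, scheme), extract_aadp(scaled))
}

#' Construct a feature table
#'
#' The tabular container shared by selection, sampling and the ensemble:
#' an n x d numeric matrix with unique feature names, sample IDs and optional
#' binary labels (1 = positive class, 0 = other).
#'
#' @param x Numeric matrix (n x d) with column names.
#' @param ids Character vector of n unique sample IDs.
#' @param labels Optional integer/numeric vector of n labels in \{0, 1\}.
#' @return A `feature_table` object.
#' @export
feature_table <- function(x, ids, labels = NULL) {
  x <- as.matrix(x)
  if (nrow(x) > 0) storage.mode(x) <- "double"
  ids <- as.character(ids)
  if (length(ids) != nrow(x))
    stop("ids length (", length(ids), ") != row count (", nrow(x), ")")
  if (anyDuplicated(ids)) stop("sample IDs must be unique")
  if (is.null(colnames(x)) && ncol(x) > 0)
    stop("feature columns must be named")
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x))
      stop("labels length (", length(labels), ") != row count (", nrow(x), ")")
    if (!all(labels %in% c(0L, 1L)))
      stop("labels must be binary 0/1")
  }
  rownames(x) <- ids
  structure(list(x = x, ids = ids, labels = labels), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table: ", nrow(x$x), " samples x ", ncol(x$x), " features",
      if (!is.null(x$labels))
        paste0(" (", sum(x$labels == 1L), " positive / ",
               sum(x$labels == 0L), " negative)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$label <- x$labels
  cbind(df, as.data.frame(x$x, optional = TRUE))
}

#' Subset a feature table by row
#'
#' @param table A [feature_table()].
#' @param i Row index vector (integer, logical, or sample IDs).
#' @return A `feature_table` with the selected rows.
#' @export
ft_rows <- function(table, i) {
  stopifnot(inherits(table, "feature_table"))
  if (is.character(i)) i <- match(i, table$ids)
  feature_table(table$x[i, , drop = FALSE], table$ids[i],
                if (!is.null(table$labels)) table$labels[i])
}

#' Featurize a batch of PSSM profiles
#'
#' Runs sigmoid scaling and the full 530-feature extraction over a list of
#' profiles and assembles a labelled [feature_table()]. Labels are attached by
#' profile ID.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param labels Optional named vector (names = profile IDs) or unnamed vector
#'   aligned with `profiles`, values in \{0, 1\}.
#' @param scheme Reduction scheme for the RPSSM block.
#' @param features Which feature families to compute: `"all"` (530), `"rpssm"`
#'   (110) or `"aadp"` (420).
#' @return A `feature_table` with one row per profile, rows in input order.
#' @export
featurize_batch <- function(profiles, labels = NULL,
                            scheme = default_reduction_scheme(),
                            features = c("all", "rpssm", "aadp")) {
  features <- match.arg(features)
  extractor <- switch(features,
    all = function(s) extract_all(s, scheme),
    rpssm = function(s) extract_rpssm(s, scheme),
    aadp = extract_aadp)
  ids <- vapply(profiles, function(p) p$id, "")
  if (length(profiles) == 0L) {
    return(feature_table(matrix(numeric(0), 0, 0), character(0),
                         if (!is.null(labels)) integer(0)))
  }
  rows <- lapply(profiles, function(p) extractor(sigmoid_scale(p)))
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  lab <- NULL
  if (!is.null(labels)) {
    if (!is.null(names(labels))) {
      miss <- setdiff(names(labels), ids)
      if (length(miss))
        stop("label IDs not among profiles: ", paste(miss, collapse = ", "))
      if (!all(ids %in% names(labels)))
        stop("profiles without labels: ",
             paste(setdiff(ids, names(labels)), collapse = ", "))
      lab <- unname(labels[ids])
    } else {
      if (length(labels) != length(profiles))
        stop("unnamed labels must align with profiles (",
             length(labels), " vs ", length(profiles), ")")
      lab <- labels
    }
  }
  feature_table(x, ids, lab)
}

#' Write / read a feature table as TSV
#'
#' Plain-text serialization: columns `id`, `label` (omitted when absent), then
#' the named features in table order; full precision (`%.17g`).
#'
#' @param table A [feature_table()].
#' @param path Output / input file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!is.character(path) || !file.exists(path))
    stop("feature table file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("feature table file lacks an 'id' column")
  labels <- if ("label" %in% names(df)) df$label
  feat <- setdiff(names(df), c("id", "label"))
  feature_table(as.matrix(df[feat]), df$id, labels)
}
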