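#' Construct a PSSM profile
#'
#' Container for one protein's position-specific scoring matrix: an L x 20
#' matrix of log-odds scores (PSI-BLAST column order, see [pssm_aa_order]),
#' the residue sequence, and an identifier. Rows are 1-based in ASCII files;
#' internally the matrix is a plain R matrix indexed from 1 as usual.
#'
#' @param id Protein identifier string.
#' @param sequence Residue string; length must equal `nrow(scores)`. Ambiguity
#'   codes (X, B, Z, ...) are kept — their score rows are still defined.
#' @param scores L x 20 numeric matrix of log-odds values, L >= 2.
#' @return A `pssm_profile` object.
#' @export
pssm_profile <- function(id, sequence, scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20L)
    stop("a PSSM needs exactly 20 score columns, got ", ncol(scores))
  if (nrow(scores) < 2L)
    stop("a PSSM needs at least 2 rows (dipeptide terms need two residues), got ",
         nrow(scores))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) != nrow(scores))
    stop("sequence length (", nchar(sequence), ") does not match PSSM rows (",
         nrow(scores), ")")
  if (any(!is.finite(scores)))
    stop("PSSM scores must be finite")
  colnames(scores) <- pssm_aa_order
  rownames(scores) <- NULL
  structure(list(id = as.character(id), sequence = sequence, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile '", x$id, "': L = ", nrow(x$scores),
      ", score range [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

# Row regex of the ASCII dialect: position index, residue letter, then numbers.
.pssm_row_re <- "^\\s*[0-9]+\\s+[A-Za-z*]\\s+-?[0-9]"

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the plain-text matrix written by PSI-BLAST's `-out_ascii_pssm`
#' option: header lines, then one row per residue holding the position index,
#' the residue letter and 20 log-odds integers, optionally followed by 20
#' weighted-percentage columns and two trailing per-row statistics. Both the
#' 20-column and the 40-column dialects are accepted; the FIRST 20 numeric
#' columns are always taken as the log-odds scores.
#'
#' @param text_or_path Path to a PSSM file, or the file's lines as a character
#'   vector (anything of length > 1, or containing a newline, is treated as
#'   text).
#' @param id Identifier for the returned profile; defaults to the file's base
#'   name (or `"pssm"` for in-memory text).
#' @return A [pssm_profile()].
#' @export
parse_pssm_ascii <- function(text_or_path, id = NULL) {
  if (length(text_or_path) == 1L && !grepl("\n", text_or_path)) {
    if (!file.exists(text_or_path))
      stop("PSSM file not found: ", text_or_path)
    lines <- readLines(text_or_path, warn = FALSE)
    if (is.null(id))
      id <- sub("\\.[^.]*$", "", basename(text_or_path))
  } else {
    lines <- unlist(strsplit(text_or_path, "\n", fixed = TRUE))
    if (is.null(id)) id <- "pssm"
  }

  is_row <- grepl(.pssm_row_re, lines)
  if (!any(is_row))
    stop("no PSSM matrix rows found (empty matrix?)")
  row_idx <- which(is_row)
  # matrix rows are contiguous; trailing statistics lines do not match the
  # row pattern (they start with letters), so the first block is the matrix
  first <- row_idx[1]
  last <- first
  while (last + 1L <= length(lines) && is_row[last + 1L]) last <- last + 1L
  row_lines <- lines[first:last]
  line_nums <- first:last

  n_expected <- NA_integer_
  positions <- integer(length(row_lines))
  letters_v <- character(length(row_lines))
  scores <- matrix(NA_real_, nrow = length(row_lines), ncol = 20L)
  for (r in seq_along(row_lines)) {
    tok <- strsplit(trimws(row_lines[r]), "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(tok[1]))
    res <- tok[2]
    nums <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (anyNA(nums))
      stop("line ", line_nums[r], ": non-numeric value in PSSM row")
    if (is.na(n_expected)) {
      if (!length(nums) %in% c(20L, 22L, 40L, 42L))
        stop("line ", line_nums[r], ": expected 20 or 40 numeric columns ",
             "(optionally plus 2 statistics), got ", length(nums))
      n_expected <- length(nums)
    } else if (length(nums) != n_expected) {
      stop("line ", line_nums[r], ": expected ", n_expected,
           " numeric columns, got ", length(nums))
    }
    positions[r] <- pos
    letters_v[r] <- toupper(res)
    scores[r, ] <- nums[1:20]
  }
  if (anyDuplicated(positions))
    stop("duplicate position indices in PSSM: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  pssm_profile(id = id, sequence = paste(letters_v, collapse = ""),
               scores = scores)
}

#' Sigmoid-scale a PSSM
#'
#' Maps every log-odds entry x to 1 / (1 + exp(-x)), squashing the matrix into
#' the open interval (0, 1). All downstream feature extractors assume this
#' scaling.
#'
#' @param profile A [pssm_profile()].
#' @return A `scaled_pssm` object: same shape and column order, entries in
#'   (0, 1).
#' @export
sigmoid_scale <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  x <- profile$scores
  if (any(!is.finite(x)))
    stop("non-finite PSSM entry; cannot scale")
  v <- 1 / (1 + exp(-x))
  structure(list(id = profile$id, values = v, column_order = pssm_aa_order),
            class = "scaled_pssm")
}

#' @export
print.scaled_pssm <- function(x, ...) {
  cat("Sigmoid-scaled PSSM '", x$id, "': L = ", nrow(x$values), " x 20\n",
      sep = "")
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin wrapper over `seqinr::read.fasta`: IDs are the first
#' whitespace-delimited token after '>'; sequences are uppercased. Residues
#' outside the IUPAC amino-acid codes trigger a warning (the records are still
#' returned).
#'
#' @param path FASTA file path.
#' @return Named list of uppercase sequence strings (names are record IDs);
#'   empty list for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L || !any(grepl("^>", readLines(path, warn = FALSE))))
    return(list())
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- lapply(recs, function(s) toupper(as.character(s)[1]))
  names(out) <- vapply(names(recs), function(n) strsplit(n, "\\s+")[[1]][1], "")
  bad <- vapply(out, function(s) {
    any(!strsplit(s, "")[[1]] %in% c(.iupac_aa, "-"))
  }, logical(1))
  if (any(bad))
    warning("non-IUPAC amino-acid codes in records: ",
            paste(names(out)[bad], collapse = ", "))
  out
}
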