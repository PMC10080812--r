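#' Simulation settings for synthetic labelled PSSM profiles
#'
#' Describes a synthetic two-class population of PSSM profiles: scores are
#' rounded Gaussian log-odds (mean 0, sd `noise_sd`, mimicking the integer
#' scores of real profiles), and positive-class profiles additionally receive
#' a mean shift of `effect_size` in the designated `signal_columns` BEFORE
#' sigmoid scaling, so both the RPSSM and AADP feature families carry class
#' information through the documented pipeline. `effect_size = 0` makes the
#' two classes identically distributed (chance-level control).
#'
#' @param n_pos,n_neg Positive / negative sample counts.
#' @param length_range Integer min/max sequence length L (min >= 2).
#' @param effect_size Mean log-odds shift (>= 0) applied to `signal_columns`
#'   for positives.
#' @param signal_columns Indices (1..20) of the shifted columns.
#' @param noise_sd Standard deviation of the Gaussian log-odds noise.
#' @param seed Integer seed.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_pos = 100L, n_neg = 100L,
                            length_range = c(30L, 120L), effect_size = 1.0,
                            signal_columns = 1:5, noise_sd = 2.0, seed = 1L) {
  stopifnot(n_pos >= 0, n_neg >= 0, length(length_range) == 2L,
            length_range[1] >= 2L, length_range[1] <= length_range[2],
            effect_size >= 0, all(signal_columns %in% 1:20), noise_sd > 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 effect_size = effect_size,
                 signal_columns = as.integer(signal_columns),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Simulation spec: ", x$n_pos, " pos / ", x$n_neg, " neg, L in [",
      x$length_range[1], ", ", x$length_range[2], "], effect ",
      x$effect_size, " on columns {",
      paste(x$signal_columns, collapse = ","), "}, noise sd ", x$noise_sd,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate one synthetic PSSM profile
#'
#' Scores are `round(rnorm(L * 20, 0, noise_sd))` with `effect_size` added to
#' the signal columns when `class_label == 1`. The residue letter of each row
#' is the amino acid of that row's maximum score (plausibility only; no
#' downstream computation reads the sequence).
#'
#' @param L Sequence length (>= 2).
#' @param class_label 0 or 1.
#' @param spec A [simulation_spec()].
#' @param id Profile identifier.
#' @return A [pssm_profile()].
#' @export
gen_profile <- function(L, class_label, spec, id = "synthetic") {
  stopifnot(inherits(spec, "simulation_spec"), L >= 2L)
  scores <- matrix(stats::rnorm(L * 20L, 0, spec$noise_sd), nrow = L)
  if (as.integer(class_label) == 1L)
    scores[, spec$signal_columns] <- scores[, spec$signal_columns] +
      spec$effect_size
  scores <- round(scores)
  seq_letters <- pssm_aa_order[max.col(scores, ties.method = "first")]
  pssm_profile(id = id, sequence = paste(seq_letters, collapse = ""),
               scores = scores)
}

#' Generate a labelled synthetic dataset
#'
#' `n_pos + n_neg` profiles with lengths drawn uniformly from `length_range`;
#' fully reproducible from `spec$seed`. Positives are listed first (IDs
#' `pos_1..`, `neg_1..`); shuffle downstream if order matters.
#'
#' @param spec A [simulation_spec()].
#' @return List with `profiles` (list of [pssm_profile()]) and `labels`
#'   (named 0/1 vector aligned with profile IDs).
#' @export
gen_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  ids <- c(sprintf("pos_%d", seq_len(spec$n_pos)),
           sprintf("neg_%d", seq_len(spec$n_neg)))
  rng <- spec$length_range[1]:spec$length_range[2]
  lens <- rng[sample.int(length(rng), n, replace = TRUE)]
  profiles <- lapply(seq_len(n), function(i)
    gen_profile(lens[i], labels[i], spec, id = ids[i]))
  names(labels) <- ids
  list(profiles = profiles, labels = labels)
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' Emits the standard layout: two header lines, the double 20-column header
#' row, one row per residue (position, letter, 20 log-odds integers and — in
#' the default 40-column dialect — 20 weighted-percentage integers plus two
#' per-row statistics), and the trailing K/Lambda block. Round-trips exactly
#' through [parse_pssm_ascii()].
#'
#' @param profile A [pssm_profile()] with integer-valued scores.
#' @param path Output file path.
#' @param dialect `"40col"` (default, log-odds + percentages) or `"20col"`.
#' @return `path`, invisibly.
#' @export
gen_ascii_pssm <- function(profile, path, dialect = c("40col", "20col")) {
  stopifnot(inherits(profile, "pssm_profile"))
  dialect <- match.arg(dialect)
  sc <- profile$scores
  if (max(abs(sc - round(sc))) > 1e-8)
    stop("ASCII PSSM scores must be integers (PSI-BLAST prints integers)")
  sc <- round(sc)
  header <- c("",
              paste("Last position-specific scoring matrix computed, weighted",
                    "observed percentages rounded down, information per",
                    "position, and relative weight of gapless real matches",
                    "to pseudocounts"),
              paste0("           ",
                     paste(sprintf("%3s", pssm_aa_order), collapse = ""),
                     if (dialect == "40col")
                       paste0("  ",
                              paste(sprintf("%3s", pssm_aa_order), collapse = ""))))
  res <- strsplit(profile$sequence, "")[[1]]
  rows <- vapply(seq_len(nrow(sc)), function(i) {
    line <- sprintf("%5d %s %s", i, res[i],
                    paste(sprintf("%3d", sc[i, ]), collapse = ""))
    if (dialect == "40col") {
      # synthetic weighted-percentage block: softmax-like rounded percentages
      w <- exp(sc[i, ] - max(sc[i, ]))
      pct <- floor(100 * w / sum(w))
      line <- paste0(line, "  ", paste(sprintf("%3d", pct), collapse = ""),
                     sprintf("  %4.2f %4.2f", 0.5, 1.0))
    }
    line
  }, character(1))
  footer <- c("", "                      K         Lambda",
              "Standard Ungapped    0.1347     0.3179", "")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}

#' Write FASTA records
#'
#' 60-character line wrapping; round-trips through [read_fasta()].
#'
#' @param records Named list/vector of sequence strings (names = IDs).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
gen_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    s <- as.character(records[[nm]])
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Write a label table as TSV
#'
#' @param labels Named 0/1 vector (names = profile IDs).
#' @param path Output file path (columns `id`, `label`).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(id = names(labels), label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @param path File written by `write_labels`.
#' @return `read_labels` returns the named integer vector.
#' @export
read_labels <- function(path) {
  if (!is.character(path) || !file.exists(path))
    stop("label file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(df)))
    stop("label file needs 'id' and 'label' columns")
  stats::setNames(as.integer(df$label), df$id)
}
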