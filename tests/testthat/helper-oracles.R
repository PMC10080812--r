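# Independent naive-loop oracles. These deliberately re-derive every quantity
# with explicit double loops / direct formulas, sharing no code with the
# package implementation.

oracle_reduce <- function(scaled, groups) {
  L <- nrow(scaled)
  out <- matrix(0, L, 10)
  for (s in 1:10) {
    cols <- match(groups[[s]], pssm_aa_order)
    for (i in 1:L) out[i, s] <- mean(scaled[i, cols])
  }
  out
}

oracle_rpssm <- function(scaled, groups) {
  red <- oracle_reduce(scaled, groups)
  L <- nrow(red)
  ds <- numeric(10)
  for (s in 1:10) {
    m <- mean(red[, s])
    acc <- 0
    for (i in 1:L) acc <- acc + (red[i, s] - m)^2
    ds[s] <- acc / L
  }
  dst <- numeric(100)
  idx <- 0
  for (s in 1:10) for (t in 1:10) {
    idx <- idx + 1
    acc <- 0
    for (i in 1:(L - 1)) acc <- acc + (red[i, s] - red[i + 1, t])^2 / 2
    dst[idx] <- acc / (L - 1)
  }
  c(ds, dst)
}

oracle_aac <- function(scaled) {
  out <- numeric(20)
  for (j in 1:20) out[j] <- sum(scaled[, j]) / nrow(scaled)
  out
}

oracle_dpc <- function(scaled) {
  L <- nrow(scaled)
  out <- numeric(400)
  idx <- 0
  for (i in 1:20) for (j in 1:20) {
    idx <- idx + 1
    acc <- 0
    for (k in 1:(L - 1)) acc <- acc + scaled[k, i] * scaled[k + 1, j]
    out[idx] <- acc / (L - 1)
  }
  out
}

oracle_metrics <- function(tp, tn, fp, fn) {
  sn <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  den <- sqrt((tp + fn)) * sqrt((tp + fp)) * sqrt((tn + fp)) * sqrt((tn + fn))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(SN = sn, SP = sp, ACC = acc, MCC = mcc)
}

# Mann-Whitney rank formulation of the ROC area.
oracle_auc_rank <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# --- fixture builders -------------------------------------------------------

random_profile <- function(L, seed, id = paste0("p", seed)) {
  set.seed(seed)
  pssm_profile(id, paste(sample(pssm_aa_order, L, replace = TRUE), collapse = ""),
               matrix(round(rnorm(L * 20, 0, 3)), nrow = L))
}

# n x d feature table: first n_signal features shifted by `effect` for the
# positive class, the rest pure noise.
signal_table <- function(n = 100, d = 20, n_signal = 5, effect = 2, seed = 1) {
  stopifnot(n_signal <= d)
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * d), n, d)
  for (j in seq_len(n_signal)) x[, j] <- x[, j] + effect * y
  colnames(x) <- sprintf("f%02d", seq_len(d))
  feature_table(x, sprintf("s%03d", seq_len(n)), y)
}

# small base configs for structural ensemble tests (the fold mechanics under
# test do not depend on learner size)
light_configs <- function() {
  list(gbm = base_config("gbm", n_estimators = 25L, max_depth = 3L),
       svm = base_config("svm_rbf"),
       ert = base_config("extra_trees", n_trees = 30L))
}
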