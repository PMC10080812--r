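scaled_from <- function(m, id = "t") {
  # wrap an arbitrary (0,1) matrix as a scaled_pssm via the inverse sigmoid,
  # so tests exercise the public path
  stopifnot(all(m > 0 & m < 1))
  sigmoid_scale(pssm_profile(id, strrep("A", nrow(m)), log(m / (1 - m))))
}

test_that("dimension contracts hold: 110 + 420 = 530", {
  p <- random_profile(25, seed = 1)
  s <- sigmoid_scale(p)
  expect_length(extract_rpssm(s), 110L)
  expect_length(extract_aadp(s), 420L)
  expect_length(extract_all(s), 530L)
  expect_length(aac_pssm(s), 20L)
  expect_length(dpc_pssm(s), 400L)
  expect_length(rpssm_ds(reduce_pssm(s)), 10L)
  expect_length(rpssm_dst(reduce_pssm(s)), 100L)
})

test_that("reduction: constant matrices stay constant, singleton groups pass through", {
  m <- matrix(0.37, 6, 20, dimnames = list(NULL, pssm_aa_order))
  s <- scaled_from(m)
  red <- reduce_pssm(s)
  expect_true(all(abs(red$values - 0.37) < 1e-12))
  expect_equal(dim(red$values), c(6L, 10L))

  s2 <- sigmoid_scale(random_profile(8, seed = 2))
  red2 <- reduce_pssm(s2)
  # group 8 is the singleton {C}: its reduced column is the C column verbatim
  expect_equal(unname(red2$values[, 8]), unname(s2$values[, "C"]))
})

test_that("reduction on a 2x20 fixture equals hand-computed group means", {
  set.seed(3)
  m <- matrix(runif(40, 0.05, 0.95), 2, 20, dimnames = list(NULL, pssm_aa_order))
  red <- reduce_pssm(scaled_from(m))
  groups <- default_reduction_scheme()$groups
  for (g in seq_len(10)) for (i in 1:2)
    expect_equal(unname(red$values[i, g]),
                 mean(m[i, match(groups[[g]], pssm_aa_order)]))
})

test_that("invalid reduction schemes are rejected", {
  expect_error(reduction_scheme(as.list(pssm_aa_order)[1:9]), "10 groups")
  bad <- default_reduction_scheme()$groups
  bad[[1]] <- c("F", "Y")              # drops W: not covering
  expect_error(reduction_scheme(bad), "missing: W")
  bad2 <- default_reduction_scheme()$groups
  bad2[[2]] <- c("M", "L", "F")        # F duplicated
  expect_error(reduction_scheme(bad2), "disjoint")
})

test_that("rpssm_ds: zero variance gives 0; (0,1)-column fixture gives 1/4", {
  m <- matrix(0.6, 4, 20, dimnames = list(NULL, pssm_aa_order))
  expect_equal(unname(rpssm_ds(reduce_pssm(scaled_from(m)))), rep(0, 10))

  # push group {C} (singleton, index 8) to values ~0 and ~1 across two rows:
  # population variance of (eps, 1-eps) tends to 0.25
  m2 <- matrix(0.5, 2, 20, dimnames = list(NULL, pssm_aa_order))
  m2[1, "C"] <- 1e-9; m2[2, "C"] <- 1 - 1e-9
  ds <- rpssm_ds(reduce_pssm(scaled_from(m2)))
  expect_equal(unname(ds[8]), 0.25, tolerance = 1e-6)
})

test_that("rpssm_dst: identical rows zero the diagonal; L=2 matches hand formula", {
  set.seed(4)
  row <- runif(20, 0.1, 0.9)
  m <- rbind(row, row, row)
  dimnames(m) <- list(NULL, pssm_aa_order)
  red <- reduce_pssm(scaled_from(m))
  dst <- matrix(rpssm_dst(red), 10, 10, byrow = TRUE)
  v <- red$values[1, ]
  expect_equal(unname(diag(dst)), rep(0, 10))
  expect_equal(dst, outer(v, v, function(a, b) (a - b)^2 / 2),
               ignore_attr = TRUE, tolerance = 1e-12)

  m2 <- matrix(runif(40, 0.1, 0.9), 2, 20, dimnames = list(NULL, pssm_aa_order))
  red2 <- reduce_pssm(scaled_from(m2))
  u <- red2$values[1, ]; w <- red2$values[2, ]
  expect_equal(matrix(rpssm_dst(red2), 10, 10, byrow = TRUE),
               outer(u, w, function(a, b) (a - b)^2 / 2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("aac/dpc: constant and 2-row fixtures match hand computations", {
  m <- matrix(0.25, 5, 20, dimnames = list(NULL, pssm_aa_order))
  s <- scaled_from(m)
  expect_equal(unname(aac_pssm(s)), rep(0.25, 20))
  expect_equal(unname(dpc_pssm(s)), rep(0.0625, 400))

  set.seed(5)
  m2 <- matrix(runif(40, 0.1, 0.9), 2, 20, dimnames = list(NULL, pssm_aa_order))
  s2 <- scaled_from(m2)
  expect_equal(unname(aac_pssm(s2)), unname(colMeans(m2)), tolerance = 1e-12)
  expect_equal(matrix(dpc_pssm(s2), 20, 20, byrow = TRUE),
               outer(m2[1, ], m2[2, ]), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("all features equal the naive-loop oracle on random profiles", {
  groups <- default_reduction_scheme()$groups
  for (seed in 1:8) {
    L <- sample(2:60, 1)
    p <- random_profile(L, seed = 100 + seed)
    s <- sigmoid_scale(p)
    v <- s$values
    expect_equal(unname(extract_rpssm(s)), oracle_rpssm(v, groups),
                 tolerance = 1e-12)
    expect_equal(unname(aac_pssm(s)), oracle_aac(v), tolerance = 1e-12)
    expect_equal(unname(dpc_pssm(s)), oracle_dpc(v), tolerance = 1e-12)
    expect_equal(unname(extract_all(s)),
                 c(oracle_rpssm(v, groups), oracle_aac(v), oracle_dpc(v)),
                 tolerance = 1e-12)
  }
})

test_that("feature values respect their ranges and concatenation order", {
  s <- sigmoid_scale(random_profile(33, seed = 6))
  all_f <- extract_all(s)
  expect_true(all(all_f[1:110] >= 0))                    # sums of squares
  expect_true(all(all_f[111:530] > 0 & all_f[111:530] < 1))
  expect_identical(all_f[1:110], extract_rpssm(s))
  expect_identical(all_f[111:130], aac_pssm(s))
  expect_identical(all_f[131:530], dpc_pssm(s))
  expect_false(anyDuplicated(names(all_f)) > 0)
})

test_that("row permutation keeps composition terms, changes order-sensitive terms", {
  p <- random_profile(30, seed = 7)
  set.seed(8)
  perm <- sample(30)
  q <- pssm_profile(p$id,
                    paste(strsplit(p$sequence, "")[[1]][perm], collapse = ""),
                    p$scores[perm, ])
  s1 <- sigmoid_scale(p); s2 <- sigmoid_scale(q)
  expect_equal(aac_pssm(s1), aac_pssm(s2), tolerance = 1e-12)
  expect_equal(rpssm_ds(reduce_pssm(s1)), rpssm_ds(reduce_pssm(s2)),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dpc_pssm(s1), dpc_pssm(s2))))
  expect_false(isTRUE(all.equal(rpssm_dst(reduce_pssm(s1)),
                                rpssm_dst(reduce_pssm(s2)))))
})

test_that("featurize_batch builds labelled tables and validates IDs", {
  spec <- simulation_spec(n_pos = 3, n_neg = 4, length_range = c(5, 12), seed = 9)
  ds <- gen_dataset(spec)
  ft <- featurize_batch(ds$profiles, ds$labels)
  expect_equal(dim(ft), c(7L, 530L))
  expect_equal(sum(ft$labels), 3L)
  expect_identical(ft$ids, vapply(ds$profiles, `[[`, "", "id"))

  expect_equal(dim(featurize_batch(ds$profiles, ds$labels,
                                   features = "rpssm"))[2], 110L)
  expect_equal(dim(featurize_batch(list())), c(0L, 0L))

  bad <- ds$labels
  names(bad)[1] <- "ghost"
  expect_error(featurize_batch(ds$profiles, bad), "ghost")
})

test_that("feature tables serialize to TSV and back losslessly", {
  ft <- signal_table(n = 12, d = 6, seed = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, f)
  got <- read_feature_table(f)
  expect_identical(got$ids, ft$ids)
  expect_identical(got$labels, ft$labels)
  expect_equal(got$x, ft$x, tolerance = 1e-15)
})
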