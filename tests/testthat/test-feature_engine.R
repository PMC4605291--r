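test_that("derive_window_size applies the nearest-rank 20th-centile rule", {
  expect_equal(derive_window_size(rep(21, 8)), 21L)
  # sorted lengths 5..50: ceil(0.2*10) = 2 -> 10 -> even -> 9
  expect_equal(derive_window_size(seq(5, 50, by = 5)), 9L)
  expect_equal(derive_window_size(c(2, 2, 2)), 5L)  # clamped to >= 5
  expect_error(derive_window_size(numeric(0)), "empty")

  # properties: odd, >= 5, monotone under a single length increase
  set.seed(20)
  for (i in 1:50) {
    lens <- sample(4:80, sample(1:30, 1), replace = TRUE)
    ws <- derive_window_size(lens)
    expect_true(ws >= 5L && ws %% 2L == 1L)
    j <- sample(seq_along(lens), 1)
    lens2 <- lens; lens2[j] <- lens2[j] + sample(1:20, 1)
    expect_gte(derive_window_size(lens2), ws)
  }
})

test_that("window_spec defaults are 55/21/33", {
  expect_equal(window_spec("rna")$ws, 55L)
  expect_equal(window_spec("dna")$ws, 21L)
  expect_equal(window_spec("protein")$ws, 33L)
  expect_error(window_spec("rna", 10), "odd")
})

# independent oracle: enumerate near/remote index sets position by position
contrast_oracle <- function(v, spec) {
  n <- length(v)
  h <- (spec$ws - 1) %/% 2
  nn <- spec$near_count
  if (nn %% 2 == 0) nn <- nn + 1  # centered near block, odd count
  hn <- (nn - 1) %/% 2
  rc <- spec$remote_count_per_side
  vapply(seq_len(n), function(i) {
    w <- max(1, i - h):min(n, i + h)
    near <- max(1, i - hn):min(n, i + hn)
    left <- setdiff(w[seq_len(min(rc, length(w)))], near)
    right <- setdiff(w[length(w) - seq_len(min(rc, length(w))) + 1], near)
    left <- left[left < min(near)]
    right <- right[right > max(near)]
    remote <- c(left, right)
    if (length(remote) == 0) 0 else mean(v[near]) - mean(v[remote])
  }, numeric(1))
}

test_that("contrast_feature matches the index-enumeration oracle", {
  spec <- window_spec("dna", 21L)
  expect_equal(contrast_feature(rep(3.2, 60), spec), rep(0, 60))

  # near block 1, remote blocks 0 at an interior position -> exactly 1
  v <- rep(0, 61)
  sets <- idrbind:::contrast_index_sets(61, 31, spec)
  v[sets$near] <- 1
  expect_equal(contrast_feature(v, spec)[31], 1)

  # linear vector, interior position
  v2 <- seq_len(100)
  expect_equal(contrast_feature(v2, spec), contrast_oracle(v2, spec))

  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:120, 1)
    ws <- sample(c(5L, 9L, 21L, 33L, 55L), 1)
    spec <- window_spec("rna", ws)
    v <- rnorm(n)
    expect_equal(contrast_feature(v, spec), contrast_oracle(v, spec),
                 tolerance = 1e-10)
  }
})

test_that("contrast_feature is translation-equivariant", {
  set.seed(22)
  v <- rnorm(200)
  spec <- window_spec("protein", 33L)
  a <- contrast_feature(v, spec)
  b <- contrast_feature(c(rnorm(10), v, rnorm(10)), spec)
  # interior positions away from both ends match after the shift
  expect_equal(a[34:167], b[44:177], tolerance = 1e-10)
})

test_that("build_features produces one row per residue and sane columns", {
  set.seed(23)
  p <- make_protein(random_seq(50))
  pm <- profile_matrix(p)
  spec <- window_spec("dna", 9L)
  f <- build_features(pm, spec)
  expect_equal(nrow(f), 50L)
  expect_error(build_features(pm, spec, channels = "nope"),
               "unknown channel")

  # constant channel -> all-zero contrast column
  pm$channels$complexity <- rep(0.4, 50)
  f2 <- build_features(pm, spec, channels = "complexity")
  expect_equal(f2[["complexity|contrast"]], rep(0, 50))

  # window_mean of a 0/1 indicator equals the windowed frequency oracle
  ind <- as.numeric(strsplit(p$sequence, "")[[1]] == "A")
  pm$channels$indA <- ind
  pm$kinds["indA"] <- "scale"
  f3 <- build_features(pm, spec, channels = "indA",
                       aggregations = "window_mean")
  want <- vapply(1:50, function(i) mean(ind[max(1, i - 4):min(50, i + 4)]),
                 numeric(1))
  expect_equal(f3[["indA|window_mean"]], want, tolerance = 1e-12)
})

test_that("select_features removes irrelevant and redundant candidates", {
  set.seed(24)
  n <- 800
  labels <- sample(c(TRUE, FALSE), n, TRUE)
  df <- data.frame(protein_id = "p", position = 1:n)
  df$good <- as.numeric(labels)
  df$good_copy <- df$good            # |corr| = 1 with good
  df$noise <- rnorm(n)
  sel <- select_features(df, labels, relevance_min_auc = 0.6,
                         redundancy_max_abs_corr = 0.7)
  expect_equal(sel, "good")          # one copy kept, noise dropped

  expect_warning(
    none <- select_features(df[, c("protein_id", "position", "noise")],
                            labels, relevance_min_auc = 0.6),
    "no feature passes")
  expect_length(none, 0L)

  expect_error(select_features(df, rep(TRUE, n)), "single-class")

  # invariance to column order
  df2 <- df[, c("protein_id", "position", "noise", "good_copy", "good")]
  expect_equal(select_features(df2, labels, relevance_min_auc = 0.6,
                               redundancy_max_abs_corr = 0.7),
               sel)
})

test_that("single-feature relevance equals the pair-counting AUC oracle", {
  set.seed(25)
  for (i in 1:20) {
    n <- 40
    x <- sample(1:8, n, TRUE) + rnorm(n, sd = 0.01)
    y <- runif(n) < plogis(scale(x))
    if (length(unique(y)) < 2) next
    pos <- x[y]; neg <- x[!y]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(idrbind:::rank_auc(x, y), mean(pairs), tolerance = 1e-12)
  }
})
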