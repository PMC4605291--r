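test_that("scale sets normalize to [0,1] and constant scales become 0.5", {
  set <- scale_set()
  expect_gte(length(set$scales), 17L)
  for (v in set$scales) {
    expect_equal(range(v), c(0, 1))
  }
  const <- scale_set(list(C1 = rep(3.7, 20)))
  expect_equal(const$scales$C1, rep(0.5, 20))
  expect_error(scale_set(list(BAD = 1:19)), "20 finite values")
})

test_that("scale_profile is a per-position lookup with X imputation", {
  p <- make_protein("AG")
  toy <- toy_scale_set()
  expect_equal(scale_profile(p, toy, "TOY"), c(0, 1))
  expect_error(scale_profile(p, toy, "NOPE"), "unknown scale_id")

  const <- scale_set(list(C1 = rep(2, 20)))
  expect_equal(scale_profile(make_protein(random_seq(30, seed = 1)),
                             const, "C1"),
               rep(0.5, 30))

  # oracle: naive per-position lookup on a random sequence
  set.seed(5)
  seq <- random_seq(60)
  p2 <- suppressWarnings(make_protein(sub("^.", "X", seq)))
  full <- scale_set()
  got <- scale_profile(p2, full, "KYTJ820101")
  lut <- setNames(full$scales$KYTJ820101, AAs)
  want <- vapply(strsplit(p2$sequence, "")[[1]], function(a)
    if (a == "X") mean(full$scales$KYTJ820101) else lut[[a]], numeric(1))
  expect_equal(got, unname(want))
})

test_that("window_composition handles homopolymers, termini and sums to 1", {
  comp <- window_composition(make_protein("AAAAA"), 3L)
  expect_equal(comp[, "A"], rep(1, 5))
  expect_equal(rowSums(comp), rep(1, 5))

  comp2 <- window_composition(make_protein("AG"), 3L)
  expect_equal(unname(comp2[1, "A"]), 0.5)  # truncated window "AG"
  expect_equal(unname(comp2[1, "G"]), 0.5)

  expect_error(window_composition(make_protein("AAAA"), 4L), "odd")

  set.seed(6)
  for (i in 1:20) {
    p <- make_protein(random_seq(sample(3:50, 1)))
    comp <- window_composition(p, sample(c(3L, 5L, 9L, 15L), 1))
    expect_equal(rowSums(comp), rep(1, length(p)))
  }
})

test_that("complexity_profile matches the windowed-entropy oracle", {
  expect_equal(complexity_profile(make_protein("AAAAAAA"), 5L), rep(0, 7))

  # a window holding all 20 amino acids exactly once -> entropy 1
  p20 <- make_protein(paste(AAs, collapse = ""))
  cx <- complexity_profile(p20, 21L)
  expect_equal(cx[10], 1)  # truncated window covers the full alphabet

  set.seed(7)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    ws <- sample(c(3L, 5L, 9L), 1)
    p <- make_protein(random_seq(n))
    got <- complexity_profile(p, ws)
    chars <- strsplit(p$sequence, "")[[1]]
    h <- (ws - 1) / 2
    want <- vapply(seq_len(n), function(i) {
      win <- chars[max(1, i - h):min(n, i + h)]
      f <- table(win) / length(win)
      -sum(f * log2(f)) / log2(20)
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("bundled disorder channels are smoothed propensities", {
  p <- make_protein(paste(rep("K", 50), collapse = ""))
  ch <- disorder_channels(p)
  expect_named(ch, c("disorder_long", "disorder_short", "disorder_glob"))
  for (v in ch) {
    expect_equal(v, rep(v[1], 50))  # constant input stays constant
    expect_true(all(v >= 0 & v <= 1))
  }

  # moving-average oracle
  set.seed(8)
  p2 <- make_protein(random_seq(80))
  raw <- scale_profile(p2, scale_set(), "TOPIDP0101")
  got <- disorder_channels(p2)
  for (w in c(long = 21L, short = 9L, glob = 41L)) {
    want <- vapply(1:80, function(i)
      mean(raw[max(1, i - (w - 1) / 2):min(80, i + (w - 1) / 2)]), numeric(1))
    nm <- paste0("disorder_", names(which(c(long = 21L, short = 9L,
                                            glob = 41L) == w)))
    expect_equal(got[[nm]], want, tolerance = 1e-12)
  }
})

test_that("file providers round-trip and report coverage gaps", {
  p <- make_protein("MKVAC")
  path <- tempfile()
  rows <- expand.grid(pos = 1:5,
                      ch = c("disorder_long", "disorder_short",
                             "disorder_glob"))
  set.seed(9)
  rows$score <- round(runif(nrow(rows)), 6)
  writeLines(sprintf("p1\t%d\t%s\t%g", rows$pos, rows$ch, rows$score), path)
  got <- disorder_channels(p, provider = paste0("file:", path))
  for (ch in names(got)) {
    expect_equal(got[[ch]], rows$score[rows$ch == ch])
  }
  # drop a position -> error naming the gap
  writeLines(sprintf("p1\t%d\t%s\t%g", rows$pos, rows$ch, rows$score)[-3],
             path)
  expect_error(disorder_channels(p, provider = paste0("file:", path)),
               "missing positions")
  expect_error(disorder_channels(p, provider = "bogus"), "provider")
})

test_that("secondary-structure channels sum to 1 per position", {
  set.seed(10)
  p <- make_protein(random_seq(70))
  ss <- secstruct_channels(p)
  expect_named(ss, c("ss_helix", "ss_strand", "ss_coil"))
  expect_equal(ss$ss_helix + ss$ss_strand + ss$ss_coil, rep(1, 70))
})

test_that("profile_matrix depends only on the sequence and stays finite", {
  set.seed(11)
  seq <- random_seq(40)
  seqX <- sub("^..", "XX", seq)
  pm1 <- profile_matrix(make_protein(seq, id = "a"))
  pm2 <- profile_matrix(make_protein(seq, id = "zzz"))
  expect_identical(pm1$channels, pm2$channels)  # id-invariance
  pmX <- profile_matrix(suppressWarnings(make_protein(seqX)))
  expect_true(all(vapply(pmX$channels,
                         function(v) all(is.finite(v)), logical(1))))
})
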