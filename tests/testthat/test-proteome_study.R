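test_that("overlap_significance matches analytic expectations", {
  proteome <- sprintf("prot%04d", 1:2000)
  half <- proteome[1:1000]
  ref <- list(name = "ref", ids = half)

  # predictions = reference = half the proteome -> ratio ~ 2
  res <- overlap_significance(half, ref, proteome, seed = 5)
  expect_equal(res$ratio, 2, tolerance = 0.3)
  expect_true(res$significant)

  # disjoint predictions -> zero overlap, ratio 0
  res0 <- overlap_significance(proteome[1001:1500], ref, proteome, seed = 5)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$ratio, 0)

  expect_error(overlap_significance(half, list(ids = "absent"), proteome),
               "disjoint")
})

test_that("random predictions overlap the reference at the chance ratio", {
  # The half-subset resampling clusters around the full-set overlap, so its
  # p-values are anticonservative under this null (see the methods
  # vignette); the chance-level *ratio* is the attainable property.
  proteome <- sprintf("prot%04d", 1:1500)
  ref <- list(name = "ref", ids = proteome[1:300])
  set.seed(70)
  ratios <- vapply(1:40, function(s) {
    pred <- sample(proteome, 400)
    overlap_significance(pred, ref, proteome, seed = s)$ratio
  }, numeric(1))
  expect_equal(median(ratios), 1, tolerance = 0.15)
})

test_that("localization enrichment finds planted terms and respects the filter", {
  set.seed(71)
  proteome <- sprintf("prot%04d", 1:1200)
  known <- proteome[1:150]
  novel <- proteome[151:250]
  rest <- proteome[251:1200]
  loc <- rbind(
    data.frame(protein_id = known, term = "nucleus"),
    data.frame(protein_id = sample(known, 80), term = "nucleolus"),
    data.frame(protein_id = novel, term = "nucleus"),
    data.frame(protein_id = rest, term = sample(c("cytoplasm", "membrane"),
                                                length(rest), TRUE)))
  res <- localization_enrichment(novel, known, loc, seed = 5)
  expect_true("nucleus" %in% res$enriched_terms)
  expect_equal(res$overlap_fraction, 1)   # novel annotated only in enriched terms
  expect_true(res$significant)

  # min_frac = 1 filters every term away
  res2 <- localization_enrichment(novel, known, loc, min_frac = 1, seed = 5)
  expect_length(res2$enriched_terms, 0L)
  expect_true(is.na(res2$overlap_fraction))
  expect_error(localization_enrichment(novel, known, loc[0, ]), "empty")
})

test_that("random localization terms do not dominate the enriched set", {
  # Spurious terms do appear under the null (same anticonservative
  # resampling mechanism); the attainable property is that random term
  # assignment never enriches the bulk of the vocabulary.
  proteome <- sprintf("prot%04d", 1:600)
  set.seed(72)
  n_enriched <- vapply(1:20, function(s) {
    loc <- data.frame(protein_id = proteome,
                      term = sample(paste0("t", 1:5), 600, TRUE))
    known <- sample(proteome, 120)
    res <- localization_enrichment(sample(proteome, 50), known, loc, seed = s)
    length(res$enriched_terms)
  }, numeric(1))
  expect_lt(mean(n_enriched), 2.5)   # well under half of the 5 terms
})

test_that("promiscuity correlation: exact, null and oracle cases", {
  ids <- sprintf("p%03d", 1:300)
  set.seed(73)
  k <- setNames(sample(0:5, 300, TRUE), ids)

  # degrees an exact function of k -> PCC 1
  deg <- setNames(10 * k + 0, ids)
  res <- promiscuity_correlation(k, deg, seed = 2)
  expect_equal(res$pcc, 1.0)
  expect_equal(res$per_k$mean_degree, 10 * res$per_k$k)

  # per-k table equals a group-by oracle
  deg2 <- setNames(rpois(300, 5 + 2 * k), ids)
  res2 <- promiscuity_correlation(k, deg2, seed = 2)
  want <- tapply(deg2[ids], k[ids], mean)
  expect_equal(res2$per_k$mean_degree, unname(as.numeric(want)))
  expect_equal(res2$per_k$k, as.integer(names(want)))

  # independent degrees -> PCC near 0 on average
  pccs <- vapply(1:25, function(s) {
    set.seed(200 + s)
    d <- setNames(rpois(300, 8), ids)
    promiscuity_correlation(k, d, seed = s)$pcc
  }, numeric(1))
  expect_equal(mean(pccs), 0, tolerance = 0.25)  # 6-bin PCCs are noisy

  expect_error(promiscuity_correlation(setNames(rep(1L, 5), ids[1:5]),
                                       setNames(1:5, ids[1:5])),
               "distinct")
})

test_that("elm_overlap counts disordered motifs intersecting predictions", {
  dis <- list(a = replace(rep(FALSE, 100), 10:60, TRUE),
              b = rep(FALSE, 100))
  elms <- data.frame(protein_id = c("a", "a", "a", "a", "a", "b"),
                     start = c(12, 20, 30, 40, 50, 5),
                     end = c(15, 24, 33, 44, 55, 9))
  pred <- data.frame(protein_id = "a",
                     start = c(12, 22, 31), end = c(16, 24, 33))
  res <- elm_overlap(pred, elms, dis)
  expect_equal(res$n_in_disorder, 5L)   # the 'b' motif is not in disorder
  expect_equal(res$fraction, 0.6)       # 3 of 5 overlap a prediction

  # every ELM inside predictions -> 1; none in disorder -> NA with count 0
  res1 <- elm_overlap(data.frame(protein_id = "a", start = 1, end = 100),
                      elms[1:5, ], dis)
  expect_equal(res1$fraction, 1)
  res0 <- elm_overlap(pred, elms[6, , drop = FALSE], dis)
  expect_true(is.na(res0$fraction))
  expect_equal(res0$n_in_disorder, 0L)
})

test_that("reference sets read one id per line", {
  path <- tempfile()
  writeLines(c("# comment", "P1", "P2", "", "P1"), path)
  ref <- read_reference_set(path, "demo")
  expect_equal(ref$ids, c("P1", "P2"))
  writeLines("# only comments", path)
  expect_error(read_reference_set(path), "empty")
})
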