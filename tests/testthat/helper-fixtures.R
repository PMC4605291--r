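# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

AAs <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AAs, n, replace = TRUE), collapse = "")
}

make_protein <- function(seq, id = "p1", tracks = NULL) {
  annotated_protein(id, seq, tracks = tracks)
}

write_tmp_fasta <- function(text) {
  path <- tempfile(fileext = ".fasta")
  writeLines(text, path)
  path
}

# Two-value scale set for hand-computable profiles: A = 0, G = 1, rest linear.
toy_scale_set <- function() {
  v <- seq(0, 1, length.out = 20)
  names(v) <- AAs
  v["A"] <- 0; v["G"] <- 1
  scale_set(list(TOY = unname(v[AAs])))
}

# Small trained fixture shared across test files (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    corpus <- simulate_corpus(sim_config(n_proteins = 30, seed = 11,
                                         len_min = 80, len_max = 200))
    fit <- suppressWarnings(idr_train(corpus$proteins))
    .fixture_env$corpus <- corpus
    .fixture_env$fit <- fit
  }
  list(corpus = .fixture_env$corpus, fit = .fixture_env$fit)
}
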