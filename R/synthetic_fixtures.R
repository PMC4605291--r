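#' Seeded synthetic corpora with planted binding signal
#'
#' The generator emulates a curated disorder corpus: proteins alternate
#' ordered and disordered segments, disordered segments use a
#' composition biased toward disorder-promoting residues (P/E/S/K/Q/G
#' enriched, W/C/F/I/Y/V depleted), and binding regions of at least 4
#' residues are planted inside disordered runs. The binding signal is
#' compositional: residues inside binding regions of a function are drawn
#' from an exponentially tilted disordered composition whose mean on a
#' designated amino-acid scale is shifted by `effect_size` standard
#' deviations of that scale. A fixed seed yields a byte-identical corpus.
#'
#' @name synthetic_fixtures
NULL

# Background (ordered) residue frequencies, SwissProt-like, canonical order.
ORDERED_COMPOSITION <- local({
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.72, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.64, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  v <- f[AA_ALPHABET]; v / sum(v)
})

# Disorder-biased composition: enrich disorder-promoting, deplete
# order-promoting residues, renormalize.
DISORDERED_COMPOSITION <- local({
  v <- ORDERED_COMPOSITION
  v[c("P", "E", "S", "K", "Q", "G")] <- v[c("P", "E", "S", "K", "Q", "G")] * 1.8
  v[c("W", "C", "F", "I", "Y", "V")] <- v[c("W", "C", "F", "I", "Y", "V")] * 0.4
  v / sum(v)
})

#' Simulation configuration
#'
#' Defaults describe a desk-scale corpus that mirrors a curated disorder
#' database in shape: 200 proteins of 100-400 residues, ~40% disordered
#' content, and per-function binding prevalences (as fractions of disordered
#' residues) ordered protein > dna > rna as in curated annotations. Region
#' lengths are log-uniform on `[4, max]` with the rna regions longest.
#'
#' @param n_proteins number of base proteins (homolog copies are added on
#'   top).
#' @param len_min,len_max uniform protein length range.
#' @param disorder_content target fraction of disordered residues.
#' @param prevalence named fractions of disordered residues carrying each
#'   binding function.
#' @param region_len_max named per-function maxima of the log-uniform region
#'   length distribution (minimum is always 4).
#' @param effect_size mean shift, in scale standard deviations, planted on
#'   the designated scale inside binding regions.
#' @param signal_scales named scale ids carrying the planted signal.
#' @param homolog_fraction fraction of proteins duplicated with 10% point
#'   mutations (exercises the homology-transfer layer).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200L, len_min = 100L, len_max = 400L,
                       disorder_content = 0.4,
                       prevalence = c(rna = 0.05, dna = 0.10, protein = 0.30),
                       region_len_max = c(rna = 60L, dna = 25L, protein = 40L),
                       effect_size = 1.0,
                       signal_scales = c(rna = "ZIMJ680104",
                                         dna = "KLEP840101",
                                         protein = "KYTJ820101"),
                       homolog_fraction = 0.1, seed = 1L) {
  stopifnot(n_proteins >= 1L, len_min >= 20L, len_max >= len_min,
            disorder_content >= 0, disorder_content <= 1,
            all(prevalence >= 0), all(prevalence <= 1),
            all(region_len_max >= 4L), effect_size >= 0,
            homolog_fraction >= 0, homolog_fraction <= 1)
  stopifnot(all(BINDING_FUNCTIONS %in% names(prevalence)),
            all(BINDING_FUNCTIONS %in% names(region_len_max)),
            all(BINDING_FUNCTIONS %in% names(signal_scales)))
  structure(list(n_proteins = as.integer(n_proteins),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 disorder_content = disorder_content,
                 prevalence = prevalence, region_len_max = region_len_max,
                 effect_size = effect_size, signal_scales = signal_scales,
                 homolog_fraction = homolog_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Solve the exponential-tilt parameter eta so that the tilted mean of scale
# values x under weights w equals mean(x) + effect * sd(x) (population sd
# under w). Monotone in eta; effect = 0 gives eta = 0.
solve_tilt <- function(x, w, effect) {
  if (effect == 0) return(0)
  m0 <- sum(w * x)
  s0 <- sqrt(sum(w * (x - m0)^2))
  target <- m0 + effect * s0
  if (target >= max(x)) {
    stop(sprintf("effect size %.2f not achievable: target mean %.3f >= max %.3f",
                 effect, target, max(x)))
  }
  tilted_mean <- function(eta) {
    wt <- w * exp(eta * (x - max(x)))   # shift for numerical stability
    sum(wt * x) / sum(wt)
  }
  stats::uniroot(function(eta) tilted_mean(eta) - target,
                 lower = 0, upper = 500, tol = 1e-10)$root
}

#' Generate a synthetic annotated corpus
#'
#' @param config a [sim_config()].
#' @param set the [scale_set()] supplying the designated signal scales.
#' @return list with `proteins` (named list of [annotated_protein()]),
#'   `regions` (data.frame of all region records, disorder included) and
#'   `meta` (config, tilt parameters, seed).
#' @export
simulate_corpus <- function(config = sim_config(), set = scale_set()) {
  stopifnot(inherits(config, "sim_config"))
  eta <- stats::setNames(vapply(BINDING_FUNCTIONS, function(f) {
    x <- set$scales[[config$signal_scales[[f]]]]
    solve_tilt(x, unname(DISORDERED_COMPOSITION), config$effect_size)
  }, numeric(1)), BINDING_FUNCTIONS)
  scale_x <- lapply(config$signal_scales, function(id) set$scales[[id]])

  with_local_seed(config$seed, {
    # --- ordered/disordered segmentation and base sequences ---------------
    proteins <- vector("list", config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      L <- sample(config$len_min:config$len_max, 1L)
      disorder <- logical(L)
      pos <- 1L
      while (pos <= L) {
        seg <- sample(12:60, 1L)
        end <- min(pos + seg - 1L, L)
        is_dis <- stats::runif(1) < config$disorder_content
        if (is_dis && end - pos + 1L >= 4L) disorder[pos:end] <- TRUE
        pos <- end + 1L
      }
      chars <- character(L)
      chars[disorder] <- sample(AA_ALPHABET, sum(disorder), replace = TRUE,
                                prob = DISORDERED_COMPOSITION)
      chars[!disorder] <- sample(AA_ALPHABET, sum(!disorder), replace = TRUE,
                                 prob = ORDERED_COMPOSITION)
      proteins[[i]] <- annotated_protein(
        sprintf("sim%04d", i), paste(chars, collapse = ""),
        tracks = list(disorder = disorder))
    }
    names(proteins) <- vapply(proteins, `[[`, character(1), "id")

    # --- corpus-level binding-region placement ----------------------------
    run_tab <- do.call(rbind, lapply(proteins, function(p) {
      runs <- true_runs(p$tracks$disorder)
      if (nrow(runs) == 0L) return(NULL)
      data.frame(protein_id = p$id, start = runs$start, end = runs$end,
                 len = runs$end - runs$start + 1L)
    }))
    total_dis <- sum(vapply(proteins, function(p) sum(p$tracks$disorder),
                            numeric(1)))
    for (f in BINDING_FUNCTIONS) {
      target <- round(config$prevalence[[f]] * total_dis)
      planted <- 0L
      tries <- 0L
      eligible <- run_tab[run_tab$len >= 4L, , drop = FALSE]
      if (nrow(eligible) == 0L && target > 0L) {
        stop("no disordered run of length >= 4 to place regions in")
      }
      while (planted < target && tries < 50L * config$n_proteins) {
        tries <- tries + 1L
        j <- sample.int(nrow(eligible), 1L, prob = eligible$len)
        run <- eligible[j, ]
        maxlen <- min(run$len, config$region_len_max[[f]])
        len <- round(exp(stats::runif(1, log(4), log(maxlen))))
        len <- min(max(len, 4L), maxlen)
        start <- run$start + sample.int(run$len - len + 1L, 1L) - 1L
        p <- proteins[[run$protein_id]]
        before <- sum(p$tracks[[f]])
        p$tracks[[f]][start:(start + len - 1L)] <- TRUE
        proteins[[run$protein_id]] <- p
        planted <- planted + sum(p$tracks[[f]]) - before
      }
      if (planted < target) {
        stop(sprintf("could not place enough %s regions (%d of %d residues)",
                     f, planted, target))
      }
    }

    # --- plant the compositional signal inside binding regions ------------
    if (config$effect_size > 0) {
      for (id in names(proteins)) {
        p <- proteins[[id]]
        cover <- lapply(BINDING_FUNCTIONS, function(f) p$tracks[[f]])
        any_bind <- Reduce(`|`, cover)
        if (!any(any_bind)) next
        chars <- seq_chars(p)
        for (i in which(any_bind)) {
          w <- unname(DISORDERED_COMPOSITION)
          for (fi in seq_along(BINDING_FUNCTIONS)) {
            if (cover[[fi]][i]) {
              w <- w * exp(eta[[fi]] * scale_x[[BINDING_FUNCTIONS[fi]]])
            }
          }
          chars[i] <- sample(AA_ALPHABET, 1L, prob = w / sum(w))
        }
        proteins[[id]] <- annotated_protein(id, paste(chars, collapse = ""),
                                            tracks = p$tracks)
      }
    }

    # --- homolog copies with 10% point mutations --------------------------
    n_hom <- round(config$homolog_fraction * config$n_proteins)
    if (n_hom > 0L) {
      src <- sample(names(proteins), n_hom)
      for (id in src) {
        p <- proteins[[id]]
        chars <- seq_chars(p)
        n <- length(chars)
        mut <- sample.int(n, max(1L, round(0.1 * n)))
        for (i in mut) {
          comp <- if (p$tracks$disorder[i]) DISORDERED_COMPOSITION
                  else ORDERED_COMPOSITION
          chars[i] <- sample(AA_ALPHABET, 1L, prob = comp)
        }
        hid <- paste0(id, "_h1")
        proteins[[hid]] <- annotated_protein(hid, paste(chars, collapse = ""),
                                             tracks = p$tracks)
      }
    }

    regions <- do.call(rbind, lapply(proteins, tracks_to_regions))
    rownames(regions) <- NULL
    list(proteins = proteins, regions = regions,
         meta = list(config = config, tilt = eta, seed = config$seed))
  })
}

#' Summary statistics of a corpus
#'
#' @param corpus a [simulate_corpus()] result (or any list with `proteins`).
#' @return list with `n_proteins`, `n_residues`, `disorder_content`,
#'   `residue_counts` (per function), `region_length_q20` (nearest-rank 20th
#'   centile of region lengths per function, `NA` when absent).
#' @export
corpus_stats <- function(corpus) {
  proteins <- corpus$proteins
  n_res <- sum(vapply(proteins, function(p) nchar(p$sequence), numeric(1)))
  n_dis <- sum(vapply(proteins, function(p) sum(p$tracks$disorder), numeric(1)))
  counts <- stats::setNames(vapply(BINDING_FUNCTIONS, function(f)
    sum(vapply(proteins, function(p) sum(p$tracks[[f]]), numeric(1))),
    numeric(1)), BINDING_FUNCTIONS)
  q20 <- stats::setNames(vapply(BINDING_FUNCTIONS, function(f) {
    lens <- unlist(lapply(proteins, function(p) {
      runs <- true_runs(p$tracks[[f]])
      runs$end - runs$start + 1L
    }))
    if (length(lens) == 0L) NA_real_ else nearest_rank_centile(lens, 0.2)
  }, numeric(1)), BINDING_FUNCTIONS)
  list(n_proteins = length(proteins), n_residues = n_res,
       disorder_content = if (n_res == 0) 0 else n_dis / n_res,
       residue_counts = counts, region_length_q20 = q20)
}

#' Write a corpus to disk
#'
#' Emits `sequences.fasta`, `regions.tsv` and `metadata.tsv` (key-value
#' record of the configuration and seed) into `dir`.
#'
#' @param corpus a [simulate_corpus()] result.
#' @param dir output directory (created if missing).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(corpus$proteins, file.path(dir, "sequences.fasta"))
  write_regions(corpus$regions, file.path(dir, "regions.tsv"))
  cfg <- corpus$meta$config
  kv <- c(n_proteins = cfg$n_proteins, len_min = cfg$len_min,
          len_max = cfg$len_max, disorder_content = cfg$disorder_content,
          stats::setNames(cfg$prevalence,
                          paste0("prevalence_", names(cfg$prevalence))),
          stats::setNames(cfg$region_len_max,
                          paste0("region_len_max_", names(cfg$region_len_max))),
          effect_size = cfg$effect_size,
          stats::setNames(cfg$signal_scales,
                          paste0("signal_scale_", names(cfg$signal_scales))),
          homolog_fraction = cfg$homolog_fraction, seed = cfg$seed)
  writeLines(paste(names(kv), unname(kv), sep = "\t"),
             file.path(dir, "metadata.tsv"))
  invisible(dir)
}
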