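#' Proteome-level validation analyses
#'
#' Protein-level predictions (a protein is a binder iff it has at least one
#' called region of at least 4 residues) are validated against user-supplied
#' reference tables: ID lists of known binders, a protein-to-interaction-degree
#' table, a protein-to-localization table, and linear-motif (ELM-style) region
#' annotations. Each analysis compares the observed statistic with a
#' randomized baseline via the shared Anderson-Darling-gated t/Wilcoxon
#' resampling test.
#'
#' @name proteome_study
NULL

#' Read a reference binder set (one protein id per line)
#'
#' @param path file path; `'#'` comments and blank lines skipped.
#' @param name label for the set.
#' @return list with `name` and `ids` (unique, non-empty character vector).
#' @export
read_reference_set <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  ids <- unique(lines[nzchar(lines) & !startsWith(lines, "#")])
  if (length(ids) == 0L) stop("empty reference set: ", path)
  list(name = name, ids = ids)
}

#' Overlap of predicted binders with a reference set versus random
#'
#' Ten random halves of the predicted binder set are overlapped with the
#' reference; ten equal-sized random draws from the proteome provide the
#' baseline. The ratio of median overlaps and the gated t/Wilcoxon p-value
#' quantify how far predictions exceed chance.
#'
#' @param predicted_ids character vector of predicted binder ids (subset of
#'   `proteome_ids`).
#' @param reference a [read_reference_set()] result (or list with `ids`).
#' @param proteome_ids all protein ids in the proteome.
#' @param n_rep repetitions, default 10.
#' @param frac fraction of predictions per repetition, default 0.5.
#' @param seed RNG seed.
#' @return list with `ratio`, `p_value`, `significant`, `test_used`,
#'   `actual_overlaps`, `random_overlaps`, `overlap` (full-set overlap count).
#' @export
overlap_significance <- function(predicted_ids, reference, proteome_ids,
                                 n_rep = 10L, frac = 0.5, seed = 1L) {
  stopifnot(all(predicted_ids %in% proteome_ids))
  ref <- intersect(reference$ids, proteome_ids)
  if (length(ref) == 0L) stop("reference set disjoint from the proteome")
  k <- max(1L, floor(frac * length(predicted_ids)))
  res <- with_local_seed(seed, {
    actual <- vapply(seq_len(n_rep), function(r)
      length(intersect(sample(predicted_ids, k), ref)), numeric(1))
    random <- vapply(seq_len(n_rep), function(r)
      length(intersect(sample(proteome_ids, k), ref)), numeric(1))
    list(actual = actual, random = random)
  })
  med_rand <- stats::median(res$random)
  ratio <- if (med_rand == 0) {
    if (stats::median(res$actual) == 0) 0 else NA_real_
  } else {
    stats::median(res$actual) / med_rand
  }
  cmp <- gated_two_sample_test(res$actual, res$random)
  list(ratio = ratio, p_value = cmp$p_value, significant = cmp$significant,
       test_used = cmp$test_used, actual_overlaps = res$actual,
       random_overlaps = res$random,
       overlap = length(intersect(predicted_ids, ref)), seed = seed)
}

#' Localization enrichment of novel predicted binders
#'
#' Step 1 finds localization terms significantly enriched among the known
#' binders relative to random proteome draws (terms carrying less than
#' `min_frac` of the known set's annotation count are removed first). Step 2
#' computes the fraction of the novel binders' localization annotations that
#' fall in those enriched terms and compares it with the same fraction for
#' random protein sets.
#'
#' @param novel_ids predicted binders absent from every reference set.
#' @param known_ids known binders.
#' @param localizations data.frame `protein_id`, `term` (one row per
#'   annotation).
#' @param min_frac low-count filter on term frequency, default 0.02.
#' @param n_rep repetitions, default 10.
#' @param seed RNG seed.
#' @return list with `enriched_terms`, `overlap_fraction`, `ratio`,
#'   `p_value`, `significant`, `coverage` (fraction of novel ids annotated).
#' @export
localization_enrichment <- function(novel_ids, known_ids, localizations,
                                    min_frac = 0.02, n_rep = 10L, seed = 1L) {
  stopifnot(is.data.frame(localizations),
            all(c("protein_id", "term") %in% colnames(localizations)))
  if (nrow(localizations) == 0L) stop("empty localization table")
  proteome_ids <- unique(localizations$protein_id)
  ann_of <- function(ids) localizations[localizations$protein_id %in% ids, ]
  known_ann <- ann_of(known_ids)
  counts <- table(known_ann$term)
  terms <- names(counts)[counts >= min_frac * nrow(known_ann)]
  if (length(terms) == 0L) {
    return(list(enriched_terms = character(0), overlap_fraction = NA_real_,
                ratio = NA_real_, p_value = NA_real_, significant = FALSE,
                coverage = mean(novel_ids %in% proteome_ids), note = "no terms pass the low-count filter"))
  }
  frac_with_term <- function(ids, term) {
    with_term <- unique(localizations$protein_id[localizations$term == term])
    mean(ids %in% with_term)
  }
  k <- max(1L, floor(0.5 * length(known_ids)))
  enriched <- with_local_seed(seed, {
    Filter(function(term) {
      actual <- vapply(seq_len(n_rep), function(r)
        frac_with_term(sample(known_ids, k), term), numeric(1))
      random <- vapply(seq_len(n_rep), function(r)
        frac_with_term(sample(proteome_ids, k), term), numeric(1))
      cmp <- gated_two_sample_test(actual, random)
      cmp$significant && stats::median(actual) > stats::median(random)
    }, terms)
  })
  if (length(enriched) == 0L) {
    return(list(enriched_terms = character(0), overlap_fraction = NA_real_,
                ratio = NA_real_, p_value = NA_real_, significant = FALSE,
                coverage = mean(novel_ids %in% proteome_ids),
                note = "no significantly enriched terms"))
  }
  frac_in_enriched <- function(ids) {
    a <- ann_of(ids)
    if (nrow(a) == 0L) return(0)
    mean(a$term %in% enriched)
  }
  kn <- max(1L, floor(0.5 * length(novel_ids)))
  res <- with_local_seed(seed + 1L, {
    actual <- vapply(seq_len(n_rep), function(r)
      frac_in_enriched(sample(novel_ids, kn)), numeric(1))
    random <- vapply(seq_len(n_rep), function(r)
      frac_in_enriched(sample(proteome_ids, kn)), numeric(1))
    list(actual = actual, random = random)
  })
  med_rand <- stats::median(res$random)
  cmp <- gated_two_sample_test(res$actual, res$random)
  list(enriched_terms = enriched,
       overlap_fraction = frac_in_enriched(novel_ids),
       ratio = if (med_rand == 0) NA_real_ else
         stats::median(res$actual) / med_rand,
       p_value = cmp$p_value, significant = cmp$significant,
       test_used = cmp$test_used,
       coverage = mean(novel_ids %in% proteome_ids), seed = seed)
}

#' Promiscuity versus predicted region count
#'
#' Correlates the number of predicted disordered protein-binding regions of a
#' protein (`k`) with the average number of interaction partners of proteins
#' having that `k`. The observed Pearson correlation is compared with a
#' baseline where region counts are permuted over proteins (group sizes per
#' `k` preserved).
#'
#' @param region_counts named integer vector: protein id -> number of
#'   predicted protein-binding regions.
#' @param degrees named numeric vector: protein id -> partner count in the
#'   interaction network.
#' @param n_rep repetitions, default 10.
#' @param seed RNG seed.
#' @return list with `pcc`, `per_k` (data.frame `k`, `mean_degree`,
#'   `n_proteins`), `ratio_to_random`, `p_value`, `significant`,
#'   `actual_pccs`, `random_pccs`.
#' @export
promiscuity_correlation <- function(region_counts, degrees, n_rep = 10L,
                                    seed = 1L) {
  ids <- intersect(names(region_counts), names(degrees))
  if (length(ids) == 0L) stop("no shared protein ids")
  k <- as.integer(region_counts[ids])
  d <- as.numeric(degrees[ids])
  if (length(unique(k)) < 3L) {
    stop("need >= 3 distinct region-count values for a correlation")
  }
  per_k_table <- function(kv, dv) {
    agg <- tapply(dv, kv, mean)
    data.frame(k = as.integer(names(agg)), mean_degree = as.numeric(agg),
               n_proteins = as.integer(table(kv)))
  }
  per_k <- per_k_table(k, d)
  pcc <- pearson_cc(per_k$k, per_k$mean_degree)
  res <- with_local_seed(seed, {
    actual <- vapply(seq_len(n_rep), function(r) {
      pick <- unlist(lapply(split(seq_along(k), k), function(idx)
        if (length(idx) == 1L) idx else sample(idx, max(1L, floor(length(idx) / 2)))))
      t <- per_k_table(k[pick], d[pick])
      if (nrow(t) < 3L) return(NA_real_)
      pearson_cc(t$k, t$mean_degree)
    }, numeric(1))
    random <- vapply(seq_len(n_rep), function(r) {
      t <- per_k_table(sample(k), d)
      pearson_cc(t$k, t$mean_degree)
    }, numeric(1))
    list(actual = actual, random = random)
  })
  actual <- res$actual[!is.na(res$actual)]
  random <- res$random[!is.na(res$random)]
  med_rand <- stats::median(random)
  cmp <- gated_two_sample_test(actual, random)
  list(pcc = pcc, per_k = per_k,
       ratio_to_random = if (med_rand <= 0) NA_real_ else
         stats::median(actual) / med_rand,
       p_value = cmp$p_value, significant = cmp$significant,
       test_used = cmp$test_used,
       actual_pccs = actual, random_pccs = random, seed = seed)
}

#' Overlap of linear motifs with predicted protein-binding regions
#'
#' Among motif regions located in disordered regions (at least one residue in
#' a disordered run), the fraction that overlap at least one predicted
#' disordered protein-binding region by at least one residue.
#'
#' @param predicted_regions data.frame of predicted protein-binding regions
#'   (`protein_id`, `start`, `end`).
#' @param elm_regions data.frame of motif regions (`protein_id`, `start`,
#'   `end`).
#' @param disorder_tracks named list: protein id -> logical disorder vector.
#' @return list with `fraction` (`NA` when no motif lies in disorder),
#'   `n_in_disorder`, `n_overlapping`.
#' @export
elm_overlap <- function(predicted_regions, elm_regions, disorder_tracks) {
  overlaps_any <- function(pid, s, e, regions) {
    sub <- regions[regions$protein_id == pid, , drop = FALSE]
    any(sub$start <= e & sub$end >= s)
  }
  n_dis <- 0L; n_hit <- 0L
  for (i in seq_len(nrow(elm_regions))) {
    r <- elm_regions[i, ]
    dis <- disorder_tracks[[r$protein_id]]
    if (is.null(dis)) next
    s <- max(1L, r$start); e <- min(length(dis), r$end)
    if (s > e || !any(dis[s:e])) next
    n_dis <- n_dis + 1L
    if (overlaps_any(r$protein_id, r$start, r$end, predicted_regions)) {
      n_hit <- n_hit + 1L
    }
  }
  list(fraction = if (n_dis == 0L) NA_real_ else n_hit / n_dis,
       n_in_disorder = n_dis, n_overlapping = n_hit)
}
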