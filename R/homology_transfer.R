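#' Homology-based annotation transfer
#'
#' Binding annotations are copied from the most similar training protein when
#' the alignment E-value falls below a cut-off (default 0.1), and the binary
#' transferred labels are merged with the regression propensities as
#' `(1 + p) / 2` at transferred residues. The builtin search engine performs
#' local alignment (BLOSUM62, affine gaps 11/1) with a Karlin-Altschul-style
#' E-value over the library size; a 12-column tabular format produced by
#' standard local-alignment tools is also accepted.
#'
#' @name homology_transfer
NULL

# Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1.
KA_LAMBDA <- 0.267
KA_K <- 0.041

ka_evalue <- function(score, query_len, library_len) {
  KA_K * query_len * library_len * exp(-KA_LAMBDA * score)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Position map (query_pos, subject_pos) from one pairwiseAlignment.
alignment_position_map <- function(pa) {
  qs <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  spos <- Biostrings::start(Biostrings::subject(pa)) - 1L
  qp <- integer(0); sp <- integer(0)
  for (k in seq_along(qs)) {
    qgap <- qs[k] == "-"
    sgap <- ss[k] == "-"
    if (!qgap) qpos <- qpos + 1L
    if (!sgap) spos <- spos + 1L
    if (!qgap && !sgap) { qp <- c(qp, qpos); sp <- c(sp, spos) }
  }
  data.frame(query_pos = qp, subject_pos = sp)
}

#' Search a library for homologs of a query
#'
#' The builtin engine scores the query against every library sequence by
#' local alignment and converts raw scores to E-values over the total library
#' length. Position maps are computed for hits passing `max_evalue`. Hits are
#' sorted by ascending E-value with ties broken by subject id.
#'
#' @param query an [annotated_protein()].
#' @param library named list of [annotated_protein()] objects (the training
#'   library; a library entry with the query's id is skipped only if
#'   `exclude_self = TRUE`).
#' @param engine `"builtin"`, or `"external-tabular:<path>"` to read hits for
#'   this query from a 12-column tabular alignment file.
#' @param max_evalue hits above this E-value are dropped (default 10).
#' @param exclude_self drop the library entry with the query's own id.
#' @return list of `alignment_hit` objects (fields `query_id`, `subject_id`,
#'   `e_value`, `score`, `position_map`), possibly empty.
#' @export
search_homologs <- function(query, library, engine = "builtin",
                            max_evalue = 10, exclude_self = FALSE) {
  if (startsWith(engine, "external-tabular:")) {
    path <- substring(engine, 18L)
    hits <- read_tabular_hits(path, query_id = query$id)
    return(sort_hits(hits))
  }
  if (!identical(engine, "builtin")) stop("unknown engine: ", engine)
  if (exclude_self) library <- library[names(library) != query$id]
  if (length(library) == 0L) return(list())
  lib_seqs <- Biostrings::AAStringSet(
    vapply(library, function(p) p$sequence, character(1)))
  qseq <- Biostrings::AAString(query$sequence)
  scores <- Biostrings::pairwiseAlignment(
    pattern = lib_seqs, subject = qseq, type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  total_len <- sum(nchar(vapply(library, function(p) p$sequence, character(1))))
  ev <- ka_evalue(scores, nchar(query$sequence), total_len)
  keep <- which(ev <= max_evalue)
  hits <- lapply(keep, function(i) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = qseq, subject = Biostrings::AAString(library[[i]]$sequence),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    structure(list(query_id = query$id,
                   subject_id = library[[i]]$id,
                   e_value = max(ev[i], .Machine$double.xmin),
                   score = scores[i],
                   position_map = alignment_position_map(pa)),
              class = "alignment_hit")
  })
  sort_hits(hits)
}

sort_hits <- function(hits) {
  if (length(hits) == 0L) return(list())
  ev <- vapply(hits, function(h) h$e_value, numeric(1))
  sid <- vapply(hits, function(h) h$subject_id, character(1))
  hits[order(ev, sid)]
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("<alignment_hit> %s -> %s  e=%.3g score=%.1f aligned=%d\n",
              x$query_id, x$subject_id, x$e_value, x$score,
              nrow(x$position_map)))
  invisible(x)
}

#' Read / write 12-column tabular alignment files
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bitscore. Since the tabular
#' format carries no per-position gap structure, the position map is the
#' linear map `qstart+k <-> sstart+k` over the shorter of the two spans.
#'
#' @param path tabular file path.
#' @param query_id optional filter to one query.
#' @return list of `alignment_hit` objects.
#' @export
read_tabular_hits <- function(path, query_id = NULL) {
  if (!file.exists(path)) stop("tabular alignment file not found: ", path)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = cols)
  if (!is.null(query_id)) df <- df[df$query == query_id, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    span <- min(r$qend - r$qstart, r$send - r$sstart)
    structure(list(query_id = as.character(r$query),
                   subject_id = as.character(r$subject),
                   e_value = max(r$evalue, .Machine$double.xmin),
                   score = r$bitscore,
                   position_map = data.frame(
                     query_pos = r$qstart + 0:span,
                     subject_pos = r$sstart + 0:span)),
              class = "alignment_hit")
  })
}

#' @rdname read_tabular_hits
#' @param hits list of `alignment_hit` objects.
#' @export
write_tabular_hits <- function(hits, path) {
  rows <- vapply(hits, function(h) {
    pm <- h$position_map
    paste(h$query_id, h$subject_id, 100, nrow(pm), 0, 0,
          min(pm$query_pos), max(pm$query_pos),
          min(pm$subject_pos), max(pm$subject_pos),
          sprintf("%.3g", h$e_value), sprintf("%.1f", h$score),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Transfer binding annotations from the best hit
#'
#' If the best hit's E-value is below `e_cutoff`, query positions aligned to
#' binding-annotated subject positions are set to 1 for each function;
#' everything else (including the no-hit case) is 0. Only the single most
#' similar sequence is used unless `use_all_hits = TRUE`.
#'
#' @param query an [annotated_protein()].
#' @param hits sorted hit list from [search_homologs()].
#' @param library_tracks named list: subject id -> list of logical binding
#'   tracks (as in `annotated_protein$tracks`).
#' @param e_cutoff transfer threshold; `0` disables the layer entirely.
#' @param use_all_hits merge transfers from every hit under the cut-off
#'   instead of the best one only.
#' @return named list of 0/1 integer vectors (`rna`, `dna`, `protein`) of
#'   query length.
#' @export
transfer_annotations <- function(query, hits, library_tracks, e_cutoff = 0.1,
                                 use_all_hits = FALSE) {
  n <- nchar(query$sequence)
  out <- stats::setNames(lapply(BINDING_FUNCTIONS, function(f) integer(n)),
                         BINDING_FUNCTIONS)
  if (e_cutoff <= 0 || length(hits) == 0L) return(out)
  used <- Filter(function(h) h$e_value < e_cutoff, hits)
  if (length(used) == 0L) return(out)
  if (!use_all_hits) used <- used[1L]
  for (h in used) {
    tracks <- library_tracks[[h$subject_id]]
    if (is.null(tracks)) stop("no library tracks for subject: ", h$subject_id)
    pm <- h$position_map
    for (f in BINDING_FUNCTIONS) {
      hit_pos <- pm$query_pos[tracks[[f]][pm$subject_pos]]
      out[[f]][hit_pos] <- 1L
    }
  }
  out
}

#' Merge regression propensities with transferred annotations
#'
#' `merged[i] = (1 + p[i]) / 2` where the transfer layer annotates residue
#' `i`, and `p[i]` elsewhere. The merge never decreases a propensity and maps
#' `[0, 1]` into `[0, 1]`.
#'
#' @param p numeric propensity vector in `[0, 1]`.
#' @param transferred 0/1 vector of the same length.
#' @return numeric vector of merged propensities.
#' @export
merge_propensity <- function(p, transferred) {
  if (length(p) != length(transferred)) {
    stop("merge_propensity: length mismatch")
  }
  ifelse(transferred == 1L, (1 + p) / 2, p)
}

#' Calibrate the transfer E-value cut-off
#'
#' Leave-one-out over an annotated corpus: each protein is queried against
#' the rest, annotations are transferred at every candidate cut-off, and the
#' cut-off maximizing the mean (over functions with positives) ratio between
#' TP-rate and FP-rate of the binary transfer is returned. Mirrors the
#' cross-validated selection that motivates the 0.1 default.
#'
#' @param proteins named list of annotated proteins with binding tracks.
#' @param cutoffs candidate E-value cut-offs.
#' @return list with `best_cutoff` and the per-cutoff `ratio` table.
#' @export
calibrate_e_cutoff <- function(proteins,
                               cutoffs = c(1e-4, 1e-3, 1e-2, 0.1, 1, 10)) {
  tracks <- lapply(proteins, `[[`, "tracks")
  hit_sets <- lapply(proteins, function(q)
    search_homologs(q, proteins, exclude_self = TRUE))
  ratios <- vapply(cutoffs, function(ct) {
    tp <- fp <- pos <- neg <- stats::setNames(numeric(3), BINDING_FUNCTIONS)
    for (i in seq_along(proteins)) {
      tr <- transfer_annotations(proteins[[i]], hit_sets[[i]], tracks,
                                 e_cutoff = ct)
      for (f in BINDING_FUNCTIONS) {
        lab <- proteins[[i]]$tracks[[f]]
        tp[f] <- tp[f] + sum(tr[[f]] == 1L & lab)
        fp[f] <- fp[f] + sum(tr[[f]] == 1L & !lab)
        pos[f] <- pos[f] + sum(lab)
        neg[f] <- neg[f] + sum(!lab)
      }
    }
    ok <- pos > 0
    tpr <- tp[ok] / pos[ok]
    fpr <- fp[ok] / neg[ok]
    mean(ifelse(fpr == 0, ifelse(tpr > 0, Inf, 0), tpr / fpr))
  }, numeric(1))
  best <- which(ratios == max(ratios))
  list(best_cutoff = min(cutoffs[best]),
       ratio = data.frame(cutoff = cutoffs, ratio = ratios))
}
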