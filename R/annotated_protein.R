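#' Annotated protein sequences
#'
#' An `annotated_protein` bundles a protein sequence (20 canonical amino-acid
#' letters plus `'X'` for anything else) with per-residue logical tracks for
#' intrinsic disorder and for the three disorder-mediated binding functions
#' (`rna`, `dna`, `protein`). Tracks always have the same length as the
#' sequence; empty tracks are all-`FALSE`.
#'
#' @param id single non-empty string, unique within a corpus.
#' @param sequence string over `ACDEFGHIKLMNPQRSTVWYX`.
#' @param tracks optional named list of logical vectors
#'   (`disorder`, `rna`, `dna`, `protein`), each of sequence length.
#' @return an object of class `annotated_protein`.
#' @export
annotated_protein <- function(id, sequence, tracks = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  bad <- !(chars %in% c(AA_ALPHABET, "X"))
  if (any(bad)) {
    warning(sprintf("protein '%s': %d residue(s) outside the 21-letter alphabet mapped to 'X'",
                    id, sum(bad)))
    chars[bad] <- "X"
    sequence <- paste(chars, collapse = "")
  }
  n <- nchar(sequence)
  full <- stats::setNames(
    lapply(TRACK_NAMES, function(t) rep(FALSE, n)), TRACK_NAMES)
  if (!is.null(tracks)) {
    for (t in names(tracks)) {
      if (!t %in% TRACK_NAMES) stop("unknown track: ", t)
      v <- as.logical(tracks[[t]])
      if (length(v) != n || anyNA(v)) {
        stop(sprintf("protein '%s': track '%s' must be a logical vector of length %d",
                     id, t, n))
      }
      full[[t]] <- v
    }
  }
  structure(list(id = id, sequence = sequence, tracks = full),
            class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("<annotated_protein> %s (%d aa)\n", x$id, nchar(x$sequence)))
  for (t in TRACK_NAMES) {
    cat(sprintf("  %-8s %d annotated residue(s)\n", t, sum(x$tracks[[t]])))
  }
  invisible(x)
}

#' @export
length.annotated_protein <- function(x) nchar(x$sequence)

seq_chars <- function(protein) strsplit(protein$sequence, "")[[1]]

#' Read a FASTA file into annotated proteins
#'
#' Sequences are uppercased and characters outside the 21-letter alphabet are
#' mapped to `'X'` with a warning. The record id is the first whitespace-
#' delimited token of the header. All tracks start empty (all `FALSE`).
#'
#' @param path path to a FASTA file.
#' @return list of [annotated_protein()] objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  proteins <- lapply(seq_along(set), function(i) {
    annotated_protein(ids[i], as.character(set[[i]]))
  })
  stats::setNames(proteins, ids)
}

#' Write annotated proteins to FASTA
#'
#' @param proteins list of [annotated_protein()] objects.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in proteins) {
    writeLines(paste0(">", p$id), con)
    s <- p$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read region annotations
#'
#' Annotation files are 4-column TSV (`protein_id`, `function`, `start`,
#' `end`), 1-based inclusive coordinates, `'#'` comments allowed. This is the
#' on-disk carrier for curated disordered-region and binding-region
#' annotations.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `protein_id`, `function.`, `start`, `end`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("region file needs >= 4 columns: ", path)
  df <- df[, 1:4]   # extra columns (e.g. mean_propensity) are ignored
  names(df) <- c("protein_id", "function.", "start", "end")
  df$protein_id <- as.character(df$protein_id)
  df$function. <- as.character(df$function.)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- !(df$function. %in% TRACK_NAMES)
  if (any(bad)) {
    stop("unknown function label(s) in ", path, ": ",
         paste(unique(df$function.[bad]), collapse = ", "))
  }
  if (any(df$start < 1L | df$end < df$start)) {
    stop("invalid region coordinates in ", path)
  }
  df
}

#' Write region annotations
#'
#' @param regions data.frame as returned by [read_regions()] (extra columns
#'   such as `mean_propensity` are written too).
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fill per-residue tracks from region records
#'
#' Residue `i` becomes `TRUE` for a function iff some record of that function
#' covers it; overlapping records of the same function are unioned.
#'
#' @param regions data.frame with columns `protein_id`, `function.`, `start`,
#'   `end` (1-based inclusive).
#' @param proteins named list of [annotated_protein()] objects.
#' @return the protein list with tracks filled.
#' @export
regions_to_tracks <- function(regions, proteins) {
  stopifnot(is.data.frame(regions))
  missing_ids <- setdiff(unique(regions$protein_id), names(proteins))
  if (length(missing_ids) > 0L) {
    stop("region records reference unknown protein id(s): ",
         paste(missing_ids, collapse = ", "))
  }
  for (k in seq_len(nrow(regions))) {
    rec <- regions[k, ]
    p <- proteins[[rec$protein_id]]
    n <- nchar(p$sequence)
    if (rec$start < 1L || rec$end > n || rec$start > rec$end) {
      stop(sprintf("out-of-range region for protein '%s': %s %d-%d (length %d)",
                   rec$protein_id, rec$function., rec$start, rec$end, n))
    }
    p$tracks[[rec$function.]][rec$start:rec$end] <- TRUE
    proteins[[rec$protein_id]] <- p
  }
  proteins
}

#' Convert per-residue tracks back to region records
#'
#' Emits maximal `TRUE` runs per track, 1-based inclusive. Round-trips with
#' [regions_to_tracks()].
#'
#' @param protein an [annotated_protein()].
#' @return data.frame with columns `protein_id`, `function.`, `start`, `end`.
#' @export
tracks_to_regions <- function(protein) {
  out <- lapply(TRACK_NAMES, function(t) {
    runs <- true_runs(protein$tracks[[t]])
    if (nrow(runs) == 0L) return(NULL)
    data.frame(protein_id = protein$id, function. = t,
               start = runs$start, end = runs$end)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), function. = character(0),
                      start = integer(0), end = integer(0))
  }
  out
}

#' Export per-residue labels as TSV
#'
#' One row per residue: `protein_id`, `position`, `residue`, then 0/1 columns
#' `disorder`, `rna`, `dna`, `protein`.
#'
#' @param proteins list of [annotated_protein()] objects.
#' @param path output path.
#' @export
write_label_tsv <- function(proteins, path) {
  rows <- lapply(proteins, function(p) {
    n <- nchar(p$sequence)
    cbind(data.frame(protein_id = p$id, position = seq_len(n),
                     residue = seq_chars(p)),
          as.data.frame(lapply(p$tracks[TRACK_NAMES], as.integer)))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check the training-corpus invariants of one protein
#'
#' Disordered runs used for training must span at least `min_idr_len`
#' residues and every binding-annotated residue must lie inside a disordered
#' run.
#'
#' @param protein an [annotated_protein()] with tracks filled.
#' @param min_idr_len minimum disordered-run length, default 4.
#' @return `TRUE` invisibly; errors when an invariant is violated.
#' @export
validate_training_protein <- function(protein, min_idr_len = 4L) {
  runs <- true_runs(protein$tracks$disorder)
  if (nrow(runs) > 0L && any(runs$end - runs$start + 1L < min_idr_len)) {
    stop(sprintf("protein '%s': disordered run shorter than %d residues",
                 protein$id, min_idr_len))
  }
  for (f in BINDING_FUNCTIONS) {
    if (any(protein$tracks[[f]] & !protein$tracks$disorder)) {
      stop(sprintf("protein '%s': %s-binding residue outside disordered region",
                   protein$id, f))
    }
  }
  invisible(TRUE)
}
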