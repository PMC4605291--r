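#' Per-residue profile channels
#'
#' The first stage of the predictor represents a protein as a set of
#' real-valued per-residue channels: normalized amino-acid scale profiles,
#' windowed amino-acid composition, windowed Shannon complexity, and putative
#' disorder and secondary-structure scores from pluggable providers. All
#' channels are full-length, finite, and (for disorder/secondary structure)
#' bounded in `[0, 1]`.
#'
#' @name profile_channels
NULL

#' Scale profile of a protein
#'
#' Position `i` carries the normalized scale value of residue `i`; `'X'` is
#' imputed with the mean of the 20 canonical values (0.5 for the bundled,
#' min-max normalized scales).
#'
#' @param protein an [annotated_protein()].
#' @param set a [scale_set()].
#' @param scale_id id of a scale in `set`.
#' @return numeric vector of protein length.
#' @export
scale_profile <- function(protein, set, scale_id) {
  if (!scale_id %in% names(set$scales)) stop("unknown scale_id: ", scale_id)
  v <- set$scales[[scale_id]]
  lut <- stats::setNames(c(v, set$x_value[[scale_id]]), c(AA_ALPHABET, "X"))
  unname(lut[seq_chars(protein)])
}

# 0/1 indicator matrix (n x 20) of the canonical residues; 'X' rows all zero.
aa_indicator_matrix <- function(protein) {
  chars <- seq_chars(protein)
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Windowed amino-acid composition
#'
#' For each canonical amino acid, the frequency of that residue in the window
#' of size `ws` centered at each position. Windows are truncated at the
#' termini (the window shrinks on one side), and the denominator is the
#' truncated window width, so the 20 frequencies sum to 1 at positions whose
#' window contains no `'X'`.
#'
#' @param protein an [annotated_protein()].
#' @param ws odd window size >= 3.
#' @return numeric matrix, protein length x 20, columns named by amino acid.
#' @export
window_composition <- function(protein, ws) {
  check_odd_ws(ws, min = 3L)
  m <- aa_indicator_matrix(protein)
  n <- nrow(m)
  h <- (ws - 1L) %/% 2L
  i <- seq_len(n)
  width <- pmin(n, i + h) - pmax(1L, i - h) + 1L
  counts <- apply(m, 2L, roll_sum_trunc, ws = ws)
  if (n == 1L) counts <- matrix(counts, nrow = 1L, dimnames = list(NULL, AA_ALPHABET))
  sweep(counts, 1L, width, "/")
}

#' Windowed sequence complexity
#'
#' Shannon entropy (bits) of the amino-acid composition in the truncated
#' window of size `ws` centered at each position, rescaled by `log2(20)` to
#' `[0, 1]`. `'X'` residues are excluded from the counts; an all-`'X'` window
#' has complexity 0.
#'
#' @inheritParams window_composition
#' @return numeric vector of protein length.
#' @export
complexity_profile <- function(protein, ws) {
  check_odd_ws(ws, min = 3L)
  m <- aa_indicator_matrix(protein)
  counts <- apply(m, 2L, roll_sum_trunc, ws = ws)
  if (nrow(m) == 1L) counts <- matrix(counts, nrow = 1L)
  tot <- rowSums(counts)
  f <- sweep(counts, 1L, pmax(tot, 1), "/")
  h <- -rowSums(ifelse(f > 0, f * log2(f), 0))
  unname(h / log2(20))
}

# Parse a provider spec: "bundled" or "file:<path>".
parse_provider <- function(provider) {
  stopifnot(is.character(provider), length(provider) == 1L)
  if (provider == "bundled") return(list(kind = "bundled"))
  if (startsWith(provider, "file:")) {
    return(list(kind = "file", path = substring(provider, 6L)))
  }
  stop("provider must be \"bundled\" or \"file:<path>\", got: ", provider)
}

# Read the external score TSV (protein_id, position, channel, score) and
# return the requested channels for one protein, checking coverage.
read_score_channels <- function(path, protein, channels) {
  if (!file.exists(path)) stop("score file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("protein_id", "position", "channel", "score"),
                          colClasses = c("character", "integer", "character", "numeric"))
  n <- nchar(protein$sequence)
  out <- lapply(channels, function(ch) {
    sub <- df[df$protein_id == protein$id & df$channel == ch, ]
    v <- rep(NA_real_, n)
    v[sub$position] <- sub$score
    gaps <- which(is.na(v))
    if (length(gaps) > 0L) {
      stop(sprintf("score file '%s': protein '%s' channel '%s' missing positions %s",
                   path, protein$id, ch,
                   paste(utils::head(gaps, 10L), collapse = ",")))
    }
    if (any(v < 0 | v > 1)) stop("scores must lie in [0, 1]")
    v
  })
  stats::setNames(out, channels)
}

#' Putative disorder channels
#'
#' Three `[0, 1]` vectors per protein: long-, short- and globular-flavoured
#' disorder scores. The bundled provider smooths the normalized TOP-IDP
#' disorder-propensity profile over windows of 21 (long), 9 (short) and 41
#' (globular surrogate) residues; it is a fast stand-in, not a re-implementation
#' of any published disorder predictor. A file provider
#' (`"file:<path>"`) reads externally computed scores from a 4-column TSV
#' (`protein_id`, `position`, `channel`, `score`) with channels
#' `disorder_long`, `disorder_short`, `disorder_glob`.
#'
#' @param protein an [annotated_protein()].
#' @param provider `"bundled"` or `"file:<path>"`.
#' @param set scale set supplying the disorder-propensity scale (bundled
#'   provider only).
#' @param windows smoothing windows for the long/short/globular channels.
#' @return named list of three numeric vectors.
#' @export
disorder_channels <- function(protein, provider = "bundled",
                              set = scale_set(),
                              windows = c(long = 21L, short = 9L, glob = 41L)) {
  spec <- parse_provider(provider)
  chans <- c("disorder_long", "disorder_short", "disorder_glob")
  if (spec$kind == "file") {
    return(read_score_channels(spec$path, protein, chans))
  }
  raw <- scale_profile(protein, set, "TOPIDP0101")
  out <- lapply(windows, function(w) roll_mean_trunc(raw, w))
  stats::setNames(out, chans)
}

#' Putative secondary-structure channels
#'
#' Three `[0, 1]` vectors (helix, strand, coil) summing to 1 at every
#' position. The bundled provider smooths normalized Chou-Fasman helix,
#' sheet and turn propensity profiles over a window of `ws` residues and
#' renormalizes per position. A file provider reads channels `ss_helix`,
#' `ss_strand`, `ss_coil` from the 4-column score TSV (renormalized the same
#' way).
#'
#' @inheritParams disorder_channels
#' @param ws smoothing window (bundled provider).
#' @return named list of three numeric vectors.
#' @export
secstruct_channels <- function(protein, provider = "bundled",
                               set = scale_set(), ws = 7L) {
  spec <- parse_provider(provider)
  chans <- c("ss_helix", "ss_strand", "ss_coil")
  if (spec$kind == "file") {
    vals <- read_score_channels(spec$path, protein, chans)
  } else {
    ids <- c("CHOP780201", "CHOP780202", "CHOP780203")
    vals <- lapply(ids, function(id)
      roll_mean_trunc(scale_profile(protein, set, id), ws))
    names(vals) <- chans
  }
  tot <- vals[[1]] + vals[[2]] + vals[[3]]
  tot[tot == 0] <- 1
  lapply(vals, function(v) v / tot)
}

#' Assemble the full profile matrix of a protein
#'
#' Computes every channel the feature stage consumes: one channel per scale in
#' `set`, 20 windowed-composition channels (`comp_A` ... `comp_Y`), a
#' `complexity` channel, three disorder and three secondary-structure
#' channels.
#'
#' @param protein an [annotated_protein()].
#' @param set a [scale_set()].
#' @param comp_ws window for composition and complexity (odd, >= 3).
#' @param disorder_provider,secstruct_provider provider specs (see
#'   [disorder_channels()]).
#' @return object of class `profile_matrix`: list with `protein_id`,
#'   `channels` (named list of full-length numeric vectors) and `kinds`.
#' @export
profile_matrix <- function(protein, set = scale_set(), comp_ws = 15L,
                           disorder_provider = "bundled",
                           secstruct_provider = "bundled") {
  ch <- list()
  kinds <- character(0)
  for (id in names(set$scales)) {
    ch[[id]] <- scale_profile(protein, set, id)
    kinds[id] <- "scale"
  }
  comp <- window_composition(protein, comp_ws)
  for (aa in AA_ALPHABET) {
    ch[[paste0("comp_", aa)]] <- unname(comp[, aa])
    kinds[paste0("comp_", aa)] <- "composition"
  }
  ch$complexity <- complexity_profile(protein, comp_ws)
  kinds["complexity"] <- "complexity"
  dis <- disorder_channels(protein, disorder_provider, set)
  for (nm in names(dis)) { ch[[nm]] <- dis[[nm]]; kinds[nm] <- "disorder" }
  ss <- secstruct_channels(protein, secstruct_provider, set)
  for (nm in names(ss)) { ch[[nm]] <- ss[[nm]]; kinds[nm] <- "secstruct" }
  stopifnot(all(vapply(ch, function(v) all(is.finite(v)), logical(1))))
  structure(list(protein_id = protein$id, channels = ch, kinds = kinds),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s: %d channels x %d residues\n",
              x$protein_id, length(x$channels),
              length(x$channels[[1]])))
  invisible(x)
}
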