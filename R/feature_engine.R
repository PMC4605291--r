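#' Window geometry for the contrast features
#'
#' Each binding function uses a sliding window of odd size `ws`. The near
#' block is the `(ws-1)/2` residues in the middle of the window (rounded up to
#' the nearest odd count so the block stays centered on the predicted
#' residue), and the remote blocks are `floor((ws-1)/4)` residues at each end
#' of the window. Defaults are `ws = 55` (rna), `21` (dna), `33` (protein).
#'
#' @param fun one of `"rna"`, `"dna"`, `"protein"`.
#' @param ws odd window size >= 5; `NULL` selects the per-function default.
#' @return object of class `window_spec` with fields `fun`, `ws`,
#'   `near_count`, `remote_count_per_side`.
#' @export
window_spec <- function(fun = c("rna", "dna", "protein"), ws = NULL) {
  fun <- match.arg(fun)
  defaults <- c(rna = 55L, dna = 21L, protein = 33L)
  if (is.null(ws)) ws <- defaults[[fun]]
  ws <- check_odd_ws(ws, min = 5L)
  structure(list(fun = fun, ws = ws,
                 near_count = (ws - 1L) %/% 2L,
                 remote_count_per_side = (ws - 1L) %/% 4L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s: ws=%d near=%d remote=%d/side\n",
              x$fun, x$ws, x$near_count, x$remote_count_per_side))
  invisible(x)
}

#' Derive a window size from training region lengths
#'
#' The window size is the nearest-rank 20th centile of the lengths of the
#' binding regions of a function (value at index `ceiling(0.2 * n)` of the
#' ascending sort), decremented by one if even, clamped to >= 5.
#'
#' @param region_lengths positive integer vector of region lengths.
#' @param centile quantile level, default 0.2.
#' @return odd integer >= 5.
#' @export
derive_window_size <- function(region_lengths, centile = 0.2) {
  if (length(region_lengths) == 0L) stop("derive_window_size: empty length list")
  stopifnot(all(region_lengths > 0))
  ws <- as.integer(nearest_rank_centile(region_lengths, centile))
  if (ws %% 2L == 0L) ws <- ws - 1L
  max(ws, 5L)
}

# Near/remote index sets at one position, mirroring contrast geometry exactly;
# shared by the vectorized implementation and readable on its own.
contrast_index_sets <- function(n, pos, spec) {
  h <- (spec$ws - 1L) %/% 2L
  w_lo <- max(1L, pos - h); w_hi <- min(n, pos + h)
  nn <- spec$near_count
  if (nn %% 2L == 0L) nn <- nn + 1L          # keep the near block centered
  hn <- (nn - 1L) %/% 2L
  n_lo <- max(1L, pos - hn); n_hi <- min(n, pos + hn)
  rc <- spec$remote_count_per_side
  left <- if (w_lo <= n_lo - 1L) w_lo:min(w_lo + rc - 1L, n_lo - 1L) else integer(0)
  right <- if (w_hi >= n_hi + 1L) max(w_hi - rc + 1L, n_hi + 1L):w_hi else integer(0)
  list(near = n_lo:n_hi, remote = c(left, right))
}

#' Near-versus-remote contrast feature
#'
#' Mean of a channel over the near block centered at each position minus the
#' mean over the pooled remote residues at the two ends of the window.
#' Windows truncate at the termini; when truncation empties one remote side,
#' only the surviving side is pooled, and the value is 0 when the remote pool
#' is empty.
#'
#' @param values numeric vector (one channel of one protein).
#' @param spec a [window_spec()].
#' @param positions positions to evaluate (default: all).
#' @return numeric vector, one value per position.
#' @export
contrast_feature <- function(values, spec, positions = seq_along(values)) {
  n <- length(values)
  cs0 <- c(0, cumsum(values))
  sum_rng <- function(lo, hi) {
    # sum over [lo, hi] with empty ranges (hi < lo) giving 0
    bad <- hi < lo
    hi2 <- pmax(pmin(hi, n), 1L)
    lo2 <- pmax(pmin(lo, n), 1L)
    s <- cs0[hi2 + 1L] - cs0[lo2]
    s[bad] <- 0
    s
  }
  h <- (spec$ws - 1L) %/% 2L
  nn <- spec$near_count
  if (nn %% 2L == 0L) nn <- nn + 1L
  hn <- (nn - 1L) %/% 2L
  rc <- spec$remote_count_per_side
  pos <- as.integer(positions)
  w_lo <- pmax(1L, pos - h); w_hi <- pmin(n, pos + h)
  n_lo <- pmax(1L, pos - hn); n_hi <- pmin(n, pos + hn)
  near_mean <- sum_rng(n_lo, n_hi) / (n_hi - n_lo + 1L)
  l_lo <- w_lo; l_hi <- pmin(w_lo + rc - 1L, n_lo - 1L)
  r_hi <- w_hi; r_lo <- pmax(w_hi - rc + 1L, n_hi + 1L)
  rem_sum <- sum_rng(l_lo, l_hi) + sum_rng(r_lo, r_hi)
  rem_n <- pmax(l_hi - l_lo + 1L, 0L) + pmax(r_hi - r_lo + 1L, 0L)
  out <- ifelse(rem_n > 0L, near_mean - rem_sum / pmax(rem_n, 1L), 0)
  as.numeric(out)
}

#' Build the per-residue feature matrix of one protein
#'
#' One column per `(channel, aggregation)` pair, aggregations being
#' `contrast` (near-minus-remote, see [contrast_feature()]) and `window_mean`
#' (truncated moving average over the full window). Feature ids are
#' `"<channel>|<aggregation>"`. Every residue contributes a row.
#'
#' @param profiles a [profile_matrix()].
#' @param spec a [window_spec()].
#' @param channels channel ids to use (default: all channels in `profiles`).
#' @param aggregations subset of `c("contrast", "window_mean")`.
#' @return data.frame with `protein_id`, `position`, `residue` and one numeric
#'   column per feature.
#' @export
build_features <- function(profiles, spec,
                           channels = names(profiles$channels),
                           aggregations = c("contrast", "window_mean")) {
  aggregations <- match.arg(aggregations, several.ok = TRUE)
  unknown <- setdiff(channels, names(profiles$channels))
  if (length(unknown) > 0L) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(profiles$channels[[1]])
  out <- list()
  for (ch in channels) {
    v <- profiles$channels[[ch]]
    if ("contrast" %in% aggregations) {
      out[[paste0(ch, "|contrast")]] <- contrast_feature(v, spec)
    }
    if ("window_mean" %in% aggregations) {
      out[[paste0(ch, "|window_mean")]] <- roll_mean_trunc(v, spec$ws)
    }
  }
  cbind(data.frame(protein_id = profiles$protein_id, position = seq_len(n),
                   stringsAsFactors = FALSE),
        as.data.frame(out, check.names = FALSE, optional = TRUE))
}

# Columns of a feature data.frame that are features (not bookkeeping).
feature_columns <- function(df) {
  setdiff(colnames(df), c("protein_id", "position", "residue", "label"))
}

# Fast Mann-Whitney AUC via ranks (ties get half credit).
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("rank_auc: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-stage relevance/redundancy feature selection
#'
#' Stage 1 (relevance) keeps features whose single-feature discriminative
#' power, `max(AUC, 1 - AUC)`, reaches `relevance_min_auc`. Stage 2
#' (redundancy) scans the survivors by descending relevance (ties broken by
#' feature id) and greedily drops any feature whose absolute Pearson
#' correlation with an already-kept feature exceeds
#' `redundancy_max_abs_corr`.
#'
#' @param features data.frame of candidate feature columns (see
#'   [build_features()]).
#' @param labels logical vector, one per row; both classes must be present.
#' @param relevance_min_auc relevance threshold, default 0.55.
#' @param redundancy_max_abs_corr redundancy threshold, default 0.7.
#' @return character vector of kept feature ids, in selection order; empty
#'   (with a warning) when nothing passes relevance.
#' @export
select_features <- function(features, labels, relevance_min_auc = 0.55,
                            redundancy_max_abs_corr = 0.7) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("select_features: labels are single-class")
  ids <- feature_columns(features)
  stopifnot(nrow(features) == length(labels))
  rel <- vapply(ids, function(id) {
    a <- rank_auc(features[[id]], labels)
    max(a, 1 - a)
  }, numeric(1))
  keep <- ids[rel >= relevance_min_auc]
  if (length(keep) == 0L) {
    warning("no feature passes the relevance threshold")
    return(character(0))
  }
  keep <- keep[order(-rel[keep], keep)]
  selected <- character(0)
  sel_mat <- NULL
  for (id in keep) {
    v <- features[[id]]
    if (length(selected) > 0L) {
      cors <- abs(suppressWarnings(stats::cor(v, sel_mat)))
      cors[is.na(cors)] <- 0
      if (any(cors > redundancy_max_abs_corr)) next
    }
    selected <- c(selected, id)
    sel_mat <- cbind(sel_mat, v)
  }
  selected
}
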