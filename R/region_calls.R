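#' Calling binding regions from propensities
#'
#' Propensities are binarized at a cut-off (default 0.5, ties count as
#' positive) and maximal positive runs of at least `min_len` residues
#' (default 4, the conventional minimum length of an intrinsically disordered
#' region) become binding regions. A protein is a binder for a function iff
#' it has at least one such region.
#'
#' @name region_calls
NULL

#' Binarize a propensity vector
#'
#' @param p numeric vector in `[0, 1]`.
#' @param cutoff threshold in `[0, 1]`; residues with `p >= cutoff` are
#'   positive.
#' @return logical vector.
#' @export
binarize <- function(p, cutoff = 0.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 || cutoff > 1) {
    stop("cutoff must lie in [0, 1]")
  }
  stopifnot(all(p >= 0 & p <= 1))
  p >= cutoff
}

#' Call binding regions from a binary vector
#'
#' @param b logical vector (see [binarize()]).
#' @param min_len minimum region length, default 4.
#' @param protein_id,fun identifiers stamped on the output rows.
#' @param p optional propensity vector used to annotate each region with its
#'   mean propensity.
#' @return data.frame with columns `protein_id`, `function.`, `start`, `end`,
#'   `mean_propensity`, in position order.
#' @export
call_regions <- function(b, min_len = 4L, protein_id = NA_character_,
                         fun = NA_character_, p = NULL) {
  stopifnot(min_len >= 1L)
  runs <- true_runs(as.logical(b))
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  mp <- if (is.null(p)) rep(NA_real_, nrow(runs)) else
    vapply(seq_len(nrow(runs)),
           function(i) mean(p[runs$start[i]:runs$end[i]]), numeric(1))
  data.frame(protein_id = rep(protein_id, nrow(runs)),
             function. = rep(fun, nrow(runs)),
             start = runs$start, end = runs$end,
             mean_propensity = mp)
}

#' Protein-level binder call
#'
#' @param regions data.frame of called regions of one protein (any subset of
#'   functions).
#' @return named logical vector over `rna`, `dna`, `protein`: `TRUE` iff at
#'   least one region of that function exists.
#' @export
protein_level_call <- function(regions) {
  vapply(BINDING_FUNCTIONS,
         function(f) any(regions$function. == f),
         logical(1))
}
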