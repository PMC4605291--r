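# Internal helpers shared across modules.

# Canonical amino-acid order used by every scale table and composition channel.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

BINDING_FUNCTIONS <- c("rna", "dna", "protein")
TRACK_NAMES <- c("disorder", BINDING_FUNCTIONS)

#' Nearest-rank centile
#'
#' Value at position `ceiling(q * n)` of the ascending sort of `x`.
#'
#' @param x numeric vector, non-empty.
#' @param q quantile level in (0, 1].
#' @return a single element of `x`.
#' @export
nearest_rank_centile <- function(x, q) {
  if (length(x) == 0L) stop("nearest_rank_centile: empty input")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1) {
    stop("nearest_rank_centile: q must be in (0, 1]")
  }
  sort(x)[ceiling(q * length(x))]
}

# Maximal TRUE runs of a logical vector as a data.frame(start, end), 1-based.
true_runs <- function(b) {
  stopifnot(is.logical(b))
  if (length(b) == 0L || !any(b)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- rle(as.logical(b))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Truncated centered rolling mean: window of half-width h clipped to [1, n].
roll_mean_trunc <- function(x, ws) {
  check_odd_ws(ws, min = 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (ws - 1L) %/% 2L
  cs0 <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs0[hi + 1L] - cs0[lo]) / (hi - lo + 1L)
}

# Truncated centered rolling sum (same geometry as roll_mean_trunc).
roll_sum_trunc <- function(x, ws) {
  check_odd_ws(ws, min = 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (ws - 1L) %/% 2L
  cs0 <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs0[hi + 1L] - cs0[lo]
}

check_odd_ws <- function(ws, min = 3L) {
  if (!is.numeric(ws) || length(ws) != 1L || is.na(ws) || ws < min ||
      ws %% 2L == 0L) {
    stop(sprintf("window size must be an odd integer >= %d (got %s)",
                 min, paste(ws, collapse = ",")))
  }
  invisible(as.integer(ws))
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Pearson correlation without stats::cor's NA handling surprises.
pearson_cc <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  mean((x - mean(x)) * (y - mean(y))) * length(x) / (length(x) - 1) / (sx * sy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
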