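#' Amino-acid scale sets
#'
#' A scale set maps scale ids to vectors of 20 numeric values in the canonical
#' amino-acid order `ACDEFGHIKLMNPQRSTVWY`. Scales are linearly rescaled to
#' `[0, 1]` before use (a constant scale becomes all 0.5), and `'X'` residues
#' are imputed with the mean of the 20 normalized values.
#'
#' @name scale_set
NULL

# Classical physicochemical scales keyed by AAindex-style ids. Values are the
# published per-residue constants; membership of the working set is
# configurable, this is the bundled default library (17 scales).
builtin_scale_values <- function() {
  o <- AA_ALPHABET
  raw <- list(
    # Kyte-Doolittle hydropathy
    KYTJ820101 = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2),
    # Hopp-Woods hydrophilicity
    HOPT810101 = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2,
                   E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
                   M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4,
                   Y = -2.3, V = -1.5),
    # Eisenberg consensus hydrophobicity
    EISD840101 = c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                   Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                   L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                   S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08),
    # Fauchere-Pliska octanol hydrophobicity
    FAUJ830101 = c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
                   Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
                   L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
                   S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22),
    # Janin transfer free energy (buried/accessible)
    JANJ790102 = c(A = 0.3, R = -1.4, N = -0.5, D = -0.6, C = 0.9, Q = -0.7,
                   E = -0.7, G = 0.3, H = -0.1, I = 0.7, L = 0.5, K = -1.8,
                   M = 0.4, F = 0.5, P = -0.3, S = -0.1, T = -0.2, W = 0.3,
                   Y = -0.4, V = 0.6),
    # Chou-Fasman alpha-helix propensity
    CHOP780201 = c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11,
                   E = 1.51, G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16,
                   M = 1.45, F = 1.13, P = 0.57, S = 0.77, T = 0.83, W = 1.08,
                   Y = 0.69, V = 1.06),
    # Chou-Fasman beta-sheet propensity
    CHOP780202 = c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10,
                   E = 0.37, G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74,
                   M = 1.05, F = 1.38, P = 0.55, S = 0.75, T = 1.19, W = 1.37,
                   Y = 1.47, V = 1.70),
    # Chou-Fasman reverse-turn propensity
    CHOP780203 = c(A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98,
                   E = 0.74, G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01,
                   M = 0.60, F = 0.60, P = 1.52, S = 1.43, T = 0.96, W = 0.96,
                   Y = 1.14, V = 0.50),
    # Zimmerman polarity
    ZIMJ680103 = c(A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48,
                   Q = 3.53, E = 49.90, G = 0.00, H = 51.60, I = 0.13,
                   L = 0.13, K = 49.50, M = 1.43, F = 0.35, P = 1.58,
                   S = 1.67, T = 1.66, W = 2.10, Y = 1.61, V = 0.13),
    # Zimmerman bulkiness
    ZIMJ680102 = c(A = 11.50, R = 14.28, N = 12.82, D = 11.68, C = 13.46,
                   Q = 14.45, E = 13.57, G = 3.40, H = 13.69, I = 21.40,
                   L = 21.40, K = 15.71, M = 16.25, F = 19.80, P = 17.43,
                   S = 9.47, T = 15.77, W = 21.67, Y = 18.03, V = 21.57),
    # Zimmerman isoelectric point
    ZIMJ680104 = c(A = 6.00, R = 10.76, N = 5.41, D = 2.77, C = 5.05,
                   Q = 5.65, E = 3.22, G = 5.97, H = 7.59, I = 6.02,
                   L = 5.98, K = 9.74, M = 5.74, F = 5.48, P = 6.30,
                   S = 5.68, T = 5.66, W = 5.89, Y = 5.66, V = 5.96),
    # Grantham polarity
    GRAR740102 = c(A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5,
                   E = 12.3, G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3,
                   M = 5.7, F = 5.2, P = 8.0, S = 9.2, T = 8.6, W = 5.4,
                   Y = 6.2, V = 5.9),
    # Net charge at neutral pH
    KLEP840101 = c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
                   H = 0, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
                   T = 0, W = 0, Y = 0, V = 0),
    # Molecular weight
    FASG760101 = c(A = 89.09, R = 174.20, N = 132.12, D = 133.10, C = 121.15,
                   Q = 146.15, E = 147.13, G = 75.07, H = 155.16, I = 131.17,
                   L = 131.17, K = 146.19, M = 149.21, F = 165.19, P = 115.13,
                   S = 105.09, T = 119.12, W = 204.24, Y = 181.19, V = 117.15),
    # Vihinen average flexibility index
    VINM940101 = c(A = 0.984, R = 1.008, N = 1.048, D = 1.068, C = 0.906,
                   Q = 1.037, E = 1.094, G = 1.031, H = 0.950, I = 0.927,
                   L = 0.935, K = 1.102, M = 0.952, F = 0.915, P = 1.049,
                   S = 1.046, T = 0.997, W = 0.904, Y = 0.929, V = 0.931),
    # McMeekin molar refractivity
    MCMT640101 = c(A = 4.34, R = 26.66, N = 13.28, D = 12.00, C = 35.77,
                   Q = 17.56, E = 17.26, G = 0.00, H = 21.81, I = 19.06,
                   L = 18.78, K = 21.29, M = 21.64, F = 29.40, P = 10.93,
                   S = 6.35, T = 11.01, W = 42.53, Y = 31.53, V = 13.92),
    # TOP-IDP intrinsic disorder propensity (Campen et al.)
    TOPIDP0101 = c(A = 0.060, R = 0.180, N = 0.007, D = 0.192, C = 0.020,
                   Q = 0.318, E = 0.736, G = 0.166, H = 0.303, I = -0.486,
                   L = -0.326, K = 0.586, M = -0.397, F = -0.697, P = 0.987,
                   S = 0.341, T = 0.059, W = -0.884, Y = -0.510, V = -0.121)
  )
  lapply(raw, function(v) unname(v[o]))
}

#' Build a normalized scale set
#'
#' @param values optional named list of numeric(20) vectors in canonical AA
#'   order; defaults to the bundled library of 17 classical scales.
#' @return object of class `scale_set`: list with `scales` (each normalized to
#'   `[0, 1]`) and `x_value` (per-scale imputation value for `'X'`).
#' @export
scale_set <- function(values = builtin_scale_values()) {
  stopifnot(is.list(values), length(values) > 0L, !is.null(names(values)))
  scales <- lapply(names(values), function(id) {
    v <- as.numeric(values[[id]])
    if (length(v) != 20L || anyNA(v) || any(!is.finite(v))) {
      stop(sprintf("scale '%s' must have exactly 20 finite values", id))
    }
    rng <- range(v)
    if (rng[1] == rng[2]) rep(0.5, 20L) else (v - rng[1]) / (rng[2] - rng[1])
  })
  names(scales) <- names(values)
  structure(list(scales = scales,
                 x_value = vapply(scales, mean, numeric(1))),
            class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat(sprintf("<scale_set> %d normalized scales: %s\n", length(x$scales),
              paste(names(x$scales), collapse = ", ")))
  invisible(x)
}

#' Read a scale table TSV
#'
#' Format: `scale_id` followed by 20 numeric columns in canonical AA order
#' `ACDEFGHIKLMNPQRSTVWY`, tab-separated, `'#'` comments allowed.
#'
#' @param path path to the TSV.
#' @return a normalized [scale_set()].
#' @export
read_scales <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 21L) stop("scale table must have 21 columns (id + 20 values)")
  vals <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, -1]))
  names(vals) <- as.character(df[[1]])
  scale_set(vals)
}

#' Write a scale set to TSV
#'
#' Note the written values are the normalized ones.
#' @param set a [scale_set()].
#' @param path output path.
#' @export
write_scales <- function(set, path) {
  df <- data.frame(id = names(set$scales),
                   do.call(rbind, set$scales), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
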