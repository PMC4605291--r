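#' Per-residue evaluation
#'
#' Assessment follows the per-residue convention: positives are the residues
#' annotated with the target function and negatives are all other residues,
#' including other disordered and all ordered residues. ROC curves sweep the
#' propensity threshold over all distinct scores, ties receive half credit
#' (so the trapezoidal area equals the Mann-Whitney pair statistic), and the
#' TP-rate at a fixed FP-rate is read off the curve by linear interpolation.
#'
#' @name eval_suite
NULL

#' ROC curve and AUC
#'
#' @param scores numeric vector of propensities (higher = more positive).
#' @param labels logical vector; both classes must be present.
#' @return object of class `evaluation_report`: list with `auc`, `roc`
#'   (data.frame `fp_rate`, `tp_rate`, monotone from (0,0) to (1,1)), `n_pos`,
#'   `n_neg`, and `counts(threshold)` accessor fields `tp`, `fp`, `tn`, `fn`
#'   at `threshold = 0.5`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single ROC vertices
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- which(!duplicated(grp, fromLast = TRUE))
  roc <- data.frame(fp_rate = c(0, fp[last] / n0),
                    tp_rate = c(0, tp[last] / n1))
  auc <- sum(diff(roc$fp_rate) * (utils::head(roc$tp_rate, -1) +
                                    utils::tail(roc$tp_rate, -1)) / 2)
  thr <- 0.5
  pos <- scores >= thr
  structure(list(auc = auc, roc = roc, n_pos = n1, n_neg = n0,
                 threshold = thr,
                 tp = sum(pos & labels), fp = sum(pos & !labels),
                 tn = sum(!pos & !labels), fn = sum(!pos & labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> AUC=%.4f (%d pos / %d neg), TP-rate@FP 0.1 = %.3f\n",
              x$auc, x$n_pos, x$n_neg, tp_rate_at_fp(x, 0.1)))
  invisible(x)
}

#' TP-rate at a fixed FP-rate
#'
#' Linearly interpolated on the ROC curve.
#'
#' @param report an [roc_auc()] result.
#' @param fp_level FP-rate in `[0, 1]`, default 0.1.
#' @return TP-rate at `fp_level`.
#' @export
tp_rate_at_fp <- function(report, fp_level = 0.1) {
  if (!is.numeric(fp_level) || fp_level < 0 || fp_level > 1) {
    stop("fp_level must lie in [0, 1]")
  }
  roc <- report$roc
  # approx with ties=max keeps the upper envelope at vertical ROC segments
  stats::approx(roc$fp_rate, roc$tp_rate, xout = fp_level,
                ties = max, rule = 2)$y
}

# Anderson-Darling normality test (case: mean and variance estimated).
# Returns the adjusted statistic and the D'Agostino-Stephens p-value.
ad_normality_test <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = 0, normal = FALSE))
  }
  z <- sort((x - mean(x)) / stats::sd(x))
  logp <- stats::pnorm(z, log.p = TRUE)
  logq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  a2s <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (a2s >= 0.6) {
    exp(1.2937 - 5.709 * a2s + 0.0186 * a2s^2)
  } else if (a2s >= 0.34) {
    exp(0.9177 - 4.279 * a2s - 1.38 * a2s^2)
  } else if (a2s >= 0.2) {
    1 - exp(-8.318 + 42.796 * a2s - 59.938 * a2s^2)
  } else {
    1 - exp(-13.436 + 101.14 * a2s - 223.73 * a2s^2)
  }
  p <- min(max(p, 0), 1)
  list(statistic = a2s, p_value = p, normal = p >= 0.05)
}

# Shared two-sample comparison: t-test iff both vectors pass Anderson-Darling
# normality at 0.05, otherwise Wilcoxon rank-sum.
gated_two_sample_test <- function(a, b, alpha = 0.05) {
  normal <- ad_normality_test(a)$normal && ad_normality_test(b)$normal
  if (normal) {
    p <- stats::t.test(a, b)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    test <- "wilcoxon"
  }
  if (is.na(p)) p <- 1
  list(test_used = test, p_value = max(min(p, 1), .Machine$double.xmin),
       significant = p < alpha)
}

#' Subset-resampling significance of an AUC difference
#'
#' Repeatedly samples a fraction of the proteins without replacement,
#' computes both predictors' AUCs over the pooled residues of the sample,
#' and compares the two AUC vectors with a t-test when both pass
#' Anderson-Darling normality at 0.05 and a Wilcoxon rank-sum test otherwise.
#'
#' @param scores_a,scores_b numeric score vectors of the two predictors.
#' @param labels logical labels, aligned with the scores.
#' @param grouping protein id per residue (sampling unit).
#' @param n_rep number of repetitions, default 10.
#' @param frac fraction of proteins per repetition, default 0.5.
#' @param alpha significance level, default 0.05.
#' @param seed RNG seed for the resampling.
#' @return object of class `significance_result`: `auc_a`, `auc_b` (vectors
#'   of `n_rep` AUCs), `test_used`, `p_value`, `significant`, `seed`.
#' @export
subset_significance <- function(scores_a, scores_b, labels, grouping,
                                n_rep = 10L, frac = 0.5, alpha = 0.05,
                                seed = 1L) {
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels),
            length(grouping) == length(labels))
  ids <- unique(grouping)
  k <- max(1L, floor(frac * length(ids)))
  auc_a <- auc_b <- numeric(n_rep)
  with_local_seed(seed, {
    for (r in seq_len(n_rep)) {
      for (attempt in seq_len(100L)) {
        pick <- sample(ids, k)
        rows <- grouping %in% pick
        if (length(unique(labels[rows])) == 2L) break
        if (attempt == 100L) stop("subset_significance: cannot sample both classes")
        message("subset_significance: single-class repetition resampled")
      }
      auc_a[r] <- rank_auc(scores_a[rows], labels[rows])
      auc_b[r] <- rank_auc(scores_b[rows], labels[rows])
    }
  })
  cmp <- gated_two_sample_test(auc_a, auc_b, alpha)
  structure(list(auc_a = auc_a, auc_b = auc_b,
                 test_used = cmp$test_used, p_value = cmp$p_value,
                 significant = cmp$significant, alpha = alpha, seed = seed),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("<significance_result> %s test, p=%.4g (%ssignificant at %.2g)\n",
              x$test_used, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' FP-rate on matched non-binding control regions
#'
#' Samples control regions matched in count and length to the positive
#' regions of the target function and reports the fraction of their residues
#' predicted positive at the binary cut-off. Control regions are
#' sub-intervals drawn uniformly from the control pool: disordered regions
#' annotated with another binding function but not the target
#' (`control_kind = "other_disorder"`), or regions not annotated as
#' disordered (`control_kind = "non_disordered"`).
#'
#' @param predictions named list: protein id -> numeric propensity vector for
#'   the target function.
#' @param proteins named list of annotated proteins (tracks supply both the
#'   positive regions and the control pool).
#' @param fun target function.
#' @param control_kind `"other_disorder"` or `"non_disordered"`.
#' @param cutoff binarization cut-off, default 0.5.
#' @param seed RNG seed for the sampling.
#' @return list with `fp_rate`, `n_regions`, `region_lengths`,
#'   `sampled_regions` (data.frame `protein_id`, `start`, `end`).
#' @export
control_region_fp_rate <- function(predictions, proteins, fun,
                                   control_kind = c("other_disorder",
                                                    "non_disordered"),
                                   cutoff = 0.5, seed = 1L) {
  control_kind <- match.arg(control_kind)
  stopifnot(fun %in% BINDING_FUNCTIONS)
  pos_lengths <- integer(0)
  pool <- list()
  for (p in proteins) {
    runs <- true_runs(p$tracks[[fun]])
    pos_lengths <- c(pos_lengths, runs$end - runs$start + 1L)
    others <- Reduce(`|`, p$tracks[setdiff(BINDING_FUNCTIONS, fun)])
    ctrl_mask <- if (control_kind == "other_disorder") {
      p$tracks$disorder & others & !p$tracks[[fun]]
    } else {
      !p$tracks$disorder
    }
    cr <- true_runs(ctrl_mask)
    if (nrow(cr) > 0L) {
      pool <- c(pool, lapply(seq_len(nrow(cr)), function(i)
        list(protein_id = p$id, start = cr$start[i], end = cr$end[i])))
    }
  }
  if (length(pos_lengths) == 0L) stop("no positive regions for function: ", fun)
  pool_lens <- vapply(pool, function(r) r$end - r$start + 1L, integer(1))
  sampled <- with_local_seed(seed, {
    lapply(pos_lengths, function(L) {
      ok <- which(pool_lens >= L)
      if (length(ok) == 0L) {
        stop(sprintf("insufficient control regions: none of length >= %d (%d needed)",
                     L, sum(pos_lengths >= L)))
      }
      j <- if (length(ok) == 1L) ok else sample(ok, 1L)
      r <- pool[[j]]
      off <- sample.int(r$end - r$start + 2L - L, 1L) - 1L
      list(protein_id = r$protein_id, start = r$start + off,
           end = r$start + off + L - 1L)
    })
  })
  n_fp <- n_tot <- 0L
  for (r in sampled) {
    pv <- predictions[[r$protein_id]]
    if (is.null(pv)) stop("no predictions for protein: ", r$protein_id)
    b <- pv[r$start:r$end] >= cutoff
    n_fp <- n_fp + sum(b)
    n_tot <- n_tot + length(b)
  }
  list(fp_rate = n_fp / n_tot,
       n_regions = length(sampled),
       region_lengths = pos_lengths,
       sampled_regions = do.call(rbind, lapply(sampled, as.data.frame)))
}
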