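#' End-to-end training and prediction
#'
#' [idr_train()] fits the three per-function binding models on an annotated
#' corpus: it derives the function-specific window sizes from the training
#' region lengths (20th centile rule) unless overridden, builds the
#' contrast/window-mean candidate features over every profile channel, runs
#' the two-stage relevance/redundancy selection, and fits the ridge logistic
#' models. [idr_predict()] applies the models to query proteins and, when a
#' training library is supplied, runs the homology-transfer layer and the
#' `(1 + p) / 2` merge before calling binding regions.
#'
#' @name pipeline
NULL

#' Train the three binding models on an annotated corpus
#'
#' @param proteins named list of [annotated_protein()] with tracks filled.
#' @param set a [scale_set()].
#' @param ws_override optional named integer vector (e.g. `c(rna = 55)`)
#'   fixing the window size of selected functions.
#' @param derive_ws derive window sizes from the corpus region lengths
#'   (default); when `FALSE` (or when a function has no regions) the
#'   per-function defaults 55/21/33 are used.
#' @param ridge_lambda ridge strength or `"cv"` (see
#'   [train_binding_model()]).
#' @param relevance_min_auc,redundancy_max_abs_corr feature-selection
#'   thresholds (see [select_features()]).
#' @param comp_ws composition/complexity channel window.
#' @param training_library_ref optional path recorded in the models for the
#'   transfer layer.
#' @param validate check the training-corpus invariants (disordered runs >= 4,
#'   binding inside disorder) before training.
#' @return list with `models` (named list of [train_binding_model()] results;
#'   functions without positive residues are skipped with a warning),
#'   `selection` (named list of selected feature ids) and `window_sizes`.
#' @export
idr_train <- function(proteins, set = scale_set(), ws_override = NULL,
                      derive_ws = TRUE, ridge_lambda = 1.0,
                      relevance_min_auc = 0.55, redundancy_max_abs_corr = 0.7,
                      comp_ws = 15L, training_library_ref = NA_character_,
                      validate = TRUE) {
  stopifnot(length(proteins) > 0L)
  if (validate) lapply(proteins, validate_training_protein)
  profiles <- lapply(proteins, profile_matrix, set = set, comp_ws = comp_ws)
  models <- list(); selection <- list(); wss <- integer(0)
  for (f in BINDING_FUNCTIONS) {
    labels_by_p <- lapply(proteins, function(p) p$tracks[[f]])
    n_pos <- sum(vapply(labels_by_p, sum, numeric(1)))
    if (n_pos == 0L) {
      warning("no positive residues for function '", f, "'; model skipped")
      next
    }
    ws <- if (!is.null(ws_override) && f %in% names(ws_override)) {
      as.integer(ws_override[[f]])
    } else if (derive_ws) {
      lens <- unlist(lapply(proteins, function(p) {
        runs <- true_runs(p$tracks[[f]])
        runs$end - runs$start + 1L
      }))
      derive_window_size(lens)
    } else {
      window_spec(f)$ws
    }
    spec <- window_spec(f, ws)
    feats <- do.call(rbind, lapply(profiles, build_features, spec = spec))
    feats$residue <- unlist(lapply(proteins, seq_chars), use.names = FALSE)
    labels <- unlist(labels_by_p, use.names = FALSE)
    sel <- select_features(feats, labels,
                           relevance_min_auc = relevance_min_auc,
                           redundancy_max_abs_corr = redundancy_max_abs_corr)
    if (length(sel) == 0L) {
      warning("function '", f,
              "': empty feature selection, training on all candidates")
      sel <- feature_columns(feats)
    }
    models[[f]] <- train_binding_model(
      feats, labels, fun = f, spec = spec, feature_ids = sel,
      ridge_lambda = ridge_lambda,
      training_library_ref = training_library_ref)
    selection[[f]] <- sel
    wss[f] <- ws
  }
  list(models = models, selection = selection, window_sizes = wss)
}

#' Predict propensities and binding regions for query proteins
#'
#' @param models named list of binding models (any subset of
#'   `rna`/`dna`/`protein`).
#' @param proteins named list of query [annotated_protein()] objects.
#' @param library optional named list of annotated training proteins enabling
#'   the homology-transfer layer.
#' @param e_cutoff transfer E-value cut-off (default 0.1); `0` disables the
#'   layer, making the output identical to the regression-only predictor.
#' @param cutoff binarization cut-off for region calling, default 0.5.
#' @param min_len minimum region length, default 4.
#' @param set a [scale_set()] (must match the one used in training).
#' @param comp_ws composition/complexity channel window (must match
#'   training).
#' @param use_all_hits see [transfer_annotations()].
#' @return list with `profiles` (per protein: `p`, `transferred`, `merged`
#'   per-function vectors) and `regions` (data.frame of called regions over
#'   all proteins and functions).
#' @export
idr_predict <- function(models, proteins, library = NULL, e_cutoff = 0.1,
                        cutoff = 0.5, min_len = 4L, set = scale_set(),
                        comp_ws = 15L, use_all_hits = FALSE) {
  stopifnot(length(models) > 0L)
  library_tracks <- if (!is.null(library)) lapply(library, `[[`, "tracks")
  profiles_out <- list()
  regions_out <- list()
  for (p in proteins) {
    pm <- profile_matrix(p, set = set, comp_ws = comp_ws)
    do_transfer <- !is.null(library) && e_cutoff > 0
    hits <- if (do_transfer) search_homologs(p, library) else list()
    prof <- list(protein_id = p$id, p = list(), transferred = list(),
                 merged = list())
    for (f in names(models)) {
      model <- models[[f]]
      feats <- build_features(pm, model$window_spec)
      pv <- predict_binding(model, feats)
      tv <- if (do_transfer) {
        transfer_annotations(p, hits, library_tracks, e_cutoff = e_cutoff,
                             use_all_hits = use_all_hits)[[f]]
      } else {
        integer(nchar(p$sequence))
      }
      mv <- merge_propensity(pv, tv)
      prof$p[[f]] <- pv
      prof$transferred[[f]] <- tv
      prof$merged[[f]] <- mv
      regions_out[[paste(p$id, f)]] <-
        call_regions(binarize(mv, cutoff), min_len = min_len,
                     protein_id = p$id, fun = f, p = mv)
    }
    profiles_out[[p$id]] <- structure(prof, class = "propensity_profile")
  }
  regions <- do.call(rbind, regions_out)
  if (is.null(regions)) {
    regions <- data.frame(protein_id = character(0), function. = character(0),
                          start = integer(0), end = integer(0),
                          mean_propensity = numeric(0))
  }
  rownames(regions) <- NULL
  list(profiles = profiles_out, regions = regions)
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat(sprintf("<propensity_profile> %s\n", x$protein_id))
  for (f in names(x$merged)) {
    cat(sprintf("  %-8s mean p=%.3f, %d transferred residue(s)\n",
                f, mean(x$merged[[f]]), sum(x$transferred[[f]])))
  }
  invisible(x)
}

#' Write per-residue predictions to TSV
#'
#' Columns: `protein_id`, `position`, `residue`, merged propensities
#' `p_rna`, `p_dna`, `p_prot` and binary calls `b_rna`, `b_dna`, `b_prot`.
#' Functions without a model are written as `NA`.
#'
#' @param prediction an [idr_predict()] result.
#' @param proteins the query proteins (for residue letters).
#' @param path output path.
#' @param cutoff binarization cut-off, default 0.5.
#' @export
write_prediction_tsv <- function(prediction, proteins, path, cutoff = 0.5) {
  rows <- lapply(names(prediction$profiles), function(id) {
    prof <- prediction$profiles[[id]]
    n <- length(prof$merged[[1]])
    df <- data.frame(protein_id = id, position = seq_len(n),
                     residue = seq_chars(proteins[[id]]))
    for (f in BINDING_FUNCTIONS) {
      short <- c(rna = "rna", dna = "dna", protein = "prot")[[f]]
      v <- prof$merged[[f]]
      df[[paste0("p_", short)]] <- if (is.null(v)) NA_real_ else v
      df[[paste0("b_", short)]] <- if (is.null(v)) NA_integer_ else
        as.integer(v >= cutoff)
    }
    df
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue prediction TSV
#'
#' @param path a file written by [write_prediction_tsv()].
#' @return named list: protein id -> list of per-function propensity vectors.
#' @export
read_prediction_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$protein_id)) {
    sub <- df[df$protein_id == id, ]
    sub <- sub[order(sub$position), ]
    out[[id]] <- list(rna = sub$p_rna, dna = sub$p_dna, protein = sub$p_prot)
  }
  out
}
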