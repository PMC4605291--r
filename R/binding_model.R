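#' Ridge-penalized logistic regression per binding function
#'
#' One logistic model per function maps the selected contrast/window features
#' of a residue to a propensity in `(0, 1)`. Coefficients maximize the
#' L2-penalized log-likelihood (intercept unpenalized) on features
#' standardized to zero mean and unit variance over the training corpus; the
#' standardization parameters travel with the model so prediction is
#' self-contained. The problem is convex and optimized by Newton/IRLS from a
#' zero start, so training is deterministic.
#'
#' @name binding_model
NULL

MODEL_FORMAT_VERSION <- 1L

# Newton/IRLS for the ridge-penalized logistic log-likelihood.
# X: n x d (standardized, no intercept column); y in {0,1}; lambda > 0.
# Returns beta (d), intercept, and the per-iteration objective trace.
ridge_logistic_fit <- function(X, y, lambda, tol = 1e-8, max_iter = 100L) {
  n <- nrow(X); d <- ncol(X)
  beta <- numeric(d); b0 <- 0
  penalized_nll <- function(b0, beta) {
    eta <- drop(X %*% beta) + b0
    # log(1 + exp(eta)) - y*eta, numerically stable
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) +
      lambda / 2 * sum(beta^2)
  }
  trace <- penalized_nll(b0, beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + b0
    p <- 1 / (1 + exp(-eta))
    g_beta <- drop(crossprod(X, p - y)) + lambda * beta
    g_b0 <- sum(p - y)
    if (sqrt(sum(c(g_b0, g_beta)^2)) <= tol) break
    w <- pmax(p * (1 - p), 1e-10)
    Xw <- X * w
    H <- rbind(
      cbind(sum(w), t(colSums(Xw))),
      cbind(colSums(Xw), crossprod(X, Xw) + diag(lambda, d, d))
    )
    step <- solve(H, c(g_b0, g_beta))
    # damped Newton: halve until the objective does not increase
    s <- 1
    repeat {
      nb0 <- b0 - s * step[1]; nbeta <- beta - s * step[-1]
      obj <- penalized_nll(nb0, nbeta)
      if (obj <= trace[length(trace)] + 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    b0 <- nb0; beta <- nbeta
    trace <- c(trace, obj)
  }
  list(beta = beta, intercept = b0, objective_trace = trace)
}

#' Train a binding model
#'
#' @param features data.frame of feature columns plus bookkeeping columns
#'   (see [build_features()]); rows whose `residue` is `'X'` are dropped from
#'   training.
#' @param labels logical vector aligned with `features` rows: `TRUE` for
#'   residues annotated with the target function, `FALSE` for everything else
#'   (other disordered and ordered residues alike).
#' @param fun the binding function the model predicts.
#' @param spec the [window_spec()] used to build `features`.
#' @param feature_ids columns to use (default: all feature columns).
#' @param ridge_lambda ridge strength on standardized features (default 1),
#'   or `"cv"` to pick from `lambda_grid` by 4-fold cross-validated AUC
#'   (folds split by protein).
#' @param lambda_grid candidate lambdas for `ridge_lambda = "cv"`.
#' @param training_library_ref optional path to the training FASTA/regions,
#'   recorded for the homology-transfer layer.
#' @return object of class `binding_model`.
#' @export
train_binding_model <- function(features, labels, fun, spec,
                                feature_ids = feature_columns(features),
                                ridge_lambda = 1.0,
                                lambda_grid = 10^seq(-3, 2, by = 1),
                                training_library_ref = NA_character_) {
  labels <- as.logical(labels)
  stopifnot(nrow(features) == length(labels))
  if ("residue" %in% colnames(features)) {
    keep <- features$residue != "X"
    features <- features[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) stop("training labels are single-class")
  X <- as.matrix(features[, feature_ids, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values in training data")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  y <- as.numeric(labels)

  if (identical(ridge_lambda, "cv")) {
    groups <- if ("protein_id" %in% colnames(features)) features$protein_id
              else as.character(seq_along(y))
    ridge_lambda <- cv_select_lambda(Xs, y, groups, lambda_grid)
  }
  stopifnot(is.numeric(ridge_lambda), ridge_lambda > 0)
  fit <- ridge_logistic_fit(Xs, y, ridge_lambda)
  structure(list(fun = fun,
                 feature_ids = feature_ids,
                 coefficients = stats::setNames(fit$beta, feature_ids),
                 intercept = fit$intercept,
                 ridge_lambda = ridge_lambda,
                 standardize_mean = stats::setNames(mu, feature_ids),
                 standardize_sd = stats::setNames(sdv, feature_ids),
                 window_spec = spec,
                 training_library_ref = training_library_ref,
                 objective_trace = fit$objective_trace,
                 format_version = MODEL_FORMAT_VERSION),
            class = "binding_model")
}

# 4-fold grouped CV over the lambda grid, maximizing mean held-out AUC.
# Deterministic: folds assigned by group order (round-robin over unique ids).
cv_select_lambda <- function(Xs, y, groups, lambda_grid, k = 4L) {
  ug <- unique(groups)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(ug)), ug)
  folds <- fold_of[groups]
  score <- vapply(lambda_grid, function(lam) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) return(NA_real_)
      fit <- ridge_logistic_fit(Xs[tr, , drop = FALSE], y[tr], lam)
      eta <- drop(Xs[!tr, , drop = FALSE] %*% fit$beta) + fit$intercept
      rank_auc(eta, y[!tr] == 1)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  lambda_grid[which.max(score)]
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> %s: %d features, ws=%d, lambda=%g\n",
              x$fun, length(x$feature_ids), x$window_spec$ws, x$ridge_lambda))
  invisible(x)
}

#' Regression propensities for one protein
#'
#' Evaluates `logistic(intercept + coefficients . standardized features)` at
#' every residue. This is the regression part only; see
#' [transfer_annotations()] and [merge_propensity()] for the homology layer.
#'
#' @param model a [train_binding_model()] result.
#' @param features feature data.frame of one protein containing every column
#'   in `model$feature_ids`.
#' @return numeric vector of propensities in `(0, 1)`.
#' @export
predict_binding <- function(model, features) {
  missing <- setdiff(model$feature_ids, colnames(features))
  if (length(missing) > 0L) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(features[, model$feature_ids, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, model$standardize_mean[model$feature_ids]),
              2L, model$standardize_sd[model$feature_ids], "/")
  eta <- drop(Xs %*% model$coefficients[model$feature_ids]) + model$intercept
  1 / (1 + exp(-eta))
}

#' Save / load a binding model
#'
#' Plain-text versioned key/value header followed by a per-feature table
#' (`id`, `mean`, `sd`, `coefficient`) written with 17 significant digits so
#' propensities round-trip bit-exactly.
#'
#' @param model a `binding_model`.
#' @param path file path.
#' @return `load_model` returns the `binding_model`.
#' @export
save_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# idrbind binding model",
    paste0("format_version\t", model$format_version),
    paste0("function\t", model$fun),
    paste0("ws\t", model$window_spec$ws),
    paste0("ridge_lambda\t", num(model$ridge_lambda)),
    paste0("intercept\t", num(model$intercept)),
    paste0("training_library\t", model$training_library_ref),
    paste0("n_features\t", length(model$feature_ids)),
    "#feature\tmean\tsd\tcoefficient",
    vapply(model$feature_ids, function(id) {
      paste(id, num(model$standardize_mean[[id]]),
            num(model$standardize_sd[[id]]),
            num(model$coefficients[[id]]), sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keyed <- kv[vapply(kv, length, integer(1)) == 2L]
  header <- stats::setNames(vapply(keyed, `[[`, character(1), 2L),
                            vapply(keyed, `[[`, character(1), 1L))
  req <- c("format_version", "function", "ws", "ridge_lambda", "intercept",
           "n_features")
  if (!all(req %in% names(header))) stop("corrupt model file: ", path)
  if (as.integer(header[["format_version"]]) != MODEL_FORMAT_VERSION) {
    stop(sprintf("model format version %s unsupported (expected %d)",
                 header[["format_version"]], MODEL_FORMAT_VERSION))
  }
  tab <- kv[vapply(kv, length, integer(1)) == 4L]
  if (length(tab) != as.integer(header[["n_features"]])) {
    stop("corrupt model file (feature table truncated): ", path)
  }
  ids <- vapply(tab, `[[`, character(1), 1L)
  getnum <- function(i) vapply(tab, function(r) as.numeric(r[[i]]), numeric(1))
  lib <- header[["training_library"]]
  structure(list(fun = header[["function"]],
                 feature_ids = ids,
                 coefficients = stats::setNames(getnum(4L), ids),
                 intercept = as.numeric(header[["intercept"]]),
                 ridge_lambda = as.numeric(header[["ridge_lambda"]]),
                 standardize_mean = stats::setNames(getnum(2L), ids),
                 standardize_sd = stats::setNames(getnum(3L), ids),
                 window_spec = window_spec(header[["function"]],
                                           as.integer(header[["ws"]])),
                 training_library_ref = if (identical(lib, "NA")) NA_character_ else lib,
                 objective_trace = NULL,
                 format_version = MODEL_FORMAT_VERSION),
            class = "binding_model")
}
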