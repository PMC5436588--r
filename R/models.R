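# NFC ~ covariates modelling: four pluggable regression backends (linear,
# additive, neural, forest), compared by cross-validated normalised mean
# square error; the winner hindcasts NFC for periods without observations
# using period-specific road metrics and static topography/climate.

#' Normalised mean square error
#'
#' Mean squared prediction error divided by the population variance of the
#' observations: 0 for perfect prediction, 1 for the global-mean predictor.
#' Values above 1 (worse than the mean predictor) are possible; the useful
#' range is [0, 1].
#'
#' @param predicted,observed numeric vectors of equal length >= 2.
#' @return A single number.
#' @export
nmse <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2)
  v <- mean((observed - mean(observed))^2)
  if (v == 0) stop("observed values are constant: NMSE undefined")
  mean((predicted - observed)^2) / v
}

#' Default NFC model features
#'
#' Topography and climate (ELE, SLO, CPP) plus the four road indicators per
#' class.
#' @return Character vector of column names.
#' @export
nfc_features <- function() {
  c("ELE", "SLO", "CPP",
    paste0(rep(c("SRL", "DNR", "NON", "MND"), 2), "_",
           rep(c("main", "secondary"), each = 4)))
}

# Missing DNR (no road of the class anywhere in a period) is informatively
# far: impute 1.5x the maximum observed DNR of that class and add a
# missingness indicator column.
impute_dnr <- function(df, reference = NULL) {
  for (cl in c("main", "secondary")) {
    col <- paste0("DNR_", cl)
    if (!col %in% names(df)) next
    ref <- if (is.null(reference)) df[[col]] else reference[[col]]
    ind <- paste0(col, "_missing")
    df[[ind]] <- as.numeric(is.na(df[[col]]))
    if (anyNA(df[[col]])) {
      mx <- suppressWarnings(max(ref, na.rm = TRUE))
      if (!is.finite(mx)) mx <- 0
      df[[col]][is.na(df[[col]])] <- 1.5 * mx
    }
  }
  df
}

model_frame <- function(cell_table, features, periods, require_nfc = TRUE) {
  rows <- cell_table$period %in% periods
  df <- cell_table[rows, , drop = FALSE]
  df <- impute_dnr(df)
  miss <- features[!features %in% names(df)]
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  bad <- features[vapply(df[features], anyNA, logical(1))]
  if (length(bad)) stop("NA covariates after imputation: ", paste(bad, collapse = ", "))
  if (require_nfc && anyNA(df$NFC))
    stop("missing NFC in training periods: ", paste(unique(df$period[is.na(df$NFC)]), collapse = ", "))
  df
}

fit_backend <- function(backend, df, features, hyper, seed) {
  x <- as.matrix(df[features])
  y <- df$NFC
  set.seed(seed)
  keep <- features[apply(x, 2, function(v) stats::sd(v) > 0)]
  switch(backend,
    linear = {
      fit <- stats::lm(stats::reformulate(c(keep, "1"), "NFC"), data = df)
      list(predict = function(nd) stats::predict(fit, nd))
    },
    additive = {
      # thin-plate smoothers on non-degenerate features (basis capped small:
      # the backend is a comparator, not the product)
      k <- if (!is.null(hyper$k)) hyper$k else 5
      terms <- vapply(keep, function(f) {
        if (length(unique(df[[f]])) > 2 * k) sprintf("s(%s, k = %d)", f, k) else f
      }, character(1))
      fit <- mgcv::gam(stats::as.formula(paste("NFC ~", paste(terms, collapse = " + "))),
                       data = df, method = "REML")
      list(predict = function(nd) as.numeric(mgcv::predict.gam(fit, nd)))
    },
    neural = {
      size <- if (!is.null(hyper$size)) hyper$size else 8
      decay <- if (!is.null(hyper$decay)) hyper$decay else 1e-3
      ctr <- list(center = colMeans(x), scale = apply(x, 2, stats::sd))
      ctr$scale[ctr$scale == 0] <- 1
      xs <- scale(x, ctr$center, ctr$scale)
      fit <- nnet::nnet(xs, y, size = size, decay = decay, linout = TRUE,
                        maxit = 500, trace = FALSE)
      list(predict = function(nd) {
        nds <- scale(as.matrix(nd[features]), ctr$center, ctr$scale)
        as.numeric(stats::predict(fit, nds))
      })
    },
    forest = {
      ntree <- if (!is.null(hyper$ntree)) hyper$ntree else 500
      mtry <- if (!is.null(hyper$mtry)) hyper$mtry else max(1, floor(length(features) / 3))
      nodesize <- if (!is.null(hyper$nodesize)) hyper$nodesize else 5
      fit <- randomForest::randomForest(x, y, ntree = ntree, mtry = mtry,
                                        nodesize = nodesize)
      list(predict = function(nd) {
        as.numeric(stats::predict(fit, as.matrix(nd[features])))
      })
    },
    stop("unknown backend: ", backend)
  )
}

#' Fit an NFC model
#'
#' Trains one model on the pooled (cell, period) rows of the requested
#' periods — one surface applied across periods, without a period feature.
#' Predictions are clipped to [0, 1].
#'
#' @param cell_table per-cell, per-period covariate table with observed NFC
#'   for the training periods.
#' @param backend one of `"linear"`, `"additive"`, `"neural"`, `"forest"`.
#' @param periods training period labels (pooled).
#' @param features covariate names (default [nfc_features()]); the DNR
#'   missingness indicators are appended automatically.
#' @param seed integer seed making the fit deterministic.
#' @param hyper optional backend-specific hyperparameter list. Forest
#'   defaults: 500 trees, `mtry = floor(p/3)`, node size 5.
#' @return An object of class `fs_model`.
#' @export
fit_nfc_model <- function(cell_table, backend = "forest",
                          periods = unique(cell_table$period),
                          features = nfc_features(), seed = 1L,
                          hyper = list()) {
  df <- model_frame(cell_table, features, periods)
  feats <- c(features, grep("_missing$", names(df), value = TRUE))
  feats <- feats[feats %in% names(df)]
  b <- fit_backend(backend, df, feats, hyper, seed)
  structure(list(backend = backend, features = feats, periods = periods,
                 seed = seed, hyper = hyper, n = nrow(df),
                 dnr_reference = df[grep("^DNR_", names(df), value = TRUE)],
                 predictor = b$predict),
            class = "fs_model")
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf("<fs_model> backend=%s, n=%d, periods=%s\n",
              x$backend, x$n, paste(x$periods, collapse = ",")))
  invisible(x)
}

#' Predict NFC for a covariate table
#'
#' @param object an `fs_model`.
#' @param newdata a cell-table slice with the model's covariates.
#' @param ... unused.
#' @return Predictions clipped to [0, 1].
#' @export
predict.fs_model <- function(object, newdata, ...) {
  nd <- impute_dnr(newdata, reference = object$dnr_reference)
  pmin(pmax(object$predictor(nd), 0), 1)
}

#' Hindcast NFC for a period
#'
#' Applies a fitted model to the target period's road metrics with the
#' period-invariant topographic and climatic covariates.
#'
#' @param model an `fs_model`.
#' @param cell_table the full covariate table.
#' @param period target period label.
#' @return `data.frame` with `cell`, `period`, `NFC_pred`.
#' @export
hindcast <- function(model, cell_table, period) {
  stopifnot(period %in% cell_table$period)
  nd <- cell_table[cell_table$period == period, , drop = FALSE]
  data.frame(cell = nd$cell, period = period,
             NFC_pred = predict(model, nd))
}

#' Compare regression backends by cross-validated NMSE
#'
#' All backends see identical fold assignments. Folds are assigned by CELL,
#' so all periods of a cell share a fold and no cell leaks across the
#' train/test split. The winner is the backend with the lowest pooled
#' out-of-fold NMSE.
#'
#' @param cell_table covariate table with observed NFC.
#' @param backends character vector of backend names (>= 1).
#' @param periods training periods (pooled).
#' @param features covariate names.
#' @param k number of folds (default 10).
#' @param seed seed controlling fold assignment and backend fits.
#' @param hyper named list: backend -> hyperparameter list.
#' @return List of class `fs_backend_comparison`: `table` (backend, nmse,
#'   n_folds_failed), `winner`, `folds`.
#' @export
compare_backends <- function(cell_table, backends = c("linear", "additive", "neural", "forest"),
                             periods = unique(cell_table$period),
                             features = nfc_features(), k = 10, seed = 1L,
                             hyper = list()) {
  stopifnot(length(backends) >= 1, k >= 2)
  df <- model_frame(cell_table, features, periods)
  feats <- c(features, grep("_missing$", names(df), value = TRUE))
  cells <- unique(df$cell)
  set.seed(seed)
  fold_of_cell <- sample(rep(seq_len(k), length.out = length(cells)))
  fold <- fold_of_cell[match(df$cell, cells)]
  res <- data.frame(backend = backends, nmse = NA_real_,
                    n_folds_failed = 0L)
  per_fold <- list()
  for (bi in seq_along(backends)) {
    b <- backends[bi]
    pred <- rep(NA_real_, nrow(df))
    fold_nmse <- rep(NA_real_, k)
    failed <- 0L
    for (f in seq_len(k)) {
      tr <- df[fold != f, , drop = FALSE]
      te <- df[fold == f, , drop = FALSE]
      p <- tryCatch({
        m <- fit_backend(b, tr, feats, hyper[[b]], seed + f)
        pmin(pmax(m$predict(te), 0), 1)
      }, error = function(e) {
        message(sprintf("backend %s failed on fold %d: %s", b, f, conditionMessage(e)))
        NULL
      })
      if (is.null(p)) { failed <- failed + 1L; next }
      pred[fold == f] <- p
      fold_nmse[f] <- nmse(p, te$NFC)
    }
    res$n_folds_failed[bi] <- failed
    if (failed == 0) res$nmse[bi] <- nmse(pred, df$NFC)
    per_fold[[b]] <- fold_nmse
  }
  ok <- !is.na(res$nmse)
  if (!any(ok)) stop("every backend failed cross-validation")
  winner <- res$backend[ok][which.min(res$nmse[ok])]
  structure(list(table = res, winner = winner, per_fold = per_fold,
                 k = k, periods = periods),
            class = "fs_backend_comparison")
}

#' @export
print.fs_backend_comparison <- function(x, ...) {
  cat(sprintf("<backend comparison> %d-fold CV, winner: %s\n", x$k, x$winner))
  print(x$table)
  invisible(x)
}
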