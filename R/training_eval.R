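# Cross-validated training protocol and the benchmarking suite:
# MAE/RMSE, residue-type breakdown, quantile segmentation by
# experimental pKa shift magnitude, null model, shift correlation.

# Reference (model-compound) pKa values of the four modeled types.
REFERENCE_PKA <- c(ASP = 3.7, GLU = 4.2, HIS = 6.5, LYS = 10.4)

#' Null-model prediction: the residue-type reference pKa
#'
#' Baseline predictor returning the fixed reference value for the type
#' (Asp 3.7, Glu 4.2, His 6.5, Lys 10.4) regardless of structure.
#'
#' @param residue_type `"ASP"`, `"GLU"`, `"HIS"` or `"LYS"` (vectorized).
#' @return reference pKa value(s).
#' @export
null_model_predict <- function(residue_type) {
  residue_type <- toupper(residue_type)
  bad <- setdiff(unique(residue_type), names(REFERENCE_PKA))
  if (length(bad))
    stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  unname(REFERENCE_PKA[residue_type])
}

#' Mean absolute error and root mean squared error
#'
#' @param pred,exp numeric vectors of equal positive length.
#' @return named vector `c(mae=, rmse=)`.
#' @export
compute_metrics <- function(pred, exp) {
  if (!length(pred) || length(pred) != length(exp))
    stop("pred and exp must be non-empty vectors of equal length")
  e <- pred - exp
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Quantile-resolved error report
#'
#' Assigns each prediction to a segment by the magnitude of its
#' experimental pKa shift relative to the residue-type reference,
#' `|delta| = |exp - ref(type)|`, using left-closed, right-open
#' intervals between the supplied cut points (the last interval is open
#' at the top, so no pair is ever dropped).  Defaults to the cut points
#' 0.2, 0.5 and 1.0, i.e. segments Q1 = \[0, 0.2), Q2 = \[0.2, 0.5),
#' Q3 = \[0.5, 1.0), Q4 = \[1.0, Inf).
#'
#' @param pred,exp numeric prediction/experiment vectors.
#' @param types residue types (for the reference values).
#' @param boundaries strictly increasing cut points of `|delta|`.
#' @return data frame with one row per segment: interval, count, MAE,
#'   RMSE; the last-to-first MAE and RMSE ratios are attached as
#'   attributes `mae_ratio` and `rmse_ratio`.
#' @export
quantile_report <- function(pred, exp, types, boundaries = c(0.2, 0.5, 1.0)) {
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  shift <- abs(exp - null_model_predict(types))
  edges <- c(0, boundaries, Inf)
  bin <- findInterval(shift, edges, rightmost.closed = FALSE, left.open = FALSE)
  nq <- length(edges) - 1L
  rows <- lapply(seq_len(nq), function(q) {
    in_q <- bin == q
    m <- if (any(in_q)) compute_metrics(pred[in_q], exp[in_q])
         else c(mae = NA_real_, rmse = NA_real_)
    data.frame(quantile = paste0("Q", q), lower = edges[q], upper = edges[q + 1],
               n = sum(in_q), mae = m[["mae"]], rmse = m[["rmse"]])
  })
  out <- do.call(rbind, rows)
  if (out$n[1] > 0 && out$n[nq] > 0) {
    attr(out, "mae_ratio") <- out$mae[nq] / out$mae[1]
    attr(out, "rmse_ratio") <- out$rmse[nq] / out$rmse[1]
  }
  out
}

#' Correlation of predicted versus experimental pKa shifts
#'
#' Pearson correlation between `pred - ref(type)` and `exp - ref(type)`.
#' Because most experimental values sit near the reference, plain
#' MAE/RMSE can flatter a predictor; the shift correlation measures
#' whether deviations from the reference are actually tracked.
#'
#' @param pred,exp numeric vectors.
#' @param types residue types.
#' @return Pearson R.
#' @export
shift_correlation <- function(pred, exp, types) {
  if (length(pred) < 3) stop("need at least 3 pairs for a correlation")
  ref <- null_model_predict(types)
  ps <- pred - ref
  es <- exp - ref
  if (stats::sd(ps) == 0 || stats::sd(es) == 0)
    stop("undefined correlation: a shift vector has zero variance")
  stats::cor(ps, es)
}

#' Full evaluation report
#'
#' Overall and per-residue-type MAE/RMSE, the quantile segmentation and
#' the shift correlation for a set of pooled predictions.
#'
#' @param pred,exp,types as in [quantile_report()].
#' @param boundaries shift-magnitude cut points.
#' @return an `eval_report` list.
#' @export
eval_report <- function(pred, exp, types, boundaries = c(0.2, 0.5, 1.0)) {
  overall <- compute_metrics(pred, exp)
  per_type <- lapply(split(seq_along(pred), toupper(types)), function(ix)
    compute_metrics(pred[ix], exp[ix]))
  qr <- quantile_report(pred, exp, types, boundaries)
  r <- tryCatch(shift_correlation(pred, exp, types), error = function(e) NA_real_)
  structure(list(n = length(pred), mae = overall[["mae"]],
                 rmse = overall[["rmse"]], per_type = per_type,
                 quantiles = qr, mae_ratio = attr(qr, "mae_ratio"),
                 rmse_ratio = attr(qr, "rmse_ratio"), shift_r = r),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, MAE %.3f, RMSE %.3f, shift R %.3f\n",
              x$n, x$mae, x$rmse, x$shift_r))
  print(x$quantiles, row.names = FALSE)
  invisible(x)
}

#' K-fold cross-validation with early stopping
#'
#' Seeded random partition into `k` near-equal folds; each fold is held
#' out in turn, the model trains on the remainder with the held-out fold
#' as the early-stopping monitor (the study's protocol collects
#' validation-batch predictions), and the held-out predictions are
#' pooled so every graph is predicted exactly once.
#'
#' @param graphs list of labeled [residue_graph()] objects.
#' @param config a [model_config()]; fold `f` trains with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @param k number of folds.
#' @param seed partition seed (defaults to `config$seed`).
#' @param stratify when `TRUE`, folds are balanced by residue type.
#' @return list with `folds` (per-fold summaries), `predictions`
#'   (data frame chain/resnum/restype/fold/pred/exp) and `report`
#'   (pooled [eval_report()]).
#' @export
cross_validate <- function(graphs, config, k = 10, seed = config$seed,
                           stratify = FALSE) {
  n <- length(graphs)
  if (k > n) stop("k = ", k, " folds but only ", n, " graphs")
  types <- vapply(graphs, function(g) g$key$residue_name, "")
  fold_of <- with_seed(seed, {
    if (stratify) {
      f <- integer(n)
      for (ty in unique(types)) {
        ix <- sample(which(types == ty))
        f[ix] <- rep_len(seq_len(k), length(ix))
      }
      f
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
  folds <- vector("list", k)
  pred_rows <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- which(fold_of == f)
    rest <- which(fold_of != f)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_model(graphs[rest], graphs[hold], cfg)
    pred <- predict_graphs(fit$params, cfg, graphs[hold])
    pred_rows[[f]] <- data.frame(
      chain = vapply(graphs[hold], function(g) g$key$chain_id, ""),
      resnum = vapply(graphs[hold], function(g) g$key$residue_seq, 0L),
      restype = types[hold],
      source_id = vapply(graphs[hold], function(g) g$source_id, ""),
      fold = f, pred = pred,
      exp = vapply(graphs[hold], function(g) g$label, 0))
    folds[[f]] <- list(fold_index = f, n_validation = length(hold),
                       epochs_run = fit$epochs_run,
                       best_epoch = fit$best_epoch,
                       best_validation_loss = fit$best_val_loss)
  }
  predictions <- do.call(rbind, pred_rows)
  report <- eval_report(predictions$pred, predictions$exp, predictions$restype)
  list(folds = folds, predictions = predictions, report = report)
}

#' Hyperparameter grid search over cross-validated configurations
#'
#' Evaluates the Cartesian product of the supplied axes with
#' [cross_validate()] and returns one row per configuration with its
#' pooled MAE and RMSE.  The best row (minimum MAE, RMSE as tie-break)
#' is flagged.
#'
#' @param graphs labeled graphs.
#' @param grid named list of axes; recognized names: `architecture`,
#'   `hidden_channels`, `batch_size`, `learning_rate`, `dropout_rate`,
#'   `loss`, `n_heads`, `pooling`.  Unlisted axes take [model_config()]
#'   defaults.
#' @param k folds per configuration.
#' @param seed master seed (partition and training).
#' @param max_epochs,patience training-loop caps applied to every
#'   configuration.
#' @return data frame of configurations with `mae`, `rmse` and `best`.
#' @export
grid_search <- function(graphs, grid, k = 10, seed = 1L, max_epochs = 500L,
                        patience = 20L) {
  if (!length(grid)) stop("empty hyperparameter grid")
  allowed <- c("architecture", "hidden_channels", "batch_size",
               "learning_rate", "dropout_rate", "loss", "n_heads", "pooling")
  unknown <- setdiff(names(grid), allowed)
  if (length(unknown))
    stop("unknown grid axis(es): ", paste(unknown, collapse = ", "))
  tab <- expand.grid(grid, stringsAsFactors = FALSE)
  results <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    args <- as.list(row)
    args$seed <- seed
    args$max_epochs <- max_epochs
    args$patience <- patience
    cfg <- do.call(model_config, args)
    cv <- cross_validate(graphs, cfg, k = k, seed = seed)
    results[[i]] <- cbind(row,
                          data.frame(mae = cv$report$mae,
                                     rmse = cv$report$rmse,
                                     stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  ord <- order(out$mae, out$rmse)
  out$best <- FALSE
  out$best[ord[1]] <- TRUE
  out
}

#' Normal-approximation confidence half-width
#'
#' `1.96 * sd / sqrt(n)` for tabulated mean-error reporting.
#'
#' @param x numeric vector.
#' @return half-width of the 95 percent confidence interval.
#' @export
ci95_halfwidth <- function(x) 1.96 * stats::sd(x) / sqrt(length(x))
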