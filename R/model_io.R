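# Self-contained model checkpoints: parameters + configuration +
# normalization constants travel together so a saved model can run
# inference on raw feature extractions.

MODEL_SCHEMA <- "pkagraph-model-v1"

#' Save a trained model checkpoint
#'
#' @param params trained parameters.
#' @param config the matching [model_config()].
#' @param path output JSON path.
#' @param normalization optional constants from [normalize_dataset()].
#' @return `path`, invisibly.
#' @export
save_model <- function(params, config, path, normalization = NULL) {
  payload <- list(schema = MODEL_SCHEMA, config = unclass(config),
                  params = params, normalization = normalization)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint saved by [save_model()]
#'
#' @param path checkpoint path.
#' @return list with `params`, `config`, `normalization`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = TRUE,
                                 simplifyDataFrame = FALSE)
  if (is.null(payload$schema) || !identical(payload$schema, MODEL_SCHEMA))
    stop("model schema mismatch: expected '", MODEL_SCHEMA, "'")
  cfg <- do.call(model_config, payload$config[
    c("architecture", "hidden_channels", "dropout_rate", "n_heads", "pooling",
      "loss", "learning_rate", "batch_size", "seed", "max_epochs", "patience")])
  params <- payload$params
  if (cfg$architecture == "GAT") {
    # jsonlite returns heads as a list of lists; coerce vectors/matrices
    params$heads1 <- lapply(params$heads1, function(hd)
      list(Ws = as.matrix(hd$Ws), Wt = as.matrix(hd$Wt),
           a = as.numeric(hd$a)))
    params$head2 <- list(Ws = matrix(params$head2$Ws, nrow = 1),
                         Wt = matrix(params$head2$Wt, nrow = 1),
                         a = as.numeric(params$head2$a))
  } else {
    for (nm in names(params))
      if (is.list(params[[nm]]) || (is.array(params[[nm]]) &&
                                    length(dim(params[[nm]])) == 2))
        params[[nm]] <- as.matrix(params[[nm]])
    for (nm in c("W1", "W2", "Wout"))
      if (!is.null(params[[nm]])) params[[nm]] <- as.matrix(params[[nm]])
    for (nm in c("b1", "b2", "bout", "eps"))
      if (!is.null(params[[nm]])) params[[nm]] <- as.numeric(params[[nm]])
  }
  norm <- payload$normalization
  if (!is.null(norm)) norm$slots <- as.integer(norm$slots)
  list(params = params, config = cfg, normalization = norm)
}
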