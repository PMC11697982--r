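#' Read and write micro-state time series as CSV
#'
#' The CSV dialect is one row per time step, header \code{x1..xp},
#' comma-separated UTF-8.  Multiple trajectories live in separate files tied
#' together by a JSON manifest.
#'
#' @param path File path.
#' @param series A T x p matrix or tibble.
#' @return \code{read_series} returns a tibble; \code{write_series} the path.
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  m <- as.matrix(out)
  if (!is.numeric(m) || !all(is.finite(m)))
    stop("invalid input: series file must be all-numeric and finite")
  out
}

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(as.matrix(as.data.frame(series)))
  if (is.null(colnames(series)) || all(colnames(df) == paste0("V", seq_len(ncol(df)))))
    names(df) <- paste0("x", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted model with a JSON sidecar
#'
#' The parameter blob is serialized with \code{saveRDS}; a human-readable
#' sidecar \code{<path>.json} records the architecture and training
#' configuration for provenance.
#'
#' @param model A \code{nisplus_model}.
#' @param path Checkpoint path (e.g. \code{"model.rds"}).
#' @return \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    p = model$encoder$p, q = model$encoder$q,
    n_coupling_layers = model$encoder$n_layers,
    hidden_width = model$encoder$hidden,
    config = unclass(model$config),
    epochs_completed = nrow(model$history))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

write_manifest <- function(path, command, config, seeds, inputs, outputs) {
  jsonlite::write_json(
    list(command = command, config = config, seeds = seeds,
         inputs = inputs, outputs = outputs,
         timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
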