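# Versioned plain-text (JSON) weight checkpoints with the element table and
# full config embedded, so a checkpoint is self-describing.

#' Save / load a model checkpoint
#'
#' Checkpoints are JSON files embedding the format version, the full model
#' config (including featurizer parameters and the element table), the
#' fitted self-energies and all weights at full precision.
#'
#' @param model a `neq_model`.
#' @param path file path (conventionally `.json`).
#' @return `path` (save) / a `neq_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "neq_model"))
  cfg <- model$config
  flat <- .flat_params(model)
  obj <- list(
    format = "neqnet-checkpoint", version = 1L,
    config = list(variant = cfg$variant, elements = cfg$elements,
                  d_afv = cfg$d_afv, d_aim = cfg$d_aim,
                  hidden_interaction = cfg$hidden_interaction,
                  hidden_head = cfg$hidden_head, n_passes = cfg$n_passes,
                  seed = cfg$seed,
                  symfun = unclass(cfg$symfun)),
    sae = lapply(as.list(model$sae), function(v) sprintf("%.17g", v)),
    embed_inv_scale = if (!is.null(model$embed_inv_scale))
      sprintf("%.17g", model$embed_inv_scale),
    # weights serialized as %.17g strings: exact double round trip
    params = lapply(flat, function(x)
      list(dim = dim(x) %||% length(x), data = sprintf("%.17g", x))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "neqnet-checkpoint"))
    stop("not a neqnet checkpoint: ", path, call. = FALSE)
  sf <- do.call(symfun_params, obj$config$symfun)
  cfg <- model_config(variant = obj$config$variant,
                      elements = obj$config$elements,
                      d_afv = obj$config$d_afv, d_aim = obj$config$d_aim,
                      hidden_interaction = obj$config$hidden_interaction,
                      hidden_head = obj$config$hidden_head,
                      n_passes = obj$config$n_passes,
                      symfun = sf, seed = obj$config$seed)
  model <- init_model(cfg)
  flat <- .flat_params(model)
  for (nm in names(flat)) {
    p <- obj$params[[nm]]
    if (is.null(p)) stop("checkpoint lacks parameter ", nm, call. = FALSE)
    x <- as.numeric(p$data)
    if (length(p$dim) == 2L) x <- matrix(x, p$dim[1], p$dim[2])
    flat[[nm]] <- x
  }
  model <- .set_flat_params(model, flat)
  model$sae <- stats::setNames(as.numeric(obj$sae), names(obj$sae))
  if (!is.null(obj$embed_inv_scale) && length(obj$embed_inv_scale))
    model$embed_inv_scale <- as.numeric(obj$embed_inv_scale)
  model
}
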