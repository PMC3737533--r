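# Human-diffable JSON serialization of fitted models.

fd_to_list <- function(fd) {
  list(feature = fd$feature, breaks = fd$breaks, mass = fd$mass, n = fd$n,
       pseudocount = fd$pseudocount, stratum = fd$stratum,
       D_cens = fd$D_cens)
}

fd_from_list <- function(x) {
  structure(list(feature = x$feature, breaks = as.numeric(x$breaks),
                 mass = as.numeric(x$mass), n = as.integer(x$n),
                 pseudocount = as.numeric(x$pseudocount),
                 stratum = x$stratum,
                 D_cens = if (is.null(x$D_cens)) NULL else as.integer(x$D_cens)),
            class = "feature_distribution")
}

#' Serialize a fitted model to JSON
#'
#' @param model An `hmm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  side <- function(x) if (inherits(x, "feature_distribution")) fd_to_list(x) else
    lapply(x, fd_to_list)
  obj <- list(
    format = "motifclust_hmm",
    version = 1L,
    feature_set = model$feature_set,
    D_cens = model$D_cens,
    log_base = model$log_base,
    init = as.list(exp(model$log_init)),
    transitions = exp(model$log_trans),
    states = HMM_STATES,
    emissions = lapply(model$emis, function(feat) lapply(feat, side)),
    config = model$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path Path to the JSON file.
#' @return An `hmm_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  if (!identical(x$format, "motifclust_hmm")) {
    abort(sprintf("%s is not a serialized motifclust model", path))
  }
  trans <- as.matrix(x$transitions)
  dimnames(trans) <- list(x$states, x$states)
  emis <- list()
  for (f in names(x$emissions)) {
    emis[[f]] <- lapply(x$emissions[[f]], function(sidev) {
      if (!is.null(sidev$feature)) fd_from_list(sidev) else
        lapply(sidev, fd_from_list)
    })
  }
  hmm_model(
    init = unlist(x$init), trans = trans, emis = emis,
    feature_set = x$feature_set, D_cens = x$D_cens, log_base = x$log_base,
    config = x$config
  )
}
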