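# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted HMM into a long parameter table
#'
#' @param x An `hmm_model`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `component`
#'   (`initial`/`transition`/`emission`), `feature`, `side`, `stratum`,
#'   `from`, `to`, `bin`, `estimate`.
#' @export
tidy.hmm_model <- function(x, ...) {
  init <- tibble(component = "initial", feature = NA_character_,
                 side = NA_character_, stratum = NA_character_,
                 from = NA_character_, to = names(x$log_init),
                 bin = NA_integer_, estimate = exp(unname(x$log_init)))
  allow <- allowed_transitions()
  idx <- which(allow, arr.ind = TRUE)
  trans <- tibble(component = "transition", feature = NA_character_,
                  side = NA_character_, stratum = NA_character_,
                  from = rownames(allow)[idx[, 1]],
                  to = colnames(allow)[idx[, 2]],
                  bin = NA_integer_,
                  estimate = exp(x$log_trans[idx]))
  emis <- list()
  push_fd <- function(feature, side, fd) {
    emis[[length(emis) + 1L]] <<- tibble(
      component = "emission", feature = feature, side = side,
      stratum = as.character(fd$stratum), from = NA_character_,
      to = NA_character_, bin = seq_along(fd$mass), estimate = fd$mass
    )
  }
  for (f in names(x$emis)) {
    for (side in c("pos", "neg")) {
      obj <- x$emis[[f]][[side]]
      if (inherits(obj, "feature_distribution")) push_fd(f, side, obj)
      else for (fd in obj) push_fd(f, side, fd)
    }
  }
  bind_rows(init, trans, bind_rows(emis))
}

#' One-row summary of a fitted HMM
#'
#' @param x An `hmm_model`.
#' @param ... Unused.
#' @return One-row tibble: feature set, censoring, score base, training
#'   sizes (when recorded).
#' @export
glance.hmm_model <- function(x, ...) {
  tibble(
    features = paste(x$feature_set, collapse = "+"),
    d_cens = x$D_cens,
    log_base = x$log_base,
    p_start_cluster = exp(x$log_init[["S_PLUS"]]),
    n_pos_sites = x$config$n_pos_sites %||% NA_integer_,
    n_neg_sites = x$config$n_neg_sites %||% NA_integer_
  )
}

#' Tidy ROC points
#'
#' @param x A `roc_eval`.
#' @param ... Unused.
#' @return The `(threshold, sensitivity, specificity)` tibble.
#' @export
tidy.roc_eval <- function(x, ...) x$points

#' One-row ROC summary
#'
#' @param x A `roc_eval`.
#' @param ... Unused.
#' @return Tibble with `auc`, `n_pos`, `n_neg` and sensitivity at the
#'   recorded specificities.
#' @export
glance.roc_eval <- function(x, ...) {
  wide <- stats::setNames(x$sens_at$sensitivity,
                          sprintf("sens_at_spec%02.0f",
                                  100 * x$sens_at$specificity))
  bind_cols(tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg),
            as_tibble(as.list(wide)))
}
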