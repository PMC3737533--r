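# The six-state HMM. State order is the Viterbi tie-break order (background
# first), so "first maximum" argmax prefers background everywhere.

#' HMM state names, in tie-break order
#'
#' `S_MINUS`/`S_PLUS`: site initiating an input sequence (background /
#' cluster); `MINUS`/`PLUS`: succeeding site; `I_MINUS`/`I_PLUS`: site
#' initiating an internal background region / motif cluster. Background
#' states come first: Viterbi ties resolve to background, so an
#' uninformative model predicts nothing.
#'
#' @format Character vector of six state names.
#' @export
HMM_STATES <- c("S_MINUS", "MINUS", "I_MINUS", "S_PLUS", "PLUS", "I_PLUS")

CLUSTER_STATES <- c("S_PLUS", "PLUS", "I_PLUS")

# state -> homologous state on the other side
HOMOLOG <- c(S_MINUS = "S_PLUS", MINUS = "PLUS", I_MINUS = "I_PLUS",
             S_PLUS = "S_MINUS", PLUS = "MINUS", I_PLUS = "I_MINUS")

# Allowed directed edges. From a cluster-side state you either stay in the
# cluster (PLUS) or leave (I_MINUS); from a background-side state you either
# stay (MINUS) or start a cluster (I_PLUS). Start states are never targets.
allowed_transitions <- function() {
  m <- matrix(FALSE, 6, 6, dimnames = list(HMM_STATES, HMM_STATES))
  for (from in c("S_PLUS", "PLUS", "I_PLUS")) m[from, c("PLUS", "I_MINUS")] <- TRUE
  for (from in c("S_MINUS", "MINUS", "I_MINUS")) m[from, c("MINUS", "I_PLUS")] <- TRUE
  m
}

# Emission component of each feature per state: the spacing component is '+'
# only for the succeeding-cluster state (an internal cluster initiator's
# distance comes from a background gap, hence '-'); start states are
# degenerate at the d = 0 sentinel. Conservation/accessibility follow the
# cluster/background side of the state.
EMIT_D <- c(S_MINUS = "degenerate", MINUS = "neg", I_MINUS = "neg",
            S_PLUS = "degenerate", PLUS = "pos", I_PLUS = "neg")
EMIT_CA <- c(S_MINUS = "neg", MINUS = "neg", I_MINUS = "neg",
             S_PLUS = "pos", PLUS = "pos", I_PLUS = "pos")

#' Construct a six-state HMM model
#'
#' Usually produced by [train_model()]; the constructor is exported so that
#' models can be built directly (e.g. from known distributions).
#'
#' @param init Named numeric: initial probabilities of `S_PLUS`/`S_MINUS`
#'   (natural scale; must sum to 1).
#' @param trans 6x6 matrix of transition probabilities (rows = from, natural
#'   scale); probabilities outside the allowed edges must be 0, rows over
#'   allowed edges must sum to 1.
#' @param emis List of emission components:
#'   `d = list(pos=, neg=)` ([estimate_distribution()] objects),
#'   `c = list(pos = <list per stratum>, neg = <list per stratum>)`,
#'   `a = list(pos=, neg=)`. Components for features outside `feature_set`
#'   may be omitted.
#' @param feature_set Subset of `c("d", "c", "a")`; must contain `"d"`.
#' @param D_cens Spacing censoring threshold the model was built with.
#' @param log_base Base used when reporting cluster scores (default 2;
#'   internal computations are in natural log).
#' @param config Optional list of provenance/training settings.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(init, trans, emis, feature_set = c("d", "c", "a"),
                      D_cens = 30L, log_base = 2, config = list()) {
  stopifnot("d" %in% feature_set, all(feature_set %in% c("d", "c", "a")))
  stopifnot(all(c("S_PLUS", "S_MINUS") %in% names(init)))
  if (abs(sum(init) - 1) > 1e-9) abort("initial probabilities must sum to 1")
  stopifnot(is.matrix(trans), all(dim(trans) == c(6, 6)))
  if (is.null(dimnames(trans))) dimnames(trans) <- list(HMM_STATES, HMM_STATES)
  trans <- trans[HMM_STATES, HMM_STATES]
  allow <- allowed_transitions()
  if (any(trans[!allow] != 0)) {
    abort("transition probability on a disallowed edge")
  }
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-9)) abort("transition rows must sum to 1")
  structure(
    list(
      feature_set = feature_set,
      D_cens = as.integer(D_cens),
      log_base = log_base,
      log_init = stats::setNames(log(c(init[["S_MINUS"]], init[["S_PLUS"]])),
                                 c("S_MINUS", "S_PLUS")),
      log_trans = suppressWarnings(log(trans)),
      emis = emis,
      config = config
    ),
    class = "hmm_model"
  )
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model: features {%s}, D_cens = %d, score base %g>\n",
              paste(x$feature_set, collapse = ","), x$D_cens, x$log_base))
  cat(sprintf("  P(S_PLUS) = %.4f\n", exp(x$log_init[["S_PLUS"]])))
  invisible(x)
}

# Emission log-probability matrix: one row per site, one column per state
# (natural log). Missing `a` drops the accessibility term symmetrically.
emission_matrix <- function(model, feats) {
  n <- nrow(feats)
  E <- matrix(0, n, 6, dimnames = list(NULL, HMM_STATES))
  if (n == 0) return(E)
  d <- feats$d
  if (any(is.na(d)) || any(d < 0 | d > model$D_cens | d != floor(d))) {
    abort(sprintf("spacing d must be integers in [0, %d]", model$D_cens))
  }
  # distance term
  lp_pos <- ifelse(d >= 1, NA_real_, -Inf)
  lp_neg <- lp_pos
  if (any(d >= 1)) {
    lp_pos[d >= 1] <- fd_logmass(model$emis$d$pos, d[d >= 1])
    lp_neg[d >= 1] <- fd_logmass(model$emis$d$neg, d[d >= 1])
  }
  degen <- ifelse(d == 0, 0, -Inf)
  for (s in HMM_STATES) {
    E[, s] <- E[, s] + switch(EMIT_D[[s]],
                              degenerate = degen,
                              pos = lp_pos, neg = lp_neg)
  }
  # conservation term, stratified by region
  if ("c" %in% model$feature_set) {
    if (!"region" %in% names(feats) || !"c" %in% names(feats)) {
      abort("feature columns 'c' and 'region' required by this model")
    }
    reg <- as.character(feats$region)
    lc_pos <- numeric(n); lc_neg <- numeric(n)
    for (r in unique(reg)) {
      ii <- which(reg == r)
      lc_pos[ii] <- fd_logmass(model$emis$c$pos[[r]], feats$c[ii])
      lc_neg[ii] <- fd_logmass(model$emis$c$neg[[r]], feats$c[ii])
    }
    for (s in HMM_STATES) {
      E[, s] <- E[, s] + if (EMIT_CA[[s]] == "pos") lc_pos else lc_neg
    }
  }
  # accessibility term; sites with missing a contribute nothing, in all
  # states alike
  if ("a" %in% model$feature_set) {
    if (!"a" %in% names(feats)) abort("feature column 'a' required by this model")
    ok <- !is.na(feats$a)
    if (any(ok)) {
      la_pos <- numeric(n); la_neg <- numeric(n)
      la_pos[ok] <- fd_logmass(model$emis$a$pos, feats$a[ok])
      la_neg[ok] <- fd_logmass(model$emis$a$neg, feats$a[ok])
      for (s in HMM_STATES) {
        E[, s] <- E[, s] + if (EMIT_CA[[s]] == "pos") la_pos else la_neg
      }
    }
  }
  E
}

#' Emission log-probability of one site under one state
#'
#' Sum of `log Pr(feature | component)` over the model's active feature set,
#' with the component chosen by the state (see the package vignette for the
#' component table) and the site's region stratum for conservation. Start
#' states contribute `log Pr(d = 0) = 0`; a missing accessibility value
#' drops the `a` term in every state symmetrically.
#'
#' @param model An `hmm_model`.
#' @param state One of [HMM_STATES].
#' @param feats One-row tibble with the site's features (`d`, and `c`,
#'   `region`, `a` as required by the model's feature set).
#' @return Natural-log probability (can be `-Inf`).
#' @export
emission_logprob <- function(model, state, feats) {
  stopifnot(state %in% HMM_STATES, nrow(feats) == 1)
  unname(emission_matrix(model, feats)[1, state])
}
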