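#' Viterbi decoding of a site-feature sequence
#'
#' Maximum joint log-probability state path over the allowed transition
#' graph. Ties are broken by the fixed state order `S- < - < I- < S+ < + <
#' I+`, i.e. background is preferred, so a model with symmetric emissions
#' decodes everything as background.
#'
#' @param model An `hmm_model`.
#' @param feats Feature tibble of one scan sequence (>= 1 site, sorted).
#' @return A `state_path`: list with `states` (character vector) and
#'   `log_prob` (natural log joint probability).
#' @export
viterbi <- function(model, feats) {
  n <- nrow(feats)
  if (n < 1) abort("viterbi needs at least one site")
  E <- emission_matrix(model, feats)
  lt <- model$log_trans
  init <- rep(-Inf, 6); names(init) <- HMM_STATES
  init["S_MINUS"] <- model$log_init[["S_MINUS"]]
  init["S_PLUS"] <- model$log_init[["S_PLUS"]]
  dp <- matrix(-Inf, n, 6, dimnames = list(NULL, HMM_STATES))
  bp <- matrix(NA_integer_, n, 6)
  dp[1, ] <- init + E[1, ]
  if (n > 1) {
    for (i in 2:n) {
      for (s in 1:6) {
        cand <- dp[i - 1, ] + lt[, s]
        b <- which.max(cand)          # first max: tie-break order
        dp[i, s] <- cand[b] + E[i, s]
        bp[i, s] <- b
      }
    }
  }
  last <- which.max(dp[n, ])
  path <- integer(n)
  path[n] <- last
  if (n > 1) for (i in n:2) path[i - 1] <- bp[i, path[i]]
  structure(list(states = HMM_STATES[path], log_prob = unname(dp[n, last])),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path: %d sites, log_prob = %.4f>\n",
              length(x$states), x$log_prob))
  cat(" ", paste(x$states, collapse = " "), "\n")
  invisible(x)
}

#' Exhaustive decoding oracle
#'
#' Enumerates every legal state path (first state in `{S+, S-}`, consecutive
#' states on allowed edges) and returns a maximizer. Intended as an
#' independent check of [viterbi()]; refuses sequences longer than 8 sites.
#'
#' @inheritParams viterbi
#' @return A `state_path` with the maximal joint log-probability (the path
#'   itself may differ from Viterbi's under ties; the score may not).
#' @export
brute_force_decode <- function(model, feats) {
  n <- nrow(feats)
  if (n < 1) abort("need at least one site")
  if (n > 8) abort("brute_force_decode refuses more than 8 sites")
  E <- emission_matrix(model, feats)
  lt <- model$log_trans
  allow <- allowed_transitions()
  best <- list(states = NULL, log_prob = -Inf)
  recurse <- function(i, state, acc, path) {
    acc <- acc + E[i, state]
    path[i] <- state
    if (i == n) {
      if (acc > best$log_prob) {
        best <<- list(states = HMM_STATES[path], log_prob = unname(acc))
      }
      return(invisible())
    }
    for (nxt in which(allow[state, ])) {
      recurse(i + 1L, nxt, acc + lt[state, nxt], path)
    }
  }
  for (s0 in c("S_MINUS", "S_PLUS")) {
    recurse(1L, match(s0, HMM_STATES), unname(model$log_init[[s0]]), integer(n))
  }
  structure(best, class = "state_path")
}
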