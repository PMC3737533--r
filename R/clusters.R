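#' Log-likelihood-ratio score of a candidate cluster
#'
#' Implements `log[P(x | cluster) / P(x | background)]` on the decoded
#' Viterbi run: the sum over member sites of the emission log-ratio between
#' the assigned cluster state and its homologous background state
#' (S+ <-> S-, + <-> -, I+ <-> I-), plus, for every within-cluster
#' transition, `log P(+ -> +) - log P(- -> -)`. The initiating site's
#' distance term cancels exactly (I+ and I- share the background distance
#' component; S+ and S- are both degenerate), so the score measures how much
#' better the cluster side explains the member sites, not where the cluster
#' starts. Reported in the model's `log_base` (default 2).
#'
#' @param model An `hmm_model`.
#' @param feats Feature tibble of the whole scan sequence.
#' @param members Integer positions (row indices into `feats`) of the member
#'   sites; must be a contiguous run.
#' @param include_transitions Include the transition log-ratio terms
#'   (default `TRUE`; set `FALSE` for a pure emission score).
#' @return Numeric score.
#' @export
score_cluster <- function(model, feats, members, include_transitions = TRUE) {
  members <- sort(as.integer(members))
  if (length(members) == 0) abort("empty member set")
  if (length(members) > 1 && any(diff(members) != 1L)) {
    abort("cluster members must form a contiguous run of sites")
  }
  E <- emission_matrix(model, feats[members, , drop = FALSE])
  states <- c(if (members[1] == 1L) "S_PLUS" else "I_PLUS",
              rep("PLUS", length(members) - 1L))
  emis_ratio <- sum(E[cbind(seq_along(members), match(states, HMM_STATES))] -
                    E[cbind(seq_along(members),
                            match(HOMOLOG[states], HMM_STATES))])
  trans_ratio <- 0
  if (include_transitions && length(members) > 1) {
    trans_ratio <- (length(members) - 1L) *
      (model$log_trans["PLUS", "PLUS"] - model$log_trans["MINUS", "MINUS"])
  }
  (emis_ratio + trans_ratio) / log(model$log_base)
}

#' Extract and score motif-site clusters from a decoded path
#'
#' Maximal runs of cluster-side states — necessarily of the form
#' `(S+ | I+)(+)*` — become candidate clusters spanning the first member's
#' start to the last member's end. Candidates are scored with
#' [score_cluster()] and filtered: functional binding typically needs at
#' least three clustered elements, so `min_sites = 3` by default.
#'
#' @param model An `hmm_model`.
#' @param feats Feature tibble of one scan sequence (with `seq_id`, `start`,
#'   `end` columns).
#' @param path A `state_path` from [viterbi()] (computed if `NULL`).
#' @param min_sites Minimum member sites per reported cluster.
#' @param min_score Optional minimum score.
#' @return Tibble of cluster calls: `seq_id`, `start`, `end`, `name`,
#'   `score`, `strand`, `n_sites`, `members` (list of member site start
#'   coordinates), sorted by position.
#' @export
call_clusters <- function(model, feats, path = NULL, min_sites = 3L,
                          min_score = NULL) {
  if (is.null(path)) path <- viterbi(model, feats)
  stopifnot(length(path$states) == nrow(feats))
  inc <- path$states %in% CLUSTER_STATES
  empty <- tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  n_sites = integer(), members = list())
  if (!any(inc)) return(empty)
  r <- rle(inc)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    members <- run_start[k]:run_end[k]
    if (length(members) < min_sites) next
    sc <- score_cluster(model, feats, members)
    if (!is.null(min_score) && sc < min_score) next
    out[[length(out) + 1L]] <- tibble(
      seq_id = feats$seq_id[members[1]],
      start = feats$start[members[1]],
      end = feats$end[members[length(members)]],
      name = ".",
      score = sc,
      strand = if ("strand" %in% names(feats)) feats$strand[members[1]] else "+",
      n_sites = length(members),
      members = list(feats$start[members])
    )
  }
  if (length(out) == 0) return(empty)
  bind_rows(out) |> arrange(.data$seq_id, .data$start)
}

#' Predict clusters across a featurized site set
#'
#' Runs Viterbi decoding independently per scan sequence (gene + flanks; no
#' cross-gene paths) and collects scored cluster calls.
#'
#' @param model An `hmm_model`.
#' @param feats Featurized site tibble (several sequences allowed).
#' @param min_sites,min_score Filters, as in [call_clusters()].
#' @return Tibble of cluster calls, with `name` filled as
#'   `cluster_<seq>_<n>`.
#' @export
predict_clusters <- function(model, feats, min_sites = 3L, min_score = NULL) {
  calls <- feats |>
    dplyr::group_split(.data$seq_id) |>
    purrr::map(function(d) {
      call_clusters(model, d, min_sites = min_sites, min_score = min_score)
    }) |>
    bind_rows()
  if (nrow(calls) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  name = character(), score = numeric(), strand = character(),
                  n_sites = integer(), members = list()))
  }
  calls |>
    arrange(.data$seq_id, .data$start) |>
    mutate(name = sprintf("cluster_%s_%d", .data$seq_id,
                          stats::ave(rep(1L, dplyr::n()), .data$seq_id,
                                     FUN = seq_along))) |>
    select("seq_id", "start", "end", "name", "score", "strand", "n_sites",
           "members")
}
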