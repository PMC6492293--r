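#' @title Actor-by-concept stance matrices
#' @name stance
#' @description The two-mode structure underlying all discourse networks:
#'   for every actor and concept, how many coded statements agreed and how
#'   many disagreed. An actor's position on a concept is reduced to a net
#'   stance (sign of agree minus disagree counts); exact ties are
#'   "contested" and concepts an actor never addressed are absent. Net
#'   stances — not raw statements — feed the congruence/conflict/subtract
#'   tie weights.
NULL

#' Aggregate a corpus into a stance matrix
#'
#' @param corpus a `dn_corpus` with at least one statement.
#' @param level actor aggregation level, `"organization"` (default) or
#'   `"person"`.
#' @return A `dn_stance_matrix`: list with `actors` and `concepts` (both in
#'   lexicographic byte order), integer matrices `n_agree` and `n_disagree`
#'   (actors x concepts), `activity` (per-actor total statement count),
#'   `actor_type` (modal coded type per actor, ties broken lexicographically)
#'   and `level`.
#' @export
build_stance_matrix <- function(corpus, level = c("organization", "person")) {
  stopifnot(inherits(corpus, "dn_corpus"))
  level <- match.arg(level)
  df <- corpus$statements
  if (nrow(df) == 0) dn_abort("dn_empty_error", "cannot build a stance matrix from an empty corpus")
  actors <- dn_sort(unique(df[[level]]))
  concepts <- dn_sort(unique(df$concept))
  af <- factor(df[[level]], levels = actors)
  cf <- factor(df$concept, levels = concepts)
  n_agree <- as.matrix(table(af[df$stance == "agree"], cf[df$stance == "agree"]))
  n_disagree <- as.matrix(table(af[df$stance == "disagree"], cf[df$stance == "disagree"]))
  storage.mode(n_agree) <- "integer"
  storage.mode(n_disagree) <- "integer"
  dimnames(n_agree) <- dimnames(n_disagree) <- list(actors, concepts)
  activity <- as.integer(table(af))
  names(activity) <- actors

  actor_type <- vapply(actors, function(a) {
    types <- df$actor_type[df[[level]] == a]
    tab <- table(types)
    dn_sort(names(tab)[tab == max(tab)])[1]
  }, character(1))

  structure(list(actors = actors, concepts = concepts,
                 n_agree = n_agree, n_disagree = n_disagree,
                 activity = activity, actor_type = actor_type,
                 level = level),
            class = "dn_stance_matrix")
}

#' Net stance from agreement and disagreement counts
#'
#' `sign(n_agree - n_disagree)`: `+1` net support, `-1` net rejection, `0`
#' contested (equal positive counts), `NA` absent (no statements at all).
#' Contested and absent stances contribute to neither congruence nor
#' conflict.
#'
#' @param n_agree,n_disagree non-negative counts (vectorized).
#' @return integer vector in `{+1, -1, 0, NA}`.
#' @export
net_stance <- function(n_agree, n_disagree) {
  if (any(n_agree < 0) || any(n_disagree < 0)) {
    dn_abort("dn_config_error", "stance counts must be non-negative")
  }
  out <- as.integer(sign(n_agree - n_disagree))
  out[n_agree == 0 & n_disagree == 0] <- NA_integer_
  out
}

#' Net-stance matrix of a stance matrix
#' @param sm a `dn_stance_matrix`.
#' @return integer matrix (actors x concepts) of net stances, `NA` = absent.
#' @export
net_stance_matrix <- function(sm) {
  stopifnot(inherits(sm, "dn_stance_matrix"))
  out <- matrix(net_stance(as.vector(sm$n_agree), as.vector(sm$n_disagree)),
                nrow = length(sm$actors),
                dimnames = list(sm$actors, sm$concepts))
  out
}

#' Export a stance matrix as a long-format table
#'
#' One row per (actor, concept) pair with at least one statement.
#'
#' @param sm a `dn_stance_matrix`.
#' @return data frame with columns `actor`, `concept`, `n_agree`,
#'   `n_disagree`, `net_stance` (`"support"`, `"reject"`, `"contested"`),
#'   sorted by actor then concept.
#' @export
stance_long <- function(sm) {
  stopifnot(inherits(sm, "dn_stance_matrix"))
  ns <- net_stance_matrix(sm)
  idx <- which(!is.na(ns), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(
    actor = sm$actors[idx[, 1]],
    concept = sm$concepts[idx[, 2]],
    n_agree = sm$n_agree[idx],
    n_disagree = sm$n_disagree[idx],
    net_stance = c("reject", "contested", "support")[ns[idx] + 2L],
    stringsAsFactors = FALSE
  )
}

#' @export
print.dn_stance_matrix <- function(x, ...) {
  cat(sprintf("<dn_stance_matrix> %d %ss x %d concepts, %d statements\n",
              length(x$actors), x$level, length(x$concepts), sum(x$activity)))
  invisible(x)
}
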