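#' @title Weighted actor networks from stance matrices
#' @name network_builder
#' @description Projects the actor-by-concept stance matrix into an
#'   undirected actor network. For an actor pair the tie components are the
#'   numbers of concepts both net-support (`co_support`), both net-reject
#'   (`co_reject`) and on which they take opposite net stances (`diverge`).
#'   The subtract transformation scores
#'   `co_support + co_reject - diverge`; average-activity normalization
#'   divides by the mean number of statements the pair made, so prolific
#'   actors are not rewarded for volume; a threshold (0.4 in the original
#'   study) then retains only robust argumentative similarity as ties.
NULL

#' Tie-weight configuration
#'
#' @param method `"subtract"` (congruence minus conflict; the default),
#'   `"congruence"` or `"conflict"`.
#' @param normalization `"average_activity"` (divide the raw score by the
#'   mean activity of the pair; default) or `"none"`.
#' @param threshold minimum weight for an edge to be retained (`weight >=
#'   threshold`, applied after normalization), or `NULL` to keep every
#'   nonzero-weight edge. Default 0.4.
#' @param activity basis of the activity term: `"statements"` (raw
#'   statement counts; the literal reading of average-activity
#'   normalization, default) or `"distinct_concepts"` (number of concepts
#'   the actor addressed, which makes the weight fully rate-invariant).
#' @return A `dn_tie_config` list.
#' @export
tie_config <- function(method = c("subtract", "congruence", "conflict"),
                       normalization = c("average_activity", "none"),
                       threshold = 0.4,
                       activity = c("statements", "distinct_concepts")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  activity <- match.arg(activity)
  if (!is.null(threshold)) {
    if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) || threshold < 0) {
      dn_abort("dn_config_error", "threshold must be a single non-negative number or NULL")
    }
  }
  structure(list(method = method, normalization = normalization,
                 threshold = threshold, activity = activity),
            class = "dn_tie_config")
}

#' Concept components of an actor pair
#'
#' @param sm a `dn_stance_matrix`.
#' @param a,b distinct actor keys present in `sm`.
#' @return Named integer vector `c(co_support, co_reject, diverge)`.
#'   Concepts where either actor's stance is absent or contested contribute
#'   to none of the three.
#' @export
pair_concept_components <- function(sm, a, b) {
  stopifnot(inherits(sm, "dn_stance_matrix"))
  if (identical(a, b)) dn_abort("dn_self_pair_error", "actor pair must be two distinct actors")
  if (!a %in% sm$actors || !b %in% sm$actors) {
    dn_abort("dn_config_error", "both actors must be present in the stance matrix")
  }
  ns <- net_stance_matrix(sm)
  sa <- ns[a, ]; sb <- ns[b, ]
  both <- !is.na(sa) & !is.na(sb)
  c(co_support = sum(both & sa == 1 & sb == 1),
    co_reject  = sum(both & sa == -1 & sb == -1),
    diverge    = sum(both & sa * sb == -1))
}

activity_for <- function(sm, config) {
  if (config$activity == "statements") {
    sm$activity
  } else {
    ns <- net_stance_matrix(sm)
    stats::setNames(rowSums(!is.na(ns)), sm$actors)
  }
}

#' Tie weight from components and activities
#'
#' @param components numeric vector `(co_support, co_reject, diverge)`.
#' @param activity_a,activity_b the two actors' activities (must be >= 1
#'   under average-activity normalization).
#' @param config a [tie_config()].
#' @return The (unthresholded) tie weight.
#' @export
tie_weight <- function(components, activity_a, activity_b, config = tie_config()) {
  stopifnot(inherits(config, "dn_tie_config"), length(components) == 3)
  raw <- switch(config$method,
    subtract   = components[[1]] + components[[2]] - components[[3]],
    congruence = components[[1]] + components[[2]],
    conflict   = components[[3]]
  )
  if (config$normalization == "average_activity") {
    if (activity_a < 1 || activity_b < 1) {
      dn_abort("dn_degenerate_actor_error",
               "average-activity normalization requires activity >= 1 for both actors")
    }
    raw <- raw / ((activity_a + activity_b) / 2)
  }
  as.numeric(raw)
}

#' Build a weighted actor network
#'
#' One undirected edge per unordered actor pair whose pre-threshold weight
#' is nonzero; thresholding (when configured) then keeps edges with
#' `weight >= threshold`. Nodes are never dropped: actors isolated by the
#' threshold remain in the node table.
#'
#' @param sm a `dn_stance_matrix` with at least two actors.
#' @param config a [tie_config()].
#' @param window optional date interval carried through from the corpus.
#' @return A `dn_network`: list with `nodes` (data frame: `actor`,
#'   `actor_type`, `statement_frequency`), `edges` (data frame: `actor_a <
#'   actor_b`, `weight`, `co_support`, `co_reject`, `diverge`, sorted),
#'   `config`, `window`.
#' @export
build_network <- function(sm, config = tie_config(), window = NULL) {
  stopifnot(inherits(sm, "dn_stance_matrix"), inherits(config, "dn_tie_config"))
  n <- length(sm$actors)
  if (n < 2) dn_abort("dn_too_few_actors_error", "need at least two actors to build a network")

  ns <- net_stance_matrix(sm)
  P <- ns == 1L;  P[is.na(P)] <- FALSE;  storage.mode(P) <- "double"
  M <- ns == -1L; M[is.na(M)] <- FALSE;  storage.mode(M) <- "double"
  co_support <- P %*% t(P)
  co_reject  <- M %*% t(M)
  diverge    <- P %*% t(M) + M %*% t(P)

  raw <- switch(config$method,
    subtract   = co_support + co_reject - diverge,
    congruence = co_support + co_reject,
    conflict   = diverge
  )
  act <- activity_for(sm, config)
  if (config$normalization == "average_activity") {
    if (any(act < 1)) {
      dn_abort("dn_degenerate_actor_error",
               "average-activity normalization requires activity >= 1 for every actor")
    }
    weight <- raw / (outer(act, act, "+") / 2)
  } else {
    weight <- raw
  }

  idx <- which(upper.tri(raw) & raw != 0, arr.ind = TRUE)
  edges <- data.frame(
    actor_a = sm$actors[idx[, 1]],
    actor_b = sm$actors[idx[, 2]],
    weight = weight[idx],
    co_support = as.integer(co_support[idx]),
    co_reject = as.integer(co_reject[idx]),
    diverge = as.integer(diverge[idx]),
    stringsAsFactors = FALSE
  )
  # canonical unordered orientation + deterministic row order
  flip <- edges$actor_a > edges$actor_b
  tmp <- edges$actor_a[flip]
  edges$actor_a[flip] <- edges$actor_b[flip]
  edges$actor_b[flip] <- tmp
  edges <- edges[order(edges$actor_a, edges$actor_b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL

  if (!is.null(config$threshold)) {
    edges <- edges[edges$weight >= config$threshold, , drop = FALSE]
    rownames(edges) <- NULL
  }

  nodes <- data.frame(actor = sm$actors,
                      actor_type = unname(sm$actor_type),
                      statement_frequency = unname(sm$activity),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, config = config, window = window),
            class = "dn_network")
}

#' Congruence and conflict networks of the same stance matrix
#'
#' Built unnormalized and unthresholded so the decomposition
#' `subtract = congruence - conflict` holds exactly, pair by pair.
#'
#' @param sm a `dn_stance_matrix` with at least two actors.
#' @return list with elements `congruence` and `conflict` (`dn_network`s).
#' @export
congruence_conflict_decomposition <- function(sm) {
  list(
    congruence = build_network(sm, tie_config("congruence", "none", threshold = NULL)),
    conflict   = build_network(sm, tie_config("conflict", "none", threshold = NULL))
  )
}

#' Edge list of a network as a data frame
#' @param network a `dn_network`.
#' @return the edge data frame (weight at full precision).
#' @export
edge_list <- function(network) {
  stopifnot(inherits(network, "dn_network"))
  network$edges
}

#' @export
print.dn_network <- function(x, ...) {
  cat(sprintf("<dn_network> %d actors, %d edges (%s, %s%s)\n",
              nrow(x$nodes), nrow(x$edges),
              x$config$method, x$config$normalization,
              if (is.null(x$config$threshold)) ""
              else sprintf(", threshold >= %g", x$config$threshold)))
  invisible(x)
}
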