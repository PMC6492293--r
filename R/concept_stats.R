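#' @title Concept prominence and contestedness tables
#' @name concept_stats
#' @description Per time window, how often each concept (argument) was
#'   agreed and disagreed with at the statement level, and how divided
#'   opinion was. These tables are the data behind per-phase bar plots of a
#'   debate.
NULL

#' Contestedness of a concept
#'
#' `min(n_agree, n_disagree) / max(n_agree, n_disagree)`: 1 means opinion is
#' perfectly divided (equal agreement and disagreement), 0 means unanimity.
#' An artifact-defined statistic; the ratio form makes it invariant under
#' scaling both counts.
#'
#' @param n_agree,n_disagree statement counts (vectorized); at least one of
#'   the pair must be positive.
#' @return numeric in `[0, 1]`.
#' @export
contestedness <- function(n_agree, n_disagree) {
  if (any(n_agree < 0) || any(n_disagree < 0)) {
    dn_abort("dn_config_error", "counts must be non-negative")
  }
  if (any(n_agree + n_disagree == 0)) {
    dn_abort("dn_undefined_ratio_error",
             "contestedness undefined when both counts are zero")
  }
  pmin(n_agree, n_disagree) / pmax(n_agree, n_disagree)
}

#' Per-concept agreement/disagreement frequency table
#'
#' Statement-level tallies per concept and stance, ranked by prominence.
#'
#' @param corpus a `dn_corpus` (possibly a window slice; the corpus window,
#'   if any, is attached to the result).
#' @return A `dn_concept_table` data frame with columns `concept`,
#'   `n_agree`, `n_disagree`, `total`, `contestedness`, sorted by `total`
#'   descending, ties lexicographic. Empty corpus gives an empty table.
#' @export
concept_frequency <- function(corpus) {
  stopifnot(inherits(corpus, "dn_corpus"))
  df <- corpus$statements
  concepts <- dn_sort(unique(df$concept))
  cf <- factor(df$concept, levels = concepts)
  n_agree <- as.integer(table(cf[df$stance == "agree"]))
  n_disagree <- as.integer(table(cf[df$stance == "disagree"]))
  out <- data.frame(concept = concepts,
                    n_agree = n_agree,
                    n_disagree = n_disagree,
                    total = n_agree + n_disagree,
                    stringsAsFactors = FALSE)
  out$contestedness <- if (nrow(out) > 0) contestedness(out$n_agree, out$n_disagree) else numeric(0)
  out <- out[order(-out$total, out$concept, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- corpus$window
  class(out) <- c("dn_concept_table", class(out))
  out
}

#' Concept tables for a sequence of time windows
#'
#' @param corpus a `dn_corpus`.
#' @param windows data frame with `Date` columns `start` and `end`
#'   (half-open intervals).
#' @return data frame with columns `window_start`, `window_end`, `concept`,
#'   `n_agree`, `n_disagree`, `total`, `contestedness`; windows in the given
#'   order. Empty windows contribute no rows.
#' @export
concept_frequency_by_window <- function(corpus, windows) {
  stopifnot(inherits(corpus, "dn_corpus"), is.data.frame(windows),
            all(c("start", "end") %in% names(windows)))
  parts <- lapply(seq_len(nrow(windows)), function(i) {
    tab <- concept_frequency(slice_window(corpus, windows$start[i], windows$end[i]))
    if (nrow(tab) == 0) return(NULL)
    cbind(data.frame(window_start = format(as.Date(windows$start[i])),
                     window_end = format(as.Date(windows$end[i])),
                     stringsAsFactors = FALSE),
          as.data.frame(tab))
  })
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) {
    return(data.frame(window_start = character(0), window_end = character(0),
                      concept = character(0), n_agree = integer(0),
                      n_disagree = integer(0), total = integer(0),
                      contestedness = numeric(0)))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
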