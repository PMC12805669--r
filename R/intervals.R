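#' Coalescent interval bookkeeping for a (possibly heterochronous) tree
#'
#' Sorts tip sampling and coalescence events by height and tracks the number
#' of extant lineages within each inter-event interval. At tied heights
#' sampling events are processed before coalescences, which keeps the
#' lineage count at least 2 at every coalescence.
#'
#' @param tree a [time_tree].
#' @return An object of class `coalescent_intervals`: a list with
#'   `events` (data.frame: height, type `"sampling"`/`"coalescence"`, node)
#'   and `intervals` (data.frame: start, end, lineages, and the node id of
#'   the event closing the interval).
#' @export
coalescent_intervals <- function(tree) {
  n <- tree$n_nodes
  n_tips <- tree$n_tips
  is_sampling <- c(rep(TRUE, n_tips), rep(FALSE, n - n_tips))
  # sampling events sort before coalescences at tied heights
  ord <- order(tree$heights, !is_sampling)
  hts <- tree$heights[ord]
  samp <- is_sampling[ord]
  k <- cumsum(ifelse(samp, 1L, -1L))
  if (k[n] != 1L) stop("coalescent_intervals: lineage count does not end at 1")
  if (any(k < 1L)) stop("coalescent_intervals: lineage count dropped below 1")
  fast_df <- function(x) structure(x, class = "data.frame",
                                   row.names = seq_along(x[[1]]))
  ev <- fast_df(list(height = hts,
                     type = ifelse(samp, "sampling", "coalescence"),
                     node = ord))
  intervals <- fast_df(list(
    start = hts[-n], end = hts[-1], lineages = k[-n],
    end_node = ord[-1], end_type = ev$type[-1]))
  structure(list(events = ev, intervals = intervals),
            class = "coalescent_intervals")
}

#' @export
print.coalescent_intervals <- function(x, ...) {
  cat(sprintf("coalescent_intervals: %d events, %d intervals\n",
              nrow(x$events), nrow(x$intervals)))
  invisible(x)
}
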