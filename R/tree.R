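#' Rooted binary time tree with node heights
#'
#' A `time_tree` is a fixed rooted binary topology whose nodes carry heights
#' measured in time units (years) before the most recent sample: the
#' youngest tip sits at height 0 and heights increase toward the root.
#' Node indexing follows the `ape` convention: tips `1..n`, root `n+1`,
#' further internal nodes `n+2..2n-1`.
#'
#' @param parent integer vector, `parent[i]` = parent node of `i` (0 at root).
#' @param heights numeric node heights (years before most recent sample).
#' @param labels tip labels, length `n`.
#' @return An object of class `time_tree` with fields `n_tips`, `n_nodes`,
#'   `parent`, `children` (list indexed by node, `NULL` at tips), `heights`,
#'   `labels`, `root`, `postorder` (internal nodes, children first), and
#'   `preorder`.
#' @export
time_tree <- function(parent, heights, labels) {
  n_nodes <- length(parent)
  n_tips <- length(labels)
  if (n_nodes != 2L * n_tips - 1L) stop("time_tree: not a binary tree (node count)")
  if (length(heights) != n_nodes) stop("time_tree: heights length mismatch")
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("time_tree: tree must have exactly one root")
  children <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    if (i != root) children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  n_child <- lengths(children)
  if (any(n_child[seq_len(n_tips)] != 0L)) stop("time_tree: tip with children")
  internal <- (n_tips + 1L):n_nodes
  if (any(n_child[internal] != 2L)) stop("time_tree: nonbinary internal node")
  # postorder over internal nodes: children before parents
  depth <- integer(n_nodes)
  for (i in seq_len(n_nodes)) {
    j <- i; d <- 0L
    while (parent[j] != 0L) { j <- parent[j]; d <- d + 1L }
    depth[i] <- d
  }
  postorder <- internal[order(depth[internal], decreasing = TRUE)]
  tree <- structure(list(
    n_tips = n_tips, n_nodes = n_nodes, parent = as.integer(parent),
    children = children, heights = as.numeric(heights), labels = labels,
    root = root, postorder = postorder, preorder = rev(postorder)
  ), class = "time_tree")
  validate_time_tree(tree)
  tree
}

validate_time_tree <- function(tree) {
  h <- tree$heights
  if (any(h[seq_len(tree$n_tips)] < 0)) stop("time_tree: negative tip height")
  if (abs(min(h[seq_len(tree$n_tips)])) > 1e-9) {
    stop("time_tree: youngest tip must have height 0")
  }
  for (i in tree$postorder) {
    for (c in tree$children[[i]]) {
      if (h[i] <= h[c]) {
        stop(sprintf("time_tree: node %d (height %g) not older than child %d (height %g)",
                     i, h[i], c, h[c]))
      }
    }
  }
  invisible(tree)
}

#' Replace the internal-node heights of a time tree
#'
#' Topology and tip heights are immutable; only internal heights vary during
#' inference. Validation of the parent-older-than-child constraint is
#' optional for speed in inner loops.
#'
#' @param tree a [time_tree].
#' @param internal_heights heights for nodes `n+1 .. 2n-1` in node order.
#' @param validate check tree invariants.
#' @return a [time_tree].
#' @export
set_internal_heights <- function(tree, internal_heights, validate = FALSE) {
  tree$heights[(tree$n_tips + 1L):tree$n_nodes] <- internal_heights
  if (validate) validate_time_tree(tree)
  tree
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, root height %.6g\n", x$n_tips, x$heights[x$root]))
  invisible(x)
}

# ---- conversion to/from ape ----

time_tree_from_phylo <- function(phy, dates = NULL) {
  if (is.null(phy$edge.length)) stop("read_newick: tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("read_newick: negative branch length")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy)) {
    stop("read_newick: a single rooted binary tree is required")
  }
  n_tips <- length(phy$tip.label)
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen[phy$edge[, 2]] <- phy$edge.length
  # depths from root, then heights anchored so the deepest tip is at 0
  root <- n_tips + 1L
  depth <- numeric(n_nodes)
  ord <- phy$edge[order(ape::node.depth(phy)[phy$edge[, 2]], decreasing = TRUE), ,
                  drop = FALSE]
  for (k in seq_len(nrow(ord))) depth[ord[k, 2]] <- depth[ord[k, 1]] + blen[ord[k, 2]]
  heights <- max(depth[seq_len(n_tips)]) - depth
  if (!is.null(dates)) {
    miss <- setdiff(phy$tip.label, names(dates))
    if (length(miss)) stop("read_newick: no date for taxa: ", paste(miss, collapse = ", "))
    d <- as.numeric(dates[phy$tip.label])
    heights[seq_len(n_tips)] <- max(d) - d
  } else {
    heights[seq_len(n_tips)][abs(heights[seq_len(n_tips)]) < 1e-9] <- 0
    if (max(abs(heights[seq_len(n_tips)])) < 1e-9) {
      heights[seq_len(n_tips)] <- 0  # isochronous: enforce ultrametric tips exactly
    }
  }
  time_tree(parent, heights, phy$tip.label)
}

as_phylo <- function(tree) {
  n_tips <- tree$n_tips
  internal <- (n_tips + 1L):tree$n_nodes
  edge <- cbind(tree$parent[-tree$root], seq_len(tree$n_nodes)[-tree$root])
  len <- tree$heights[edge[, 1]] - tree$heights[edge[, 2]]
  phy <- list(edge = edge, edge.length = len, tip.label = tree$labels,
              Nnode = length(internal))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Read a rooted time tree from a Newick file
#'
#' Branch lengths are interpreted in years. Without dates the deepest tip is
#' anchored at height 0; with tip dates (calendar years), tip heights are set
#' to `max(date) - date` so the youngest sample sits at height 0. Dates may
#' alternatively be embedded in taxon labels as `name_YYYY` (split on the
#' last underscore); an explicit date table wins on conflict.
#'
#' @param path Newick file path.
#' @param dates optional named numeric vector of tip sampling dates, or a
#'   path to a two-column tab-separated table (taxon, date).
#' @param dates_from_labels parse `name_YYYY` suffixes when no table given.
#' @return A [time_tree].
#' @export
read_newick <- function(path, dates = NULL, dates_from_labels = FALSE) {
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) stop("read_newick: expected a single tree")
  if (is.null(phy)) stop("read_newick: could not parse tree")
  if (is.character(dates) && length(dates) == 1L && file.exists(dates)) {
    dates <- read_date_table(dates)
  }
  if (is.null(dates) && dates_from_labels) {
    dates <- parse_label_dates(phy$tip.label)
  }
  time_tree_from_phylo(phy, dates)
}

#' @rdname read_newick
#' @param text a Newick string (alternative entry point used by tests and
#'   the simulator round-trips).
#' @export
read_newick_text <- function(text, dates = NULL, dates_from_labels = FALSE) {
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("read_newick: could not parse tree")
  if (is.null(dates) && dates_from_labels) dates <- parse_label_dates(phy$tip.label)
  time_tree_from_phylo(phy, dates)
}

#' Write a time tree as Newick (branch lengths in years)
#'
#' @param tree a [time_tree].
#' @param path output path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(as_phylo(tree), digits = 15)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a two-column tab-separated taxon/date table
#'
#' @param path TSV path with columns taxon and decimal date (a header line
#'   is detected and skipped).
#' @return named numeric vector of dates.
#' @export
read_date_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("read_date_table: expected two tab-separated columns")
  if (is.na(suppressWarnings(as.numeric(df[1, 2])))) df <- df[-1, , drop = FALSE]
  dates <- suppressWarnings(as.numeric(df[, 2]))
  if (anyNA(dates)) stop("read_date_table: non-numeric date")
  stats::setNames(dates, as.character(df[, 1]))
}

#' @export
write_date_table <- function(dates, path) {
  utils::write.table(data.frame(taxon = names(dates), date = unname(dates)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_label_dates <- function(labels) {
  parts <- regmatches(labels, regexpr("_[0-9.]+$", labels))
  if (length(parts) != length(labels)) {
    stop("read_newick: some labels lack a _date suffix")
  }
  stats::setNames(as.numeric(sub("^_", "", parts)), labels)
}

# maximum descendant tip height for every node (lower bound of its height)
node_lower_bounds <- function(tree) {
  lb <- numeric(tree$n_nodes)
  lb[seq_len(tree$n_tips)] <- tree$heights[seq_len(tree$n_tips)]
  for (i in tree$postorder) lb[i] <- max(lb[tree$children[[i]]])
  lb
}
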