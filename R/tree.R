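# Species trees carrying WGD events on edges.
#
# Events are serialized in newick comment blocks attached to the node below
# the edge they sit on, e.g. ((A,B)[&WGD=allo],C); places an
# allotetraploidization on the stem of the (A,B) clade. ape's newick parser
# does not carry comments, so reading/writing goes through a sentinel
# substitution pass around ape::read.tree / ape::write.tree.

.WGD_SENTINEL <- "__WGD%s__"

# Names for every node id (1..Ntip tips, then internals). Unlabeled internal
# nodes get stable synthetic names ("n<id>").
node_names <- function(phy) {
  ntip <- length(phy$tip.label)
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", phy$Nnode)
  lab[!nzchar(lab)] <- paste0("n", ntip + which(!nzchar(lab)))
  c(phy$tip.label, lab)
}

#' Construct a WGD-annotated species tree
#'
#' @param phylo a rooted `ape::phylo` tree.
#' @param events `data.frame(node, mode)`: for each WGD, the id of the node
#'   below the edge carrying it and its mode (`"auto"` or `"allo"`). Row
#'   order on a shared edge is the order the events occurred.
#' @return an object of class `wgd_tree`: a list with elements `phylo` and
#'   `events`.
#' @export
wgd_tree <- function(phylo, events = NULL) {
  stopifnot(inherits(phylo, "phylo"))
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  if (is.null(events)) {
    events <- data.frame(node = integer(0), mode = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("node", "mode") %in% names(events)))
  if (nrow(events) && !all(events$mode %in% c("auto", "allo"))) {
    stop("WGD mode must be 'auto' or 'allo'")
  }
  # make node names materialized and stable
  ntip <- length(phylo$tip.label)
  lab <- phylo$node.label
  if (is.null(lab)) lab <- rep("", phylo$Nnode)
  lab[!nzchar(lab)] <- paste0("n", ntip + which(!nzchar(lab)))
  phylo$node.label <- lab
  structure(list(phylo = phylo, events = events), class = "wgd_tree")
}

as_wgd_tree <- function(x) {
  if (inherits(x, "wgd_tree")) return(x)
  if (inherits(x, "phylo")) return(wgd_tree(x))
  stop("expected a wgd_tree or ape::phylo object")
}

#' @export
print.wgd_tree <- function(x, ...) {
  cat(sprintf("WGD-annotated species tree: %d tips, %d WGD event(s)\n",
              length(x$phylo$tip.label), nrow(x$events)))
  if (nrow(x$events)) {
    nms <- node_names(x$phylo)
    for (i in seq_len(nrow(x$events))) {
      cat(sprintf("  %s WGD on the edge above node '%s'\n",
                  x$events$mode[i], nms[x$events$node[i]]))
    }
  }
  invisible(x)
}

#' Read a newick tree with WGD edge annotations
#'
#' Accepts standard newick with optional `[&WGD=auto]` / `[&WGD=allo]`
#' comment blocks attached to the node below the annotated edge (several on
#' one edge are applied in written order). Any other comment blocks are
#' ignored. The tree must be rooted.
#'
#' @param path file to read (or use `text`).
#' @param text newick string, overrides `path`.
#' @return a [wgd_tree()].
#' @export
read_wgd_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply 'path' or 'text'")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  # validate every WGD-tagged comment before substituting
  tags <- regmatches(text, gregexpr("\\[&WGD=[^]]*\\]", text))[[1L]]
  bad <- tags[!grepl("^\\[&WGD=(auto|allo)\\]$", tags)]
  if (length(bad)) {
    stop("malformed WGD annotation (expected [&WGD=auto] or [&WGD=allo]): ",
         paste(bad, collapse = ", "))
  }
  txt <- gsub("\\[&WGD=(auto|allo)\\]", "__WGD\\1__", text)
  # annotations written after a branch length belong to the same edge:
  # move them back onto the label so the numeric field parses
  txt <- gsub("(:[0-9.eE+-]+)((?:__WGD(?:auto|allo)__)+)", "\\2\\1", txt)
  # drop any remaining (non-WGD) comments
  txt <- gsub("\\[[^]]*\\]", "", txt)
  phy <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(phy)) stop("could not parse newick tree")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")

  ntip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label %||% rep("", phy$Nnode))
  ev_node <- integer(0)
  ev_mode <- character(0)
  for (i in seq_along(labels)) {
    if (!grepl("__WGD", labels[i], fixed = TRUE)) next
    modes <- regmatches(labels[i],
                        gregexpr("__WGD(auto|allo)__", labels[i]))[[1L]]
    modes <- sub("^__WGD", "", sub("__$", "", modes))
    ev_node <- c(ev_node, rep(i, length(modes)))
    ev_mode <- c(ev_mode, modes)
    labels[i] <- gsub("__WGD(auto|allo)__", "", labels[i])
  }
  phy$tip.label <- labels[seq_len(ntip)]
  if (phy$Nnode) phy$node.label <- labels[(ntip + 1L):length(labels)]
  wgd_tree(phy, data.frame(node = ev_node, mode = ev_mode,
                           stringsAsFactors = FALSE))
}

#' Write a WGD-annotated tree as newick
#'
#' Inverse of [read_wgd_newick()]: events are emitted as `[&WGD=mode]`
#' comment blocks on the node below their edge.
#'
#' @param tree a [wgd_tree()].
#' @param path output file; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_wgd_newick <- function(tree, path = NULL) {
  tree <- as_wgd_tree(tree)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  labels <- node_names(phy)
  if (nrow(tree$events)) {
    for (i in seq_len(nrow(tree$events))) {
      nd <- tree$events$node[i]
      labels[nd] <- paste0(labels[nd],
                           sprintf(.WGD_SENTINEL, tree$events$mode[i]))
    }
  }
  phy$tip.label <- labels[seq_len(ntip)]
  phy$node.label <- labels[(ntip + 1L):length(labels)]
  nwk <- ape::write.tree(phy)
  nwk <- gsub("__WGD(auto|allo)__", "[&WGD=\\1]", nwk)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

# parent id of every node (0 for the root)
parent_vec <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

# ids on the path from `node` to the root, starting at `node`
root_path <- function(phy, node) {
  par <- parent_vec(phy)
  out <- node
  while (par[node] != 0L) {
    node <- par[node]
    out <- c(out, node)
  }
  out
}

# is `a` an ancestor of `b`? (strict unless inclusive = TRUE)
is_ancestor <- function(phy, a, b, inclusive = FALSE) {
  if (a == b) return(inclusive)
  a %in% root_path(phy, b)[-1L]
}

node_depth_edges <- function(phy, node) length(root_path(phy, node)) - 1L

node_id <- function(phy, name) {
  id <- match(name, node_names(phy))
  if (is.na(id)) stop("unknown tree node: '", name, "'")
  id
}

# number of WGD events experienced on the path from an origin node down to a
# leaf: events whose carrying edge lies strictly below the origin.
n_wgd_on_path <- function(tree, origin, leaf) {
  tree <- as_wgd_tree(tree)
  phy <- tree$phylo
  path <- root_path(phy, leaf)
  if (!origin %in% path) {
    stop("node_of_origin is not ancestral to the leaf")
  }
  below <- path[seq_len(match(origin, path) - 1L)]
  sum(tree$events$node %in% below)
}

# Node below the edge on which the WGD creating a subgenome label occurred.
# Label depth gives the event's ordinal: "1"/"2" come from the first WGD,
# two-character labels ("1a".."2b") from the second, and so on. Events are
# ranked by their distance from the root; ties (parallel WGDs in different
# lineages) are not disambiguated and yield the first by depth.
slot_origin_node <- function(tree, slot) {
  tree <- as_wgd_tree(tree)
  phy <- tree$phylo
  if (identical(slot, "none")) return(length(phy$tip.label) + 1L)
  rank <- if (slot %in% c("1", "2")) 1L else nchar(slot)
  if (!nrow(tree$events)) stop("tree carries no WGD events")
  depths <- vapply(tree$events$node,
                   function(nd) node_depth_edges(phy, nd), integer(1L))
  ord <- order(depths)
  if (rank > nrow(tree$events)) {
    stop("subgenome label '", slot, "' implies more WGDs than the tree carries")
  }
  tree$events$node[ord[rank]]
}
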