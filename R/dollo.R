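# Dollo-parsimony reconstruction of ancestral miRNA repertoires.
#
# Characters are (unit, subgenome-slot) pairs encoded "unit|slot", where a
# unit is an ancestral gene or polycistron. Dollo: each character is gained
# exactly once and only lost thereafter, which matches how subgenome-placed
# miRNA paralogs behave (no re-gain after fractionation).

CHAR_SEP <- "|"

character_name <- function(unit, slot) paste(unit, slot, sep = CHAR_SEP)

split_characters <- function(chars) {
  parts <- strsplit(chars, CHAR_SEP, fixed = TRUE)
  data.frame(unit = vapply(parts, `[`, "", 1L),
             slot = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Leaf presence/absence matrix of (unit, slot) characters
#'
#' @param genomes named list (taxon -> locus table).
#' @param unit_map optional named map family -> unit id (ancestral
#'   polycistrons counted as one unit); default: one unit per family.
#' @return logical matrix, taxa x characters (`"unit|slot"`).
#' @export
leaf_presence <- function(genomes, unit_map = NULL) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  per_taxon <- lapply(genomes, function(g) {
    validate_loci(g)
    units <- if (is.null(unit_map)) g$family else {
      u <- unname(unit_map[g$family])
      u[is.na(u)] <- g$family[is.na(u)]
      u
    }
    unique(character_name(units, g$subgenome))
  })
  chars <- sort(unique(unlist(per_taxon)))
  out <- matrix(FALSE, nrow = length(genomes), ncol = length(chars),
                dimnames = list(names(genomes), chars))
  for (tx in names(genomes)) out[tx, per_taxon[[tx]]] <- TRUE
  out
}

#' Character origin nodes from simulator/database annotations
#'
#' For each (unit, slot) character, the gain can be no older than the later
#' of (i) the unit's annotated node of origin and (ii) the WGD event that
#' created the slot. Supplying these origins to [dollo_reconstruct()]
#' recovers presence even at nodes lying rootward of the MRCA of the
#' surviving carriers.
#'
#' @param genomes named list of locus tables carrying `node_of_origin`.
#' @param tree a [wgd_tree()].
#' @param unit_map optional family -> unit map (see [leaf_presence()]).
#' @return named integer vector: character -> origin node id.
#' @export
character_origins <- function(genomes, tree, unit_map = NULL) {
  tree <- as_wgd_tree(tree)
  phy <- tree$phylo
  nms <- node_names(phy)
  all_loci <- do.call(rbind, lapply(genomes, function(g) {
    g[, c("family", "subgenome", "node_of_origin")]
  }))
  units <- if (is.null(unit_map)) all_loci$family else {
    u <- unname(unit_map[all_loci$family])
    u[is.na(u)] <- all_loci$family[is.na(u)]
    u
  }
  chars <- character_name(units, all_loci$subgenome)
  first <- !duplicated(chars)
  origin_name <- all_loci$node_of_origin[first]
  slot <- all_loci$subgenome[first]
  out <- vapply(seq_along(origin_name), function(i) {
    fam_node <- match(origin_name[i], nms)
    if (is.na(fam_node)) {
      stop("unknown node_of_origin '", origin_name[i], "'")
    }
    slot_node <- slot_origin_node(tree, slot[i])
    # the later (more tipward) of family origin and slot creation
    if (is_ancestor(phy, fam_node, slot_node, inclusive = TRUE)) {
      slot_node
    } else {
      fam_node
    }
  }, integer(1L))
  stats::setNames(out, chars[first])
}

#' Dollo-parsimony ancestral state reconstruction
#'
#' Each character is gained once: on the edge above the MRCA of the leaves
#' carrying it, or at the annotated origin when one is supplied and is
#' ancestral to that MRCA (an annotation that conflicts with the leaf
#' distribution is ignored with a warning). A node is reconstructed as
#' present iff it lies on a path from the gain node to a carrying leaf,
#' which minimizes the number of losses given the single gain; losses are
#' the edges on which presence switches off.
#'
#' @param tree a [wgd_tree()]; leaf names must match the rows of
#'   `presence`.
#' @param presence logical taxa x characters matrix (see
#'   [leaf_presence()]); every character must be present in at least one
#'   leaf.
#' @param origins optional named vector character -> origin node id (see
#'   [character_origins()]).
#' @return an object of class `ancestral_state`: `presence` (node x
#'   character logical matrix over all tree nodes), `gains` (character ->
#'   node id), `losses` (`data.frame(character, node)`, the child node of
#'   each loss edge), and the tree.
#' @export
dollo_reconstruct <- function(tree, presence, origins = NULL) {
  tree <- as_wgd_tree(tree)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nms <- node_names(phy)
  stopifnot(is.matrix(presence), is.logical(presence))
  if (!all(rownames(presence) %in% phy$tip.label)) {
    stop("presence matrix rows must be tree leaf names")
  }
  chars <- colnames(presence)
  if (any(colSums(presence) == 0L)) {
    stop("characters absent from every leaf: ",
         paste(chars[colSums(presence) == 0L], collapse = ", "))
  }
  slot_of <- split_characters(chars)$slot
  par <- parent_vec(phy)

  n_nodes <- ntip + phy$Nnode
  node_presence <- matrix(FALSE, nrow = n_nodes, ncol = length(chars),
                          dimnames = list(nms, chars))
  gains <- integer(length(chars))
  names(gains) <- chars

  for (j in seq_along(chars)) {
    carriers <- match(rownames(presence)[presence[, j]], phy$tip.label)
    mrca <- if (length(carriers) == 1L) carriers else {
      ape::getMRCA(phy, carriers)
    }
    gain <- mrca
    if (!is.null(origins) && chars[j] %in% names(origins)) {
      og <- origins[[chars[j]]]
      if (is_ancestor(phy, og, mrca, inclusive = TRUE)) {
        gain <- og
      } else {
        warning("annotated origin for '", chars[j],
                "' is not ancestral to the carriers' MRCA; using the MRCA")
      }
    }
    # a subgenome slot cannot predate the WGD that created it
    if (slot_of[j] %in% c("1", "2") || nchar(slot_of[j]) >= 2L) {
      slot_node <- slot_origin_node(tree, slot_of[j])
      if (is_ancestor(phy, gain, slot_node)) {
        stop("character '", chars[j], "': gain node predates the WGD that ",
             "created subgenome slot '", slot_of[j], "'")
      }
    }
    gains[j] <- gain
    for (leaf in carriers) {
      nd <- leaf
      repeat {
        node_presence[nd, j] <- TRUE
        if (nd == gain) break
        nd <- par[nd]
        if (nd == 0L) stop("gain node is not ancestral to carrier leaf")
      }
    }
  }

  loss_char <- character(0)
  loss_node <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    pe <- phy$edge[i, 1L]
    chv <- phy$edge[i, 2L]
    off <- node_presence[pe, ] & !node_presence[chv, ]
    if (any(off)) {
      loss_char <- c(loss_char, chars[off])
      loss_node <- c(loss_node, rep(chv, sum(off)))
    }
  }

  structure(
    list(presence = node_presence, gains = gains,
         losses = data.frame(character = loss_char, node = loss_node,
                             stringsAsFactors = FALSE),
         tree = tree),
    class = "ancestral_state"
  )
}

#' @export
print.ancestral_state <- function(x, ...) {
  cat(sprintf("Dollo ancestral states: %d characters on %d nodes, %d losses\n",
              ncol(x$presence), nrow(x$presence), nrow(x$losses)))
  invisible(x)
}

#' Ancestral retention table at an internal node
#'
#' Tabulates the reconstructed repertoire of a last common ancestor in the
#' shape of the classic subgenome retention tables. With
#' `rows = "multiplicity"` (the four-subgenome scheme), rows are
#' multiplicity classes (4x..1x: on how many slots a unit survives) and
#' cells count units present on each slot. With `rows = "origin"` (the
#' two-subgenome scheme), units are classed by whether their origin
#' predates a reference speciation node, and columns are "both"/each slot.
#'
#' @param state an [dollo_reconstruct()] result.
#' @param node name of the internal node to tabulate.
#' @param slots subgenome slots (columns).
#' @param rows `"multiplicity"` or `"origin"`.
#' @param ref_node reference node name for `rows = "origin"`.
#' @param unit_origins named vector unit -> origin node name, required for
#'   `rows = "origin"`.
#' @return integer matrix; column sums over multiplicity rows equal the
#'   per-slot unit totals.
#' @export
lca_retention_table <- function(state, node, slots = SUBGENOME_SLOTS,
                                rows = c("multiplicity", "origin"),
                                ref_node = NULL, unit_origins = NULL) {
  stopifnot(inherits(state, "ancestral_state"))
  rows <- match.arg(rows)
  phy <- state$tree$phylo
  nd <- node_id(phy, node)
  pres <- state$presence[nd, ]
  info <- split_characters(colnames(state$presence))
  keep <- info$slot %in% slots
  info <- info[keep, , drop = FALSE]
  pres <- pres[keep]

  units <- sort(unique(info$unit))
  mat <- matrix(FALSE, nrow = length(units), ncol = length(slots),
                dimnames = list(units, slots))
  mat[cbind(match(info$unit, units), match(info$slot, slots))] <- pres
  mat <- mat[rowSums(mat) > 0L, , drop = FALSE]

  if (rows == "multiplicity") {
    return(retention_table(mat, slots))
  }

  if (length(slots) != 2L) {
    stop("rows = 'origin' is defined for a two-slot scheme")
  }
  if (is.null(ref_node) || is.null(unit_origins)) {
    stop("rows = 'origin' requires ref_node and unit_origins")
  }
  ref <- node_id(phy, ref_node)
  nms <- node_names(phy)
  out <- matrix(0L, nrow = 2L, ncol = 3L,
                dimnames = list(c("pre", "post"), c("both", slots)))
  for (u in rownames(mat)) {
    og <- match(unit_origins[[u]] %||% NA_character_, nms)
    if (is.na(og)) stop("no origin annotation for unit '", u, "'")
    rcl <- if (is_ancestor(phy, og, ref, inclusive = TRUE)) "pre" else "post"
    ccl <- if (all(mat[u, ])) "both" else slots[mat[u, ]]
    out[rcl, ccl] <- out[rcl, ccl] + 1L
  }
  out
}

#' Continued post-LCA losses per subgenome
#'
#' Counts, for each subgenome slot, the characters reconstructed as present
#' at an ancestral node but absent from a descendant leaf, summed over
#' leaves (each leaf contributes independently, so a loss shared by sister
#' taxa counts once per leaf — the convention of per-taxon loss rows in
#' retention tables). A parsimony-based per-edge tally (each loss edge
#' counted once) is attached as attribute `per_edge`.
#'
#' @param state an [dollo_reconstruct()] result.
#' @param lca_node name of the ancestral node.
#' @param leaves leaf names (must all descend from `lca_node`).
#' @param slots subgenome slots to tally.
#' @return named integer vector of per-slot loss counts with attribute
#'   `per_edge`.
#' @export
continued_loss_counts <- function(state, lca_node, leaves,
                                  slots = SUBGENOME_SLOTS) {
  stopifnot(inherits(state, "ancestral_state"))
  phy <- state$tree$phylo
  lca <- node_id(phy, lca_node)
  info <- split_characters(colnames(state$presence))
  keep <- info$slot %in% slots
  tally <- stats::setNames(integer(length(slots)), slots)
  for (tx in leaves) {
    leaf <- node_id(phy, tx)
    if (!is_ancestor(phy, lca, leaf, inclusive = TRUE)) {
      stop("'", lca_node, "' is not ancestral to leaf '", tx, "'")
    }
    lost <- state$presence[lca, keep] & !state$presence[leaf, keep]
    tl <- table(factor(info$slot[keep][lost], levels = slots))
    tally <- tally + as.integer(tl)
  }
  # per-edge convention: each parsimony-placed loss below the LCA once
  per_edge <- stats::setNames(integer(length(slots)), slots)
  if (nrow(state$losses)) {
    below <- vapply(state$losses$node, function(nd) {
      is_ancestor(phy, lca, nd, inclusive = FALSE)
    }, logical(1L))
    slot_l <- split_characters(state$losses$character)$slot
    sel <- below & slot_l %in% slots
    tl <- table(factor(slot_l[sel], levels = slots))
    per_edge <- per_edge + as.integer(tl)
  }
  attr(tally, "per_edge") <- per_edge
  tally
}
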