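# Polycistron clustering under the 50-kb rule and paralog multiplicity
# census per miRNA family, stratified by the number of WGDs a family has
# experienced.

#' Cluster miRNA loci into polycistrons (50-kb rule)
#'
#' Single-linkage chaining along each contig: two neighbouring loci join the
#' same polycistron iff the gap between them (next start minus previous
#' end) is strictly less than `max_gap`. 50 kb is the conventional maximal
#' extent of a miRNA polycistron. Strand is ignored: polycistrons are
#' positional units, and overlapping loci on opposite strands are counted
#' as distinct members of one cluster.
#'
#' @param loci a locus table (any row order; clustering sorts internally by
#'   contig and start).
#' @param max_gap joining threshold in bp (strict `<`; a gap of exactly
#'   `max_gap` separates clusters).
#' @return the locus table sorted by (contig, start) with a `cluster_id`
#'   column added.
#' @seealso [polycistrons()] for the per-cluster summary.
#' @export
cluster_loci <- function(loci, max_gap = 50000) {
  validate_loci(loci)
  if (!is.numeric(max_gap) || length(max_gap) != 1L || max_gap <= 0) {
    stop("max_gap must be a single positive number")
  }
  loci <- loci[order(loci$contig, loci$start, loci$end, loci$locus_id), ,
               drop = FALSE]
  rownames(loci) <- NULL
  n <- nrow(loci)
  if (n == 0L) {
    loci$cluster_id <- character(0)
    return(loci)
  }
  new_cluster <- c(TRUE,
                   loci$contig[-1L] != loci$contig[-n] |
                     (loci$start[-1L] - loci$end[-n]) >= max_gap)
  idx <- cumsum(new_cluster)
  # cluster ids are numbered within contig for readability
  within <- stats::ave(idx, loci$contig, FUN = function(x) match(x, unique(x)))
  loci$cluster_id <- sprintf("%s_c%d", loci$contig, within)
  loci
}

#' Summarize polycistrons
#'
#' @param clustered output of [cluster_loci()].
#' @return one row per cluster: contig, span, member count and families.
#' @export
polycistrons <- function(clustered) {
  stopifnot("cluster_id" %in% names(clustered))
  if (!nrow(clustered)) {
    return(data.frame(cluster_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      n_loci = integer(0), span = integer(0),
                      families = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(clustered)), clustered$cluster_id)
  out <- do.call(rbind, lapply(names(sp), function(cid) {
    rows <- clustered[sp[[cid]], , drop = FALSE]
    data.frame(
      cluster_id = cid, contig = rows$contig[1L],
      start = min(rows$start), end = max(rows$end),
      n_loci = nrow(rows), span = max(rows$end) - min(rows$start),
      families = paste(sort(unique(rows$family)), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Paralog occurrence profile per family
#'
#' For each miRNA family, counts the number of distinct genomic occurrences
#' (polycistrons or singleton loci under the 50-kb rule) and stratifies
#' families by age class: the number of WGD events the family has
#' experienced, i.e. WGDs lying on the tree path between the family's node
#' of origin and the censused taxon. With no tandem duplication the
#' occurrence count of a family that experienced n WGDs is at most 2^n.
#'
#' @param loci locus table of one taxon.
#' @param tree optional [wgd_tree()]; without it all families fall in one
#'   age class (`n_wgd = 0`).
#' @param taxon leaf name of the censused taxon (required with `tree`).
#' @param max_gap clustering threshold in bp.
#' @return a list of class `occurrence_profile`: `profile` (one row per
#'   family: occurrences and `n_wgd`) and `histogram`
#'   (`n_wgd` x occurrences -> number of families).
#' @export
occurrence_profile <- function(loci, tree = NULL, taxon = NULL,
                               max_gap = 50000) {
  clustered <- cluster_loci(loci, max_gap)
  if (nrow(clustered) == 0L) {
    prof <- data.frame(family = character(0), occurrences = integer(0),
                       n_wgd = integer(0), stringsAsFactors = FALSE)
    hist <- data.frame(n_wgd = integer(0), occurrences = integer(0),
                       n_families = integer(0), stringsAsFactors = FALSE)
    return(structure(list(profile = prof, histogram = hist),
                     class = "occurrence_profile"))
  }
  occ <- tapply(clustered$cluster_id, clustered$family,
                function(x) length(unique(x)))
  fams <- names(occ)
  if (is.null(tree)) {
    n_wgd <- rep(0L, length(fams))
  } else {
    tree <- as_wgd_tree(tree)
    if (is.null(taxon)) stop("taxon must be given when a tree is supplied")
    leaf <- node_id(tree$phylo, taxon)
    origin_of <- clustered$node_of_origin[match(fams, clustered$family)]
    nms <- node_names(tree$phylo)
    n_wgd <- vapply(seq_along(fams), function(i) {
      oid <- match(origin_of[i], nms)
      if (is.na(oid)) {
        stop("unknown node_of_origin '", origin_of[i],
             "' for family '", fams[i], "'")
      }
      n_wgd_on_path(tree, oid, leaf)
    }, integer(1L))
  }
  prof <- data.frame(family = fams, occurrences = as.integer(occ),
                     n_wgd = n_wgd, stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  tab <- as.data.frame(table(n_wgd = prof$n_wgd,
                             occurrences = prof$occurrences),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  hist <- data.frame(n_wgd = as.integer(tab$n_wgd),
                     occurrences = as.integer(tab$occurrences),
                     n_families = tab$Freq, stringsAsFactors = FALSE)
  hist <- hist[order(hist$n_wgd, hist$occurrences), , drop = FALSE]
  rownames(hist) <- NULL
  structure(list(profile = prof, histogram = hist),
            class = "occurrence_profile")
}

#' @export
print.occurrence_profile <- function(x, ...) {
  cat(sprintf("Occurrence profile: %d families\n", nrow(x$profile)))
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Maximum paralog multiplicity in an age class
#'
#' @param profile an [occurrence_profile()].
#' @param age_class number of WGDs experienced (`NULL`: all families).
#' @return the maximum occurrence count; errors on an empty class. With
#'   `tandem_rate = 0` this is bounded by `2^age_class`.
#' @export
max_multiplicity <- function(profile, age_class = NULL) {
  stopifnot(inherits(profile, "occurrence_profile"))
  prof <- profile$profile
  if (!is.null(age_class)) prof <- prof[prof$n_wgd == age_class, , drop = FALSE]
  if (!nrow(prof)) {
    stop("no families in age class ",
         if (is.null(age_class)) "(any)" else age_class)
  }
  max(prof$occurrences)
}

#' Subgenome retention table from one genome
#'
#' Tabulates, per retention unit (ancestral gene or polycistron) and
#' subgenome slot, the presence of at least one locus, then cross-tabulates
#' multiplicity class (on how many slots the unit survives) against slot.
#' This is the shape of the classic four-subgenome retention tables: rows
#' 4x..1x, columns 1a, 2a, 1b, 2b, cells counting units.
#'
#' @param loci locus table (one taxon or a reconstructed ancestral genome).
#' @param slots subgenome slots to tabulate (columns).
#' @param unit_map optional named map family -> unit id to count ancestral
#'   polycistrons as single units ("genes or clusters of genes"); the
#'   default counts each family separately.
#' @return an integer matrix (multiplicity class x slot) with a `"total"`
#'   attribute-free final interpretation: column sums equal per-slot unit
#'   counts.
#' @export
retention_from_loci <- function(loci, slots = SUBGENOME_SLOTS,
                                unit_map = NULL) {
  validate_loci(loci)
  keep <- loci$subgenome %in% slots
  loci <- loci[keep, , drop = FALSE]
  units <- if (is.null(unit_map)) loci$family else {
    u <- unname(unit_map[loci$family])
    u[is.na(u)] <- loci$family[is.na(u)]
    u
  }
  presence <- table(units, factor(loci$subgenome, levels = slots)) > 0L
  retention_table(presence, slots)
}

# Shared builder: presence is a logical units x slots matrix.
retention_table <- function(presence, slots) {
  k <- length(slots)
  rows <- paste0(k:1, "x")
  out <- matrix(0L, nrow = k, ncol = k, dimnames = list(rows, slots))
  if (nrow(presence)) {
    mult <- rowSums(presence)
    for (m in seq_len(k)) {
      sel <- presence[mult == m, , drop = FALSE]
      out[paste0(m, "x"), ] <- as.integer(colSums(sel))
    }
  }
  out
}
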