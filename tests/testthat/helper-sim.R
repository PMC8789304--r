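# Shared fixtures: small trees and parameter sets built in code.

# Two-tip tree with n WGDs stacked on the terminal edge of tip A.
chain_tree <- function(n_wgd, modes = NULL) {
  if (is.null(modes)) {
    modes <- if (n_wgd >= 2L) c("auto", "allo", rep("auto", n_wgd - 2L))
    else rep("auto", n_wgd)
  }
  ann <- paste(sprintf("[&WGD=%s]", modes), collapse = "")
  read_wgd_newick(text = sprintf("(A%s:0.05,B:0.05)root;", ann))
}

# Five-taxon tree: auto then allo WGD on the ingroup stem, outgroup OUT.
ingroup_tree <- function() {
  read_wgd_newick(text = paste0(
    "(((A:0.05,B:0.05)AB:0.05,(C:0.05,D:0.05)CD:0.05)",
    "ING[&WGD=auto][&WGD=allo]:0.05,OUT:0.2)root;"
  ))
}

# Small parameter sets for quick simulations.
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_families = 20, n_linkage_groups = 5, cluster_fraction = 0.25,
         mean_cluster_size = 2, lg_length = 1e8, rng_seed = 1L),
    list(...)
  )
  do.call(sim_params, args)
}

# Brute-force clustering oracle: transitive closure of the pairwise
# same-contig gap-< relation (O(n^2)), independent of the chaining code.
oracle_clusters <- function(loci, max_gap = 50000) {
  n <- nrow(loci)
  if (n == 0L) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (loci$contig[i] != loci$contig[j]) next
      gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j])
      if (gap < max_gap) adj[i, j] <- TRUE
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(adj[i, ])
      if (length(linked)) {
        m <- min(comp[c(i, linked)])
        if (any(comp[c(i, linked)] != m)) {
          comp[c(i, linked)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random locus table on a handful of contigs (for property-style tests)
random_loci <- function(n, n_contigs = 3, span = 5e5, width = 70) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(
    locus_id = sprintf("L%03d", seq_len(n)),
    family = sprintf("Fam%02d", sample.int(max(1L, n %/% 2L), n, replace = TRUE)),
    paralog_label = "",
    contig = sprintf("ctg%d", sample.int(n_contigs, n, replace = TRUE)),
    start = start, end = start + width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    subgenome = "none", node_of_origin = "root",
    stringsAsFactors = FALSE
  )
}
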