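# Forward simulator: ancestral genome layout, WGD, fractionation, sequence
# drift, expression, and composition along a WGD-annotated species tree.

# Placement constants (bp). Units (singleton genes or polycistrons) are
# separated by at least 50 kb so they never chain into one cluster; loci
# within a polycistron sit well under 50 kb apart.
.INTER_UNIT_GAP <- c(60000L, 150000L)
.INTRA_UNIT_GAP <- c(200L, 20000L)
.LG_OFFSET <- c(10000L, 100000L)

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a pre-WGD ancestral miRNA genome
#'
#' Lays out `n_families` single-copy miRNA families over
#' `n_linkage_groups` linkage groups. A fraction of families
#' (`cluster_fraction`) is organised into polycistrons whose internal gaps
#' are far below 50 kb, while distinct genes/polycistrons are spaced at
#' least 50 kb apart, so the 50-kb clustering rule recovers the intended
#' units exactly. Each family receives a random precursor sequence; the
#' seed (mature positions 2-8) is recorded and later protected from
#' substitution.
#'
#' @param params a [sim_params()] object.
#' @param with_sequences generate precursor/mature sequences? Retention-only
#'   studies can skip them.
#' @param origin_node name recorded as `node_of_origin` for ancestral
#'   families (default `"root"`).
#' @return a locus table (`data.frame`) with one row per miRNA gene:
#'   coordinates (0-based half-open), `family`, `subgenome` (`"none"` before
#'   any WGD), `node_of_origin`, the ancestral unit id `anc_unit`
#'   (polycistron membership), and, if requested, `pre_seq`, `mature5p`,
#'   `mature3p`.
#' @export
simulate_ancestral_genome <- function(params, with_sequences = TRUE,
                                      origin_node = "root") {
  p <- validate_sim_params(params)
  n <- p$n_families
  fams <- sprintf("Fam%03d", seq_len(n))

  # Partition families into polycistrons and singletons.
  n_target <- round(p$cluster_fraction * n)
  sizes <- integer(0)
  total <- 0L
  while (total + 2L <= n_target) {
    s <- 2L + stats::rpois(1L, max(p$mean_cluster_size - 2, 0))
    s <- min(s, n_target - total)
    if (s < 2L) break
    sizes <- c(sizes, s)
    total <- total + s
  }
  ord <- sample.int(n)
  units <- list()
  at <- 1L
  for (s in sizes) {
    units[[length(units) + 1L]] <- fams[ord[at:(at + s - 1L)]]
    at <- at + s
  }
  for (i in seq_len(n - total)) {
    units[[length(units) + 1L]] <- fams[ord[at]]
    at <- at + 1L
  }
  units <- units[sample.int(length(units))]

  lg_names <- sprintf("LG%02d", seq_len(p$n_linkage_groups))
  lg_of_unit <- rep_len(seq_len(p$n_linkage_groups), length(units))

  # Reject layouts that cannot respect the spacing rules.
  max_size <- max(c(1L, sizes))
  max_span <- (max_size - 1L) * (.INTRA_UNIT_GAP[2L] + p$pre_len) + p$pre_len
  per_lg <- tabulate(lg_of_unit, nbins = p$n_linkage_groups)
  need <- .LG_OFFSET[2L] + per_lg * (.INTER_UNIT_GAP[2L] + max_span)
  if (any(need > p$lg_length)) {
    stop("linkage groups cannot hold the requested genes/clusters at the ",
         "required >= 50 kb spacing; increase lg_length or n_linkage_groups")
  }

  fam_out <- character(0)
  lg_out <- character(0)
  start_out <- integer(0)
  unit_out <- character(0)
  for (li in seq_len(p$n_linkage_groups)) {
    here <- which(lg_of_unit == li)
    if (!length(here)) next
    pos <- sample(.LG_OFFSET[1L]:.LG_OFFSET[2L], 1L)
    for (k in seq_along(here)) {
      u <- units[[here[k]]]
      uid <- sprintf("%s.u%d", lg_names[li], k)
      for (j in seq_along(u)) {
        if (j > 1L) {
          pos <- pos + p$pre_len +
            sample(.INTRA_UNIT_GAP[1L]:.INTRA_UNIT_GAP[2L], 1L)
        }
        fam_out <- c(fam_out, u[j])
        lg_out <- c(lg_out, lg_names[li])
        start_out <- c(start_out, pos)
        unit_out <- c(unit_out, uid)
      }
      pos <- pos + p$pre_len +
        sample(.INTER_UNIT_GAP[1L]:.INTER_UNIT_GAP[2L], 1L)
    }
  }

  loci <- data.frame(
    locus_id = fam_out,
    family = fam_out,
    paralog_label = "",
    contig = lg_out,
    lg = lg_out,
    start = start_out,
    end = start_out + p$pre_len,
    strand = sample(c("+", "-"), length(fam_out), replace = TRUE),
    subgenome = "none",
    node_of_origin = origin_node,
    anc_unit = unit_out,
    stringsAsFactors = FALSE
  )
  loci <- loci[order(match(loci$family, fams)), , drop = FALSE]
  rownames(loci) <- NULL

  if (with_sequences) {
    pre <- random_dna(nrow(loci), p$pre_len)
    loci$pre_seq <- pre
    loci$mature5p <- substr(pre, 1L, p$mature_len)
    loci$mature3p <- substr(pre, p$pre_len - p$mature_len + 1L, p$pre_len)
  }
  validate_loci(loci)
}

#' Duplicate a genome through one WGD
#'
#' Every contig and locus is duplicated once. The two copies receive the
#' split subgenome labels (first WGD: `none -> 1, 2`; second WGD:
#' `1 -> 1a, 1b` and `2 -> 2a, 2b`, matching the P1-P4 paralog-label
#' convention). Sequences start identical between copies and coordinates
#' are preserved on each daughter contig.
#'
#' @param genome a locus table.
#' @param event a [wgd_event()].
#' @return the doubled locus table.
#' @export
apply_wgd <- function(genome, event) {
  validate_loci(genome)
  stopifnot(inherits(event, "wgd_event"))
  labels <- unique(genome$subgenome)
  map <- event$label_map %||% default_label_map(labels)
  if (!all(labels %in% names(map))) {
    stop("label_map does not cover current subgenome labels: ",
         paste(setdiff(labels, names(map)), collapse = ", "))
  }
  lg <- if ("lg" %in% names(genome)) genome$lg else genome$contig
  halves <- lapply(1:2, function(side) {
    h <- genome
    h$subgenome <- vapply(map[genome$subgenome], `[`, character(1L), side)
    h$lg <- lg
    h$contig <- paste0(lg, "_", h$subgenome)
    h$paralog_label <- paralog_label_for(h$subgenome)
    h$locus_id <- paste(h$family, h$subgenome, sep = "_")
    h
  })
  out <- rbind(halves[[1L]], halves[[2L]])
  out$locus_id <- make.unique(out$locus_id, sep = ".")
  rownames(out) <- NULL
  out
}

#' Fractionation: subgenome-biased paralog loss
#'
#' Deletes each locus independently with the loss probability of its
#' subgenome. Under allotetraploidy losses accrue preferentially on one
#' parental subgenome (the beta side in the vertebrate 2R event); under
#' autotetraploidy the probabilities are symmetric.
#'
#' @param genome a locus table.
#' @param loss_prob named numeric covering every subgenome label present.
#' @return the surviving loci, with attributes `removed` (the deleted rows)
#'   and `loss_tally` (deletions per subgenome).
#' @export
fractionate <- function(genome, loss_prob) {
  validate_loci(genome)
  labels <- unique(genome$subgenome)
  missing <- setdiff(labels, names(loss_prob))
  if (length(missing)) {
    stop("loss_prob lacks entries for subgenome labels: ",
         paste(missing, collapse = ", "))
  }
  if (!is_prob(loss_prob)) stop("loss probabilities must lie in [0, 1]")
  pr <- unname(loss_prob[genome$subgenome])
  drop <- stats::runif(nrow(genome)) < pr
  out <- genome[!drop, , drop = FALSE]
  removed <- genome[drop, , drop = FALSE]
  rownames(out) <- NULL
  tally <- table(factor(removed$subgenome, levels = sort(labels)))
  attr(out, "removed") <- removed
  attr(out, "loss_tally") <- stats::setNames(as.integer(tally), names(tally))
  out
}

#' Evolve precursor sequences along a branch
#'
#' Jukes-Cantor-like drift: each unconstrained site accumulates a
#' Poisson(`branch_len` x multiplier) number of substitutions, each
#' replacing the current base uniformly among the three alternatives. The
#' seed positions of both mature arms are hard-masked and never change, so
#' the seed heptamer stays identical across all paralogs of a family.
#' Mature sequences are re-derived from the evolved precursor.
#'
#' @param genome a locus table with sequences.
#' @param branch_len branch length in substitutions/site (>= 0) on the
#'   unconstrained portion.
#' @param rate_multiplier named numeric of per-subgenome rate factors
#'   (absent labels use 1).
#' @param seed_positions seed positions within the mature arm (default 2-8).
#' @return the locus table with evolved sequences.
#' @export
evolve_sequences <- function(genome, branch_len, rate_multiplier = NULL,
                             seed_positions = 2:8) {
  validate_loci(genome, require_seqs = TRUE)
  if (length(branch_len) != 1L || is.na(branch_len) || branch_len < 0) {
    stop("branch_len must be a single number >= 0")
  }
  n <- nrow(genome)
  if (n == 0L || branch_len == 0) return(genome)

  pre <- genome$pre_seq
  pre_len <- nchar(pre[1L])
  mlen <- nchar(genome$mature5p[1L])
  mask <- unique(c(seed_positions, (pre_len - mlen) + seed_positions))
  free <- setdiff(seq_len(pre_len), mask)

  mult <- lookup(rate_multiplier, genome$subgenome, 1)
  n_events <- stats::rpois(n, branch_len * mult * length(free))
  for (i in which(n_events > 0L)) {
    chars <- strsplit(pre[i], "", fixed = TRUE)[[1L]]
    pos <- free[sample.int(length(free), n_events[i], replace = TRUE)]
    for (pp in pos) {
      chars[pp] <- sample(BASES[BASES != chars[pp]], 1L)
    }
    pre[i] <- paste(chars, collapse = "")
  }
  genome$pre_seq <- pre
  genome$mature5p <- substr(pre, 1L, mlen)
  genome$mature3p <- substr(pre, pre_len - mlen + 1L, pre_len)
  genome
}

#' Simulate mature-miRNA expression
#'
#' Reads per million are drawn from a lognormal and scaled by a
#' per-subgenome multiplier, emulating the enhanced expression of
#' alpha-subgenome paralogs observed after allotetraploidy.
#'
#' @param genome a locus table.
#' @param expr_base numeric `c(meanlog, sdlog)` of log rpm.
#' @param expr_multiplier named numeric of per-subgenome factors (> 0;
#'   absent labels use 1).
#' @return `data.frame(locus_id, rpm)`.
#' @export
simulate_expression <- function(genome, expr_base = c(meanlog = 4, sdlog = 1),
                                expr_multiplier = numeric()) {
  validate_loci(genome)
  if (length(expr_base) != 2L || expr_base[2L] < 0) {
    stop("expr_base must be c(meanlog, sdlog) with sdlog >= 0")
  }
  if (length(expr_multiplier) && any(expr_multiplier <= 0)) {
    stop("expr_multiplier values must be > 0")
  }
  mult <- lookup(expr_multiplier, genome$subgenome, 1)
  rpm <- stats::rlnorm(nrow(genome), expr_base[1L], expr_base[2L]) * mult
  data.frame(locus_id = genome$locus_id, rpm = rpm, stringsAsFactors = FALSE)
}

new_family_locus <- function(genome, fam, node_name, params, with_sequences,
                             used_seeds) {
  if (nrow(genome)) {
    contigs <- unique(genome$contig)
    ci <- contigs[sample.int(length(contigs), 1L)]
    row1 <- genome[match(ci, genome$contig), , drop = FALSE]
    start <- max(genome$end[genome$contig == ci]) +
      sample(.INTER_UNIT_GAP[1L]:.INTER_UNIT_GAP[2L], 1L)
    sub <- row1$subgenome
    lg <- if ("lg" %in% names(row1)) row1$lg else row1$contig
  } else {
    ci <- "LG01"
    lg <- "LG01"
    start <- sample(.LG_OFFSET[1L]:.LG_OFFSET[2L], 1L)
    sub <- "none"
  }
  locus <- data.frame(
    locus_id = if (sub == "none") fam else paste(fam, sub, sep = "_"),
    family = fam, paralog_label = paralog_label_for(sub),
    contig = ci, lg = lg, start = start, end = start + params$pre_len,
    strand = sample(c("+", "-"), 1L), subgenome = sub,
    node_of_origin = node_name, anc_unit = paste0("born.", fam),
    stringsAsFactors = FALSE
  )
  if (with_sequences) {
    repeat {
      pre <- random_dna(1L, params$pre_len)
      m5 <- substr(pre, 1L, params$mature_len)
      seed <- substr(m5, min(params$seed_positions), max(params$seed_positions))
      if (!seed %in% used_seeds$seen) break
    }
    used_seeds$seen <- c(used_seeds$seen, seed)
    locus$pre_seq <- pre
    locus$mature5p <- m5
    locus$mature3p <- substr(pre, params$pre_len - params$mature_len + 1L,
                             params$pre_len)
  }
  locus
}

#' Simulate a clade of miRNA genomes along a WGD-annotated species tree
#'
#' Composes the elementary operations along a rooted species tree: WGD
#' events attached to edges double the genome (auto or allo mode),
#' fractionation removes paralogs with per-subgenome probabilities on every
#' post-WGD branch, sequences drift with per-subgenome rate multipliers
#' (seed masked), new families are born along branches at
#' `family_birth_rate` with fresh unused seeds, and expression is drawn at
#' the leaves. The full truth (per-node snapshots, per-branch loss tallies,
#' event modes, multipliers, seed) is recorded so downstream inference can
#' be validated exactly.
#'
#' All randomness derives from `params$rng_seed`; identical parameters and
#' seed reproduce the simulation bit-for-bit.
#'
#' @param tree a [wgd_tree()] (or bare `ape::phylo`, taken as event-free).
#' @param params a [sim_params()] object.
#' @param sequences simulate sequences? (`FALSE` skips drift; useful for
#'   retention-only studies.)
#' @param out_dir optional directory: per-leaf BED/FASTA/rpm files, the
#'   annotated tree and `truth.json` are written there.
#' @return a list of class `wgd_simulation` with elements `genomes` (named
#'   list of leaf locus tables), `expression` (named list of rpm tables),
#'   `tree`, and `truth`.
#' @export
simulate_clade <- function(tree, params, sequences = TRUE, out_dir = NULL) {
  tree <- as_wgd_tree(tree)
  p <- validate_sim_params(params)
  phy <- tree$phylo
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  if (nrow(tree$events) && any(tree$events$node == root)) {
    stop("WGD events cannot be placed on the root's parent edge")
  }
  nms <- node_names(phy)

  set.seed(p$rng_seed)
  anc <- simulate_ancestral_genome(p, with_sequences = sequences,
                                   origin_node = nms[root])
  used_seeds <- new.env(parent = emptyenv())
  used_seeds$seen <- if (sequences) {
    unique(substr(anc$mature5p, min(p$seed_positions), max(p$seed_positions)))
  } else {
    character(0)
  }

  snapshots <- list()
  snapshots[[nms[root]]] <- anc
  loss_tallies <- list()
  event_log <- list()
  fam_counter <- p$n_families

  phy2 <- stats::reorder(phy, "cladewise")
  has_bl <- !is.null(phy2$edge.length)
  for (i in seq_len(nrow(phy2$edge))) {
    par <- phy2$edge[i, 1L]
    ch <- phy2$edge[i, 2L]
    g <- snapshots[[nms[par]]]

    ev_here <- which(tree$events$node == ch)
    for (k in ev_here) {
      before <- unique(g$subgenome)
      g <- apply_wgd(g, wgd_event(mode = tree$events$mode[k]))
      event_log[[length(event_log) + 1L]] <- list(
        node = nms[ch], mode = tree$events$mode[k],
        labels_created = setdiff(unique(g$subgenome), before)
      )
    }

    if (nrow(g) && any(g$subgenome != "none") && length(p$loss_prob)) {
      labels <- unique(g$subgenome)
      lp <- stats::setNames(lookup(p$loss_prob, labels, 0), labels)
      g <- fractionate(g, lp)
      loss_tallies[[nms[ch]]] <- attr(g, "loss_tally")
    }

    bl <- if (has_bl) phy2$edge.length[i] else p$branch_lengths
    if (sequences && bl > 0 && nrow(g)) {
      g <- evolve_sequences(g, bl, p$rate_multiplier, p$seed_positions)
    }

    if (p$tandem_rate > 0 && nrow(g)) {
      dup <- stats::runif(nrow(g)) < p$tandem_rate
      if (any(dup)) {
        td <- g[dup, , drop = FALSE]
        shift <- td$end - td$start +
          sample(.INTRA_UNIT_GAP[1L]:.INTRA_UNIT_GAP[2L], nrow(td),
                 replace = TRUE)
        td$start <- td$start + shift
        td$end <- td$end + shift
        td$locus_id <- paste0(td$locus_id, ".t")
        g <- rbind(g, td)
        g$locus_id <- make.unique(g$locus_id, sep = ".")
      }
    }

    nb <- stats::rpois(1L, p$family_birth_rate)
    for (b in seq_len(nb)) {
      fam_counter <- fam_counter + 1L
      born <- new_family_locus(g, sprintf("Fam%03d", fam_counter), nms[ch],
                               p, sequences, used_seeds)
      g <- rbind(g, born)
    }

    attr(g, "removed") <- NULL
    attr(g, "loss_tally") <- NULL
    rownames(g) <- NULL
    snapshots[[nms[ch]]] <- g
  }

  genomes <- snapshots[phy$tip.label]
  expression <- lapply(genomes, simulate_expression,
                       expr_base = p$expr_base,
                       expr_multiplier = p$expr_multiplier)

  unit_map <- stats::setNames(anc$anc_unit, anc$family)
  truth <- list(
    rng_seed = p$rng_seed,
    events = event_log,
    snapshots = snapshots,
    loss_tallies = loss_tallies,
    expr_multiplier = p$expr_multiplier,
    rate_multiplier = p$rate_multiplier,
    loss_prob = p$loss_prob,
    unit_map = unit_map
  )
  sim <- structure(
    list(genomes = genomes, expression = expression, tree = tree,
         truth = truth, params = p),
    class = "wgd_simulation"
  )
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}
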