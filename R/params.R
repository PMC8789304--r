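#' Simulation parameters
#'
#' Bundles every knob of the forward simulator: the layout of the ancestral
#' genome, the WGD schedule, per-subgenome loss probabilities (biased
#' fractionation), sequence-drift and expression models, and the RNG seed.
#'
#' Defaults describe a chordate-scale ancestor: 33 single-copy miRNA families
#' (genes or polycistrons) on 17 linkage groups, about a quarter of families
#' sitting inside polycistrons of mean size two, 70-nt precursors with 22-nt
#' mature arms whose seed (mature positions 2-8) never mutates, lognormal
#' expression in reads per million, and no tandem duplication.
#'
#' @param n_linkage_groups number of ancestral linkage groups (contigs).
#' @param n_families number of ancestral single-copy miRNA families.
#' @param cluster_fraction probability mass of families placed inside
#'   polycistrons (clusters of >= 2 families within 50 kb).
#' @param mean_cluster_size mean number of families per polycistron.
#' @param wgd_schedule optional list of WGD event specs (see [wgd_event()]);
#'   normally events live on the species tree instead.
#' @param loss_prob named numeric: per-locus deletion probability per
#'   post-WGD branch, keyed by subgenome label. Labels absent from the map
#'   lose nothing.
#' @param family_birth_rate expected number of new families per branch.
#' @param tandem_rate per-locus probability of a tandem duplication per
#'   branch. Default 0: tandem duplication is essentially absent from
#'   conserved miRNA repertoires.
#' @param expr_base numeric `c(meanlog, sdlog)` of the lognormal rpm model.
#' @param expr_multiplier named numeric, per-subgenome expression factor.
#' @param rate_multiplier named numeric, per-subgenome substitution-rate
#'   factor.
#' @param branch_lengths default branch length (substitutions/site on the
#'   unconstrained portion of the precursor) used when the tree carries none.
#' @param pre_len precursor length in nucleotides.
#' @param mature_len mature-arm length in nucleotides.
#' @param seed_positions 1-based positions within the mature arm that form
#'   the seed and are masked from substitution.
#' @param lg_length length (bp) available on each linkage group; placement
#'   that cannot respect the 50-kb spacing within this length is rejected.
#' @param rng_seed integer seed governing all stages of a simulation.
#' @return an object of class `sim_params` (a validated list).
#' @seealso [simulate_clade()], [simulate_ancestral_genome()]
#' @export
sim_params <- function(n_linkage_groups = 17,
                       n_families = 33,
                       cluster_fraction = 0.25,
                       mean_cluster_size = 2,
                       wgd_schedule = list(),
                       loss_prob = numeric(),
                       family_birth_rate = 0,
                       tandem_rate = 0,
                       expr_base = c(meanlog = 4, sdlog = 1),
                       expr_multiplier = numeric(),
                       rate_multiplier = numeric(),
                       branch_lengths = 0.05,
                       pre_len = 70,
                       mature_len = 22,
                       seed_positions = 2:8,
                       lg_length = 2e7,
                       rng_seed = 1L) {
  p <- list(
    n_linkage_groups = n_linkage_groups, n_families = n_families,
    cluster_fraction = cluster_fraction, mean_cluster_size = mean_cluster_size,
    wgd_schedule = wgd_schedule, loss_prob = loss_prob,
    family_birth_rate = family_birth_rate, tandem_rate = tandem_rate,
    expr_base = expr_base, expr_multiplier = expr_multiplier,
    rate_multiplier = rate_multiplier, branch_lengths = branch_lengths,
    pre_len = pre_len, mature_len = mature_len,
    seed_positions = seed_positions, lg_length = lg_length,
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (!is_count(p$n_linkage_groups, 1L)) stop("n_linkage_groups must be a positive count")
  if (!is_count(p$n_families, 1L)) stop("n_families must be a positive count")
  if (!is_prob(p$cluster_fraction)) stop("cluster_fraction must lie in [0, 1]")
  if (!is.numeric(p$mean_cluster_size) || p$mean_cluster_size < 1) {
    stop("mean_cluster_size must be >= 1")
  }
  if (!is_prob(p$loss_prob)) stop("loss_prob values must lie in [0, 1]")
  if (!is_prob(p$tandem_rate)) stop("tandem_rate must lie in [0, 1]")
  if (p$family_birth_rate < 0) stop("family_birth_rate must be >= 0")
  if (length(p$expr_multiplier) && any(p$expr_multiplier <= 0)) {
    stop("expr_multiplier values must be > 0")
  }
  if (length(p$rate_multiplier) && any(p$rate_multiplier <= 0)) {
    stop("rate_multiplier values must be > 0")
  }
  if (any(p$branch_lengths < 0)) stop("branch_lengths must be >= 0")
  if (!is_count(p$pre_len, 1L) || !is_count(p$mature_len, 1L)) {
    stop("pre_len and mature_len must be positive counts")
  }
  if (p$pre_len < 2 * p$mature_len) {
    stop("pre_len must be at least twice mature_len so both arms fit")
  }
  if (any(p$seed_positions < 1) || any(p$seed_positions > p$mature_len)) {
    stop("seed_positions must lie within the mature arm")
  }
  if (p$lg_length <= 0) stop("lg_length must be > 0")
  p
}

#' Specify a WGD event
#'
#' @param mode `"auto"` (autotetraploidy: doubling of one genome, symmetric
#'   subsequent loss) or `"allo"` (allotetraploidy: hybridization of two
#'   genomes, loss biased toward one parental subgenome).
#' @param label_map optional named list mapping each current subgenome label
#'   to the two labels its copies receive. By default the first WGD splits
#'   `none -> {1, 2}` and later WGDs append `a`/`b` (so a second round gives
#'   `1a, 2a, 1b, 2b`, matching the P1-P4 paralog convention).
#' @return a list of class `wgd_event`.
#' @export
wgd_event <- function(mode = c("auto", "allo"), label_map = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, label_map = label_map), class = "wgd_event")
}

# Default label split for one WGD given the labels currently present.
default_label_map <- function(labels) {
  out <- lapply(labels, function(l) {
    if (identical(l, "none")) c("1", "2") else paste0(l, c("a", "b"))
  })
  names(out) <- labels
  out
}
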