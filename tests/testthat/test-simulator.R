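test_that("ancestral genome layout respects counts, spacing and validation", {
  set.seed(1)
  p <- sim_params(n_families = 33, n_linkage_groups = 17)
  g <- simulate_ancestral_genome(p)
  expect_equal(nrow(g), 33)
  expect_equal(length(unique(g$family)), 33)
  expect_true(all(g$subgenome == "none"))
  expect_true(all(table(g$family) == 1))
  expect_lte(length(unique(g$contig)), 17)

  # degenerate cases
  g1 <- simulate_ancestral_genome(sim_params(n_families = 1,
                                             cluster_fraction = 0))
  expect_equal(nrow(g1), 1)
  expect_error(sim_params(n_families = 0), "n_families")
  expect_error(
    simulate_ancestral_genome(sim_params(n_families = 100,
                                         n_linkage_groups = 2,
                                         lg_length = 1e6)),
    "cannot hold"
  )
})

test_that("intra-cluster gaps stay below 50 kb and inter-unit gaps above", {
  set.seed(1)
  p <- sim_params(n_families = 100, n_linkage_groups = 10,
                  mean_cluster_size = 3, cluster_fraction = 0.5,
                  lg_length = 1e8)
  g <- simulate_ancestral_genome(p)
  # exhaustive scan of adjacent gaps per contig
  g <- g[order(g$contig, g$start), ]
  for (ct in unique(g$contig)) {
    rows <- g[g$contig == ct, ]
    if (nrow(rows) < 2) next
    gaps <- rows$start[-1] - rows$end[-nrow(rows)]
    same_unit <- rows$anc_unit[-1] == rows$anc_unit[-nrow(rows)]
    expect_true(all(gaps[same_unit] < 50000))
    expect_true(all(gaps[!same_unit] >= 50000))
  }
  # clustering recovers exactly the intended units
  cl <- cluster_loci(g)
  expect_equal(length(unique(cl$cluster_id)),
               length(unique(g$anc_unit)))
})

test_that("apply_wgd doubles loci and contigs and composes to 2^k", {
  set.seed(2)
  g <- simulate_ancestral_genome(tiny_params(n_families = 3,
                                             cluster_fraction = 0))
  g1 <- apply_wgd(g, wgd_event("auto"))
  expect_equal(nrow(g1), 6)
  expect_equal(length(unique(g1$contig)), 2 * length(unique(g$contig)))
  expect_setequal(unique(g1$subgenome), c("1", "2"))
  # copies start sequence-identical
  expect_equal(sort(table(g1$pre_seq)), sort(table(g$pre_seq)) * 2,
               ignore_attr = TRUE)

  g2 <- apply_wgd(g1, wgd_event("allo"))
  expect_equal(nrow(g2), 12)
  expect_setequal(unique(g2$subgenome), c("1a", "2a", "1b", "2b"))
  expect_equal(unname(table(g2$family)), rep(4L, 3), ignore_attr = TRUE)
  expect_equal(g2$paralog_label,
               paralog_label_for(g2$subgenome))

  g3 <- apply_wgd(g2, wgd_event("auto"))
  expect_equal(unname(table(g3$family)), rep(8L, 3), ignore_attr = TRUE)
  expect_false(any(duplicated(g3$locus_id)))
})

test_that("fractionation removes loci at the per-subgenome rate", {
  set.seed(3)
  g <- simulate_ancestral_genome(tiny_params(n_families = 10))
  expect_equal(fractionate(g, c(none = 0))[, names(g)], g)
  empty <- fractionate(g, c(none = 1))
  expect_equal(nrow(empty), 0)
  expect_equal(unname(attr(empty, "loss_tally")), nrow(g))
  expect_error(fractionate(g, c(`1a` = 0.5)), "lacks entries")

  # binomial recovery of biased loss rates: 1000 loci per subgenome
  set.seed(7)
  big <- simulate_ancestral_genome(
    sim_params(n_families = 1000, n_linkage_groups = 20, lg_length = 1e9,
               cluster_fraction = 0))
  big2 <- apply_wgd(big, wgd_event("allo"))
  big2$subgenome <- ifelse(big2$subgenome == "1", "a", "b")
  out <- fractionate(big2, c(a = 0.3, b = 0.6))
  tally <- attr(out, "loss_tally")
  sd_a <- sqrt(1000 * 0.3 * 0.7)
  sd_b <- sqrt(1000 * 0.6 * 0.4)
  expect_lt(abs(tally[["a"]] - 300), 3 * sd_a)
  expect_lt(abs(tally[["b"]] - 600), 3 * sd_b)
})

test_that("sequence drift is JC-like, rate-scaled, and seed-masked", {
  set.seed(4)
  g <- simulate_ancestral_genome(
    sim_params(n_families = 250, n_linkage_groups = 10, lg_length = 1e9,
               cluster_fraction = 0))
  g2 <- apply_wgd(g, wgd_event("allo"))
  g2$subgenome <- ifelse(g2$subgenome == "1", "2a", "2b")

  expect_identical(evolve_sequences(g2, 0), g2)

  ev <- evolve_sequences(g2, 0.05, c(`2a` = 1, `2b` = 2))
  # seed heptamer never substituted, for both arms
  expect_identical(substr(ev$mature5p, 2, 8), substr(g2$mature5p, 2, 8))
  expect_identical(substr(ev$mature3p, 2, 8), substr(g2$mature3p, 2, 8))
  # mature/pre consistency
  expect_identical(ev$mature5p, substr(ev$pre_seq, 1, 22))
  expect_identical(ev$mature3p, substr(ev$pre_seq, 49, 70))

  # p-distance ratio 2b:2a recovered within 20% of 2 (truth snapshots)
  pdist <- function(a, b) {
    mapply(function(x, y) {
      mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, a, b, USE.NAMES = FALSE)
  }
  p2a <- mean(pdist(ev$pre_seq[ev$subgenome == "2a"],
                    g2$pre_seq[g2$subgenome == "2a"]))
  p2b <- mean(pdist(ev$pre_seq[ev$subgenome == "2b"],
                    g2$pre_seq[g2$subgenome == "2b"]))
  expect_gt(p2b / p2a, 2 * 0.8)
  expect_lt(p2b / p2a, 2 * 1.2)
})

test_that("expression draws scale exactly with multipliers when noise-free", {
  set.seed(5)
  g <- simulate_ancestral_genome(tiny_params(n_families = 40))
  g1 <- apply_wgd(g, wgd_event("auto"))
  ex <- simulate_expression(g1, c(meanlog = 4, sdlog = 0),
                            c(`1` = 2, `2` = 1))
  rpm1 <- ex$rpm[g1$subgenome == "1"]
  rpm2 <- ex$rpm[g1$subgenome == "2"]
  expect_true(all(rpm1 == 2 * rpm2[1]))
  expect_true(all(rpm2 == exp(4)))

  # equal multipliers: per-subgenome medians agree within sampling error
  set.seed(6)
  big <- apply_wgd(simulate_ancestral_genome(
    sim_params(n_families = 500, n_linkage_groups = 20, lg_length = 1e9,
               cluster_fraction = 0)), wgd_event("auto"))
  ex2 <- simulate_expression(big, c(4, 1))
  m1 <- median(ex2$rpm[big$subgenome == "1"])
  m2 <- median(ex2$rpm[big$subgenome == "2"])
  expect_gt(m1 / m2, 0.8)
  expect_lt(m1 / m2, 1.25)
})

test_that("clade simulation composes events, births and conservation", {
  tr <- ingroup_tree()
  p <- tiny_params(n_families = 15,
                   loss_prob = c(`1a` = 0.2, `2a` = 0.2,
                                 `1b` = 0.5, `2b` = 0.5),
                   family_birth_rate = 1, rng_seed = 11)
  sim <- simulate_clade(tr, p)
  expect_named(sim$genomes, c("A", "B", "C", "D", "OUT"), ignore.order = TRUE)
  # ingroup leaves carry the four subgenome labels, outgroup none
  expect_setequal(
    unique(sim$genomes$A$subgenome[sim$genomes$A$node_of_origin == "root"]),
    intersect(unique(sim$genomes$A$subgenome), c("1a", "2a", "1b", "2b"))
  )
  expect_true(all(sim$genomes$OUT$subgenome == "none"))

  # conservation: leaf characters are subsets of the post-WGD ancestor's
  for (leaf in c("A", "B", "C", "D")) {
    lf <- unique(paste(sim$genomes[[leaf]]$family,
                       sim$genomes[[leaf]]$subgenome))
    anc_nodes <- c("ING", if (leaf %in% c("A", "B")) "AB" else "CD")
    for (nd in anc_nodes) {
      tru <- sim$truth$snapshots[[nd]]
      anc_chars <- unique(paste(tru$family, tru$subgenome))
      born_after <- sim$genomes[[leaf]]$node_of_origin %in%
        c(leaf, setdiff(c("AB", "CD"), nd))
      inherited <- unique(paste(sim$genomes[[leaf]]$family,
                                sim$genomes[[leaf]]$subgenome)[!born_after])
      expect_true(all(inherited %in% anc_chars))
    }
  }

  # families born after the last WGD are singletons in every leaf
  for (leaf in names(sim$genomes)) {
    g <- sim$genomes[[leaf]]
    born <- g[g$node_of_origin != "root", ]
    if (nrow(born)) expect_true(all(table(born$family) == 1))
  }
})

test_that("identical parameters and seed reproduce a simulation exactly", {
  tr <- ingroup_tree()
  p <- tiny_params(n_families = 10,
                   loss_prob = c(`1a` = 0.2, `2a` = 0.2,
                                 `1b` = 0.5, `2b` = 0.5),
                   family_birth_rate = 0.5, rng_seed = 42)
  s1 <- simulate_clade(tr, p)
  s2 <- simulate_clade(tr, p)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$truth$snapshots, s2$truth$snapshots)
})

test_that("single-leaf tree without events returns the ancestral genome", {
  tr <- read_wgd_newick(text = "(A:0.1);")
  p <- tiny_params(n_families = 8, rng_seed = 2)
  sim <- simulate_clade(tr, p, sequences = FALSE)
  set.seed(2)
  anc <- simulate_ancestral_genome(p, with_sequences = FALSE,
                                   origin_node = "n2")
  expect_equal(sim$genomes$A, anc)
})

test_that("events on the root's parent edge are rejected", {
  tr <- read_wgd_newick(text = "(A:1,B:1)root[&WGD=auto];")
  expect_error(simulate_clade(tr, tiny_params()), "root")
})
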