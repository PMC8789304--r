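test_that("Dollo places single gains and minimal losses on toy characters", {
  tr <- ingroup_tree()
  taxa <- c("A", "B", "C", "D", "OUT")
  pres <- matrix(FALSE, nrow = 5, ncol = 3,
                 dimnames = list(taxa, c("f1|none", "f2|none", "f3|none")))
  pres[, "f1|none"] <- TRUE                 # everywhere
  pres["A", "f2|none"] <- TRUE              # single leaf
  pres[c("A", "D"), "f3|none"] <- TRUE      # scattered in the ingroup
  st <- dollo_reconstruct(tr, pres)

  # present in all leaves: gained at the root, no losses
  expect_equal(unname(st$gains["f1|none"]),
               which(wgdmirna:::node_names(tr$phylo) == "root"))
  expect_true(all(st$presence[, "f1|none"]))
  expect_equal(sum(st$losses$character == "f1|none"), 0)

  # single carrier: present nowhere else
  expect_equal(sum(st$presence[, "f2|none"]), 1)
  expect_true(st$presence["A", "f2|none"])

  # A + D: gain at ING, presence on both root-ward paths, losses on B and C
  expect_equal(unname(st$gains["f3|none"]),
               which(wgdmirna:::node_names(tr$phylo) == "ING"))
  expect_true(all(st$presence[c("ING", "AB", "CD"), "f3|none"]))
  expect_false(st$presence["OUT", "f3|none"])
  expect_setequal(
    wgdmirna:::node_names(tr$phylo)[st$losses$node[st$losses$character == "f3|none"]],
    c("B", "C")
  )

  # character in no leaf is rejected
  pres0 <- cbind(pres, "f4|none" = FALSE)
  expect_error(dollo_reconstruct(tr, pres0), "absent from every leaf")
})

test_that("a subgenome slot cannot predate its WGD", {
  tr <- ingroup_tree()
  taxa <- c("A", "B", "C", "D", "OUT")
  pres <- matrix(FALSE, nrow = 5, ncol = 1,
                 dimnames = list(taxa, "f1|1a"))
  pres[c("A", "OUT"), 1] <- TRUE  # MRCA is the root, above the WGDs
  expect_error(dollo_reconstruct(tr, pres), "predates the WGD")
})

test_that("reconstruction recovers simulated ancestral repertoires exactly", {
  tr <- ingroup_tree()
  phy <- tr$phylo
  nms <- wgdmirna:::node_names(phy)
  for (s in 1:8) {
    p <- tiny_params(n_families = 20,
                     loss_prob = c(`1a` = 0.25, `2a` = 0.25,
                                   `1b` = 0.5, `2b` = 0.5),
                     family_birth_rate = 1, rng_seed = s)
    sim <- simulate_clade(tr, p, sequences = FALSE)
    pres <- leaf_presence(sim$genomes)
    org <- character_origins(sim$genomes, tr)
    st <- dollo_reconstruct(tr, pres, origins = org)
    for (nd in c("ING", "AB", "CD")) {
      tru <- sim$truth$snapshots[[nd]]
      truth_chars <- unique(paste(tru$family, tru$subgenome, sep = "|"))
      nid <- which(nms == nd)
      desc <- phy$tip.label[vapply(seq_along(phy$tip.label), function(tp) {
        wgdmirna:::is_ancestor(phy, nid, tp)
      }, logical(1))]
      retained <- colnames(pres)[colSums(pres[desc, , drop = FALSE]) > 0]
      expect_setequal(intersect(names(which(st$presence[nd, ])), retained),
                      intersect(truth_chars, retained))
    }
  }
})

test_that("LCA retention tables have consistent sums and loss-bias direction", {
  tr <- ingroup_tree()
  # zero loss: every ancestral family in the 4x row, identical columns
  p0 <- tiny_params(n_families = 16, rng_seed = 5)
  sim0 <- simulate_clade(tr, p0, sequences = FALSE)
  st0 <- dollo_reconstruct(tr, leaf_presence(sim0$genomes),
                           character_origins(sim0$genomes, tr))
  tab0 <- lca_retention_table(st0, "ING")
  expect_equal(unname(tab0["4x", ]), rep(16L, 4), ignore_attr = TRUE)
  expect_equal(sum(tab0[c("3x", "2x", "1x"), ]), 0)

  # biased allo loss: alpha columns exceed beta columns, sign from truth
  p1 <- tiny_params(n_families = 60, n_linkage_groups = 10,
                    loss_prob = c(`1a` = 0.2, `2a` = 0.2,
                                  `1b` = 0.6, `2b` = 0.6),
                    rng_seed = 6)
  sim1 <- simulate_clade(tr, p1, sequences = FALSE)
  st1 <- dollo_reconstruct(tr, leaf_presence(sim1$genomes),
                           character_origins(sim1$genomes, tr))
  tab1 <- lca_retention_table(st1, "ING")
  tot <- colSums(tab1)
  expect_gt(tot[["1a"]] + tot[["2a"]], tot[["1b"]] + tot[["2b"]])
  tru <- sim1$truth$snapshots[["ING"]]
  tru_tot <- table(factor(tru$subgenome, levels = c("1a", "2a", "1b", "2b")))
  expect_gt(tru_tot[["1a"]] + tru_tot[["2a"]], tru_tot[["1b"]] + tru_tot[["2b"]])

  # column sums always equal per-slot unit totals (programmatic invariant)
  pres_ing <- st1$presence["ING", ]
  info <- wgdmirna:::split_characters(names(pres_ing))
  for (slot in c("1a", "2a", "1b", "2b")) {
    expect_equal(unname(colSums(tab1)[slot]),
                 sum(pres_ing[info$slot == slot]))
  }

  expect_error(lca_retention_table(st1, "NOPE"), "unknown tree node")
})

test_that("origin-classed tables split pre- and post-reference units", {
  tr <- chain_tree(1)
  # family f_old present in A on both subgenomes, f_new on one
  pres <- matrix(FALSE, nrow = 2, ncol = 3,
                 dimnames = list(c("A", "B"),
                                 c("old|1", "old|2", "new|1")))
  pres["A", ] <- TRUE
  st <- dollo_reconstruct(tr, pres)
  tab <- lca_retention_table(
    st, "A", slots = c("1", "2"), rows = "origin", ref_node = "root",
    unit_origins = c(old = "root", new = "A")
  )
  expect_equal(tab["pre", "both"], 1L)
  expect_equal(tab["post", "1"], 1L)
  expect_equal(sum(tab), 2L)
})

test_that("continued losses are tallied per leaf with a per-edge variant", {
  tr <- ingroup_tree()
  # zero post-LCA loss: tallies all zero
  p0 <- tiny_params(n_families = 12, rng_seed = 7)
  sim0 <- simulate_clade(tr, p0, sequences = FALSE)
  st0 <- dollo_reconstruct(tr, leaf_presence(sim0$genomes),
                           character_origins(sim0$genomes, tr))
  l0 <- continued_loss_counts(st0, "ING", c("A", "B", "C", "D"))
  expect_equal(unname(l0), rep(0L, 4), ignore_attr = TRUE)

  # hand-built single loss: one character lost in one leaf
  taxa <- c("A", "B", "C", "D", "OUT")
  pres <- matrix(FALSE, nrow = 5, ncol = 2,
                 dimnames = list(taxa, c("f|1a", "f|1b")))
  pres[c("A", "B", "C", "D"), "f|1a"] <- TRUE
  pres[c("A", "B", "C"), "f|1b"] <- TRUE
  ing <- which(wgdmirna:::node_names(tr$phylo) == "ING")
  org <- c("f|1a" = ing, "f|1b" = ing)
  st <- dollo_reconstruct(tr, pres, origins = org)
  l1 <- continued_loss_counts(st, "ING", c("A", "B", "C", "D"))
  expect_equal(l1[["1b"]], 1L)
  expect_equal(sum(l1), 1L)
  expect_equal(attr(l1, "per_edge")[["1b"]], 1L)

  # a shared loss counts once per leaf but once per edge
  pres["C", "f|1b"] <- FALSE  # now lost in C and D (sister taxa)
  st2 <- dollo_reconstruct(tr, pres, origins = org)
  l2 <- continued_loss_counts(st2, "ING", c("A", "B", "C", "D"))
  expect_equal(l2[["1b"]], 2L)
  expect_equal(attr(l2, "per_edge")[["1b"]], 1L)

  expect_error(continued_loss_counts(st, "AB", c("C")), "not ancestral")
})

test_that("raising a slot's loss rate never raises its retention column", {
  # paired-seed monotonicity through the shared uniform draws
  for (s in 1:6) {
    base <- tiny_params(n_families = 40, n_linkage_groups = 8, rng_seed = s)
    run <- function(beta_loss) {
      set.seed(s)
      g <- simulate_ancestral_genome(base, with_sequences = FALSE)
      g <- apply_wgd(apply_wgd(g, wgd_event("auto")), wgd_event("allo"))
      g <- fractionate(g, c(`1a` = 0.2, `2a` = 0.2,
                            `1b` = beta_loss, `2b` = beta_loss))
      colSums(retention_from_loci(g))
    }
    lo <- run(0.3)
    hi <- run(0.6)
    expect_lte(hi[["1b"]], lo[["1b"]])
    expect_lte(hi[["2b"]], lo[["2b"]])
  }
})
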