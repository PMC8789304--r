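test_that("unique-mature filtering removes every sharer of a mature arm", {
  set.seed(30)
  g <- simulate_ancestral_genome(tiny_params(n_families = 10))
  # all sequences random: identity
  f <- filter_unique_mature(g)
  expect_equal(nrow(f), nrow(g))
  expect_equal(nrow(attr(f, "removed")), 0)

  # two loci sharing a 5p arm: both removed
  g2 <- g
  g2$mature5p[2] <- g2$mature5p[1]
  f2 <- filter_unique_mature(g2)
  expect_false(any(c(g2$locus_id[1:2]) %in% f2$locus_id))
  expect_setequal(attr(f2, "removed")$locus_id, g2$locus_id[1:2])

  # zero branch length after WGD: all paralog arms identical, so every
  # multi-copy family drops out while singletons born later survive
  tr <- chain_tree(2)
  p <- tiny_params(n_families = 8, family_birth_rate = 3, rng_seed = 31)
  # zero-length branches
  tr$phylo$edge.length[] <- 0
  sim <- simulate_clade(tr, p)
  gA <- sim$genomes$A
  fA <- filter_unique_mature(gA)
  multi <- names(which(table(gA$family) > 1))
  single <- names(which(table(gA$family) == 1))
  expect_true(all(!fA$family %in% multi))
  expect_setequal(fA$family, single)
})

test_that("expression summaries recover subgenome multipliers", {
  set.seed(32)
  g <- simulate_ancestral_genome(
    sim_params(n_families = 100, n_linkage_groups = 10, lg_length = 1e9),
    with_sequences = FALSE)
  g <- apply_wgd(apply_wgd(g, wgd_event("auto")), wgd_event("allo"))

  # degenerate noise: beta multiplier 0.5 gives a ratio of exactly 0.5
  ex0 <- simulate_expression(g, c(meanlog = 4, sdlog = 0),
                             c(`1a` = 1, `2a` = 1, `1b` = 0.5, `2b` = 0.5))
  s0 <- expression_by_subgenome(ex0, g)
  expect_equal(unname(s0$ratios["beta_vs_alpha"]), 0.5)
  expect_equal(unname(s0$ratios["one_vs_two"]), 1)

  # an empty side yields an undefined ratio, not an error
  gb <- g[wgdmirna:::subgenome_class(g$subgenome) %in% "alpha", ]
  sb <- expression_by_subgenome(ex0, gb, paired_only = FALSE)
  expect_true(is.na(sb$ratios["beta_vs_alpha"]))
})

test_that("expression bias test is null at proportional reads and powered", {
  set.seed(33)
  g <- simulate_ancestral_genome(
    sim_params(n_families = 100, n_linkage_groups = 10, lg_length = 1e9),
    with_sequences = FALSE)
  g <- apply_wgd(apply_wgd(g, wgd_event("auto")), wgd_event("allo"))

  ex_eq <- simulate_expression(g, c(4, 0))
  s_eq <- expression_by_subgenome(ex_eq, g)
  expect_equal(expression_bias_test(s_eq)$statistic, 0, tolerance = 1e-10)

  # alpha multiplier 2 with equal locus counts: strong rejection
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    ex <- simulate_expression(g, c(4, 1), c(`1a` = 2, `2a` = 2))
    r <- expression_bias_test(expression_by_subgenome(ex, g))
    hits <- hits + (r$p_value < 0.05)
  }
  expect_gte(hits, 19)
})

test_that("JC69 distance matches the closed form and its domain rules", {
  expect_equal(jc69_distance("ACGT", "ACGT"), 0)

  # p = 0.10 -> 0.1073 to 4 d.p.
  a <- strrep("A", 10)
  b <- paste0(strrep("A", 9), "C")
  expect_equal(round(jc69_distance(a, b), 4), 0.1073)

  # saturation at p >= 3/4
  expect_error(jc69_distance("AAAA", "CCCC"), "saturated")
  expect_error(jc69_distance("AAAA", "CCCA"), "saturated")

  # gap columns excluded pairwise
  expect_equal(jc69_distance("AC-T", "ACGT"), 0)
  expect_error(jc69_distance("AC", "ACG"), "equal length")

  # symmetry and monotonicity in p
  set.seed(34)
  xs <- sample(c("A", "C", "G", "T"), 60, TRUE)
  ys <- xs
  flip <- sample.int(60, 15)
  ys[flip] <- vapply(ys[flip],
                     function(ch) sample(setdiff(c("A", "C", "G", "T"), ch), 1),
                     "")
  x <- paste(xs, collapse = "")
  y <- paste(ys, collapse = "")
  expect_equal(jc69_distance(x, y), jc69_distance(y, x))
  p <- seq(0, 0.7, by = 0.05)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
})

test_that("consensus is column plurality with alphabetical tie-break", {
  expect_equal(consensus_sequence(c("AAC", "AAG", "AAG")), "AAG")
  # 2-2 tie at the last column: alphabetically first base wins
  expect_equal(consensus_sequence(c("AAC", "AAC", "AAG", "AAG")), "AAC")
  expect_equal(consensus_sequence(c("A", "C")), "A")
})

test_that("rate summary recovers per-subgenome rate multipliers", {
  set.seed(35)
  p <- sim_params(n_families = 60, n_linkage_groups = 10, lg_length = 1e9)
  anc <- simulate_ancestral_genome(p)
  g <- apply_wgd(apply_wgd(anc, wgd_event("auto")), wgd_event("allo"))

  # branch length zero: all divergences zero
  tab0 <- do.call(rbind, lapply(c("T1", "T2"), function(tx) {
    data.frame(taxon = tx, family = g$family, subgenome = g$subgenome,
               pre_seq = g$pre_seq, stringsAsFactors = FALSE)
  }))
  rs0 <- subgenome_rate_summary(tab0)
  expect_true(all(rs0$per_group$mean_divergence == 0))

  # 2b at twice the 2a rate: separation in every taxon
  mult <- c(`1a` = 1, `2a` = 1, `1b` = 1, `2b` = 2)
  tab <- do.call(rbind, lapply(sprintf("T%d", 1:5), function(tx) {
    e <- evolve_sequences(g, 0.05, mult)
    data.frame(taxon = tx, family = e$family, subgenome = e$subgenome,
               pre_seq = e$pre_seq, stringsAsFactors = FALSE)
  }))
  rs <- subgenome_rate_summary(tab, groups = c("2a", "2b"))
  pg <- rs$per_group
  d2a <- pg$mean_divergence[pg$subgenome == "2a"]
  d2b <- pg$mean_divergence[pg$subgenome == "2b"]
  expect_true(all(d2b > d2a))
  expect_lt(rs$anova$p_value, 0.01)

  # the F statistic agrees with the standard linear-model ANOVA
  dat <- data.frame(y = c(d2a, d2b),
                    grp = rep(c("2a", "2b"), c(length(d2a), length(d2b))))
  ref <- stats::anova(stats::lm(y ~ grp, data = dat))
  expect_equal(rs$anova$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(rs$anova$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # single-sequence families are excluded with a log entry
  tab12 <- tab[tab$taxon %in% c("T1", "T2"), ]
  solo <- tab12$family[1]
  tab_mixed <- rbind(
    tab12[!(tab12$taxon == "T1" & tab12$family == solo), ],
    tab12[tab12$taxon == "T1" & tab12$family == solo, ][1, ]
  )
  rs1 <- subgenome_rate_summary(tab_mixed, paired_only = FALSE,
                                groups = c("2a", "2b"))
  expect_true(solo %in% rs1$excluded$family[rs1$excluded$reason ==
                                              "single sequence"])
})
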