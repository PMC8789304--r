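---
title: "Methods: simulating and testing miRNA retention through whole-genome duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and testing miRNA retention through whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdmirna)
```

## The scientific problem

Whole-genome duplications (WGDs) double every gene in a genome; most of the
duplicates are subsequently lost during rediploidization. The *mode* of the
duplication leaves a signature in what survives. After **autotetraploidy**
(doubling of a single genome) losses are symmetric between the two resulting
subgenomes; after **allotetraploidy** (hybridization of two species) losses
preferentially strike one parental subgenome — *biased fractionation* or
*subgenome dominance*. A lineage that underwent an auto- and then an
allotetraploidy carries four subgenome copies, conventionally labelled
1α, 2α, 1β, 2β (ASCII `1a, 2a, 1b, 2b` everywhere in this package; 1/2 from
the first WGD, α/β from the second; the paralog labels P1–P4 map to them in
that order).

MicroRNAs are unusually clean markers for this question. They are short,
deeply conserved, essentially never tandem-duplicated, and their targeting
is determined by the **seed** (nucleotides 2–8 of the mature arm), which is
invariant among paralogs — so any retention bias between subgenomes cannot
be explained by divergent target repertoires and must reflect the genomic
origin of the locus itself. `wgdmirna` provides the full chain of machinery
to study this: a forward simulator with known truth, a paralog census, an
ancestral-repertoire reconstruction, bias tests with an auto/allo mode
classifier, and expression/substitution-rate comparisons across subgenomes.

## The generative model

`simulate_clade()` composes five elementary operations along a rooted
species tree whose edges may carry `[&WGD=auto]` / `[&WGD=allo]`
annotations:

1. **Ancestral genome** (`simulate_ancestral_genome()`): `n_families`
   single-copy miRNA families are laid out on `n_linkage_groups` linkage
   groups. A fraction `cluster_fraction` of families sits in polycistrons
   (intra-cluster gaps of 0.2–20 kb); distinct genes/polycistrons are
   spaced at least 60 kb apart so the 50-kb clustering rule recovers the
   intended units exactly. Defaults (33 families, 17 linkage groups, a
   quarter of families clustered with mean cluster size 2) describe a
   chordate-ancestor-scale repertoire.
2. **WGD** (`apply_wgd()`): every contig and locus is duplicated; labels
   split `none → 1, 2`, then `1 → 1a, 1b`, `2 → 2a, 2b`. Successive events
   compose, so a family that predates *n* WGDs has at most `2^n` slots.
3. **Fractionation** (`fractionate()`): on every post-WGD branch each locus
   is deleted independently with its subgenome's probability from
   `loss_prob`. Auto vs allo is purely a property of this map (symmetric vs
   β-biased); whole-family loss is allowed. Loss is Bernoulli per locus per
   branch — the data this emulates record outcomes, not the loss process,
   so the simplest memoryless process is used, and any decay of loss bias
   with time can be expressed through per-branch maps.
4. **Sequence drift** (`evolve_sequences()`): per unconstrained site the
   number of substitutions is Poisson(branch length × per-subgenome rate
   multiplier), each replacing the base uniformly among the three
   alternatives — a Jukes–Cantor process whose expected corrected distance
   equals the branch length. The seed positions of both mature arms are
   hard-masked, so the seed heptamer is invariant within a family across
   all taxa and paralogs. Precursors are 70 nt with 22-nt arms by default.
5. **Expression** (`simulate_expression()`): reads per million are
   lognormal(μ = 4, σ = 1 on the log scale) times a per-subgenome
   multiplier. σ = 1 (a ±7-fold central 95% range) matches the spread of
   read counts among conserved, well-expressed miRNA loci after the
   unique-mature filter; raw small-RNA data span more orders of magnitude,
   but those extremes are dominated by loci the filter removes.

Families are also born along branches (Poisson with mean
`family_birth_rate` per branch, independent of WGDs, each with a fresh
unused seed), because real miRNA innovation is not WGD-associated. Tandem
duplication is available (`tandem_rate`) but defaults to 0 — conserved
miRNA repertoires show essentially none. A single integer seed
(`rng_seed`) governs every stage; identical parameters and seed reproduce
every output byte-for-byte, and the full truth (per-node snapshots,
per-branch loss tallies, event modes, multipliers) is recorded for
validation.

What the generator does *not* emulate: assembly artifacts, unplaced
contigs, expression measurement noise beyond the lognormal, GC/rate
heterogeneity along the precursor, gene conversion between homeologs, and
chromosome fusion/fission. Passing tests therefore demonstrate correctness
of the inference machinery under a clean, Dollo-consistent history — not
robustness to curation errors in real databases.

## Census and reconstruction

`cluster_loci()` chains loci into polycistrons on each contig when the gap
(next start − previous end) is strictly below 50 kb — 50 kb being the
conventional maximal extent of a miRNA polycistron. The boundary is strict:
a gap of exactly 50,000 bp separates clusters. Strand is ignored
(polycistrons are positional units) and overlapping opposite-strand loci
count as distinct members of one cluster. The chaining provably equals the
transitive closure of the pairwise gap relation; the tests verify this
against a brute-force O(n²) oracle. `occurrence_profile()` then counts,
per family, the number of distinct genes-or-polycistrons and stratifies by
the number of WGDs between the family's node of origin and the censused
taxon; with no tandem duplication the count is bounded by `2^n`.

`dollo_reconstruct()` reconstructs ancestral repertoires for characters
"(unit, subgenome slot)" under Dollo parsimony: one gain, losses only.
The gain sits at the MRCA of the carriers, unless an annotated origin
(`character_origins()`: the later of the family's node of origin and the
WGD that created the slot) is ancestral to that MRCA, in which case the
annotation wins — this is what makes reconstruction exact at nodes where
some but not all descendants retain a character. An annotation that
conflicts with the carrier distribution is ignored with a warning. A slot
whose implied gain would predate its creating WGD is an error.
`lca_retention_table()` tabulates the reconstructed repertoire as the
classic multiplicity-by-subgenome retention table (column sums equal
per-slot totals by construction), and `continued_loss_counts()` tallies
post-LCA losses per slot — both per leaf (each descendant counts its own
losses, so a shared loss counts once per leaf) and per parsimony-placed
edge, since published per-taxon loss rows do not state which convention
they use. The counting unit is the ancestral gene-or-polycistron
(`unit_map`); per-gene counting is the default when no map is given.

## Statistics: what is tested, and how calibrated

`subgenome_bias_test()` pools the four columns into α = 1a+2a vs
β = 1b+2b (or 1 vs 2) and runs a chi-square goodness-of-fit against
equality (df = 1), matching the df = 1 statistics reported for such
comparisons in the comparative literature. `classify_wgd_mode()` calls
allotetraploidy iff that contrast rejects at `alpha_level` and names the
dominant subgenome. `continued_loss_test()` compares per-slot losses to an
expectation proportional to the LCA repertoire (df = 3), and
`expression_bias_test()` compares pooled α vs β total reads to locus-count
expectations.

One calibration subtlety is worth stating precisely. The goodness-of-fit
χ² treats the pooled counts as a multinomial allocation of a fixed total.
Under the generator, retention events are independent Bernoulli trials per
locus, so the pooled retained counts are binomials whose variance is
(1 − q) times the multinomial value, q being the per-slot survival
probability. The test is therefore *conservative* for retention data —
exactly calibrated only in the sparse-retention (Poisson) limit, with
effective level `1 - pchisq(qchisq(0.95, 1) / (1 - q), 1)`. The acceptance
suite accordingly checks the nominal 5% level under heavy fractionation
(loss 0.95 per branch, effective level 0.044) and separately asserts
conservativeness at moderate loss. The same reasoning applies to the
four-category loss test, whose variance match is exact at loss probability
0.25. None of this affects the allo calls, which reject at p-values many
orders below any of these levels; it only means "auto" calls are, if
anything, slightly over-cautious claims of symmetry.

Because published headline χ² values for such data (e.g. 95.6 or 32.0 with
their df) derive from per-taxon supplementary tables rather than the
pooled main-text counts, they are not recomputable from retention tables
alone under either the pooled or the contingency convention; this package
implements the pooled goodness-of-fit as primary and makes no attempt to
reverse-engineer those inputs.

## Expression and substitution rates

`filter_unique_mature()` removes every locus whose 5p or 3p mature
sequence occurs more than once in the taxon (all sharers go, since merged
read counts cannot be attributed). `expression_by_subgenome()` then
summarizes rpm per slot and pooled side over families with at least one α
and one β paralog; both per-taxon and pooled-across-taxa summaries are
emitted by the pipeline because a median can reasonably be taken either
way. Ratios are undefined (NA), not errors, when a side is empty.

For rates, `subgenome_rate_summary()` computes each paralog's JC69
distance (`d = -(3/4) ln(1 - 4p/3)`) from its family's column-plurality
consensus (alphabetical tie-break, gaps excluded pairwise; saturation
p ≥ 3/4 is excluded with a log entry), averages per taxon × subgenome, and
contrasts two groups (default 2a vs 2b) with a one-way ANOVA whose p-value
comes from the F survival function. JC69-against-consensus slightly
compresses absolute divergences (the consensus is not the true ancestor),
but preserves ordering and ratios, which is what the subgenome contrast
needs; a full GTR+Γ ML treatment is deliberately out of scope. The
degenerate all-identical case yields F = 0, p = 1 rather than 0/0.

## Problem sizes and numerical choices

The test suite validates at deliberately modest scales chosen as the
smallest sizes at which every effect is unambiguous: 20–33 families on
5–17 linkage groups for exactness checks; 50 seeds for Dollo exactness;
1,000 / 200 seeds at 200 / 300 families for classifier calibration and
power; 1,000 loci for the expression-ratio recovery; 100 seeds of 13 taxa
× 170 families (the scale of published multi-taxon rate comparisons) for
the rate contrast. Coordinates are 0-based half-open (BED convention)
everywhere. Cluster ids, consensus tie-breaks and traversal orders are
deterministic, so every result is reproducible from the seed alone.

## Worked example

```{r example, eval = FALSE}
tree <- read_wgd_newick(text = paste0(
  "(((A:0.05,B:0.05)AB:0.05,(C:0.05,D:0.05)CD:0.05)",
  "ING[&WGD=auto][&WGD=allo]:0.05,OUT:0.2)root;"))
params <- sim_params(
  n_families = 60, n_linkage_groups = 10, lg_length = 1e8,
  loss_prob = c(`1a` = 0.2, `2a` = 0.2, `1b` = 0.6, `2b` = 0.6),
  expr_multiplier = c(`1a` = 2, `2a` = 2, `1b` = 1, `2b` = 1),
  rate_multiplier = c(`2a` = 1, `2b` = 2), rng_seed = 6)
sim <- simulate_clade(tree, params)

pres <- leaf_presence(sim$genomes)
state <- dollo_reconstruct(tree, pres, character_origins(sim$genomes, tree))
tab <- lca_retention_table(state, "ING")
classify_wgd_mode(tab)
```

Or run every stage from one configuration: `run_pipeline(list(seed = 1),
out_dir = "run1")` writes clusters, occurrence histograms, ancestral
states, the retention table, loss tallies, the dominance report and the
expression/rate summaries, each with a provenance header.

## Known limitations

Dollo reconstruction is exact only for Dollo-consistent histories; gene
conversion or re-gain would be misread as late gains. The slot-to-WGD
mapping assumes nested WGDs along one lineage per slot depth (parallel
WGDs in different lineages with equal depth are not disambiguated). The
classifier tests only the contrast it is given; nested mode inference for
more than two WGDs requires calling it per event. Real-data mode consumes
pre-exported locus tables; no database client is included.
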