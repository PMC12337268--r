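---
title: "pavnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pavnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Rhizobia vary enormously in the benefit they confer on their legume host
("partner quality"): inoculating one host genotype with different wild
*Sinorhizobium* strains can change shoot biomass several-fold. Two layers of
symbiont variation plausibly drive this: which genes a strain *carries*
(presence–absence variation, PAV, concentrated on the symbiotic megaplasmid
pSymA), and how host and symbiont genes are *expressed* together inside the
nodule. `pavnet` implements a desk-scale, fully testable version of the
analysis chain that connects these layers: dual RNA-seq counts from nodules
→ expression-based PAV calls → syntenic gene clusters associated with host
biomass → pangenome frequency classes → weighted coexpression networks for
both organisms → module–trait and cross-kingdom module–module association.

Because the real inputs are large external sequencing deposits, the package
ships a synthetic-data generator that emulates the study design (20 strains
× 4 nodule RNA-seq replicates, a multipartite genome of ~6,000 symbiont
genes, ~5,000 host genes) with a *recorded ground truth*, so every stage of
the pipeline can be validated end to end on data whose answer is known.

# Presence–absence calling from expression

For each strain, the count floor (default 10, the same floor used for the
expressed/not-expressed classification) is converted into a CPM cutoff by
the median library size of that strain's replicates, in the spirit of
edgeR's `filterByExpr`. A gene is called **absent** in a strain when its CPM
falls below the cutoff in at least `ceil(0.75 * n_reps)` replicates (3 of 4
in the default design) and **present** otherwise. The 3-of-4 rule tolerates
one noisy replicate in either direction.

Candidate PAV genes are those with an on/off pattern across strains:
present in at least 3 and at most `n_strains - 3` strains (3–17 of 20).
Genes outside this window are either effectively core or too rare to test.
Candidates are then correlated with strain-mean shoot biomass using the
point-biserial (Pearson) correlation of the 0/1 presence vector, with
p-values from the t transform and Benjamini–Hochberg FDR across the tested
set; the default significance rule is |r| > 0.5 and FDR < 0.15. A config
switch (`presence_correlation = "logcpm"`) correlates strain-mean logCPM
instead, for users who prefer a dosage-style test; binary presence is the
default because PAV itself is the object of inference.

Expression-based calls are optionally confirmed against genome assemblies:
a seed-and-extend nucleotide search (exact 31-mers on both strands, chained
on the dominant diagonal, then a local alignment of the query against the
spanned window) reports the best hit's identity and coverage, and a gene is
sequence-present at ≥ 98% identity and ≥ 98% query coverage. Only genes
whose expression and sequence calls agree in *every* strain survive the
confirmation (the 100%-agreement rule). Ambiguous IUPAC bases count as
mismatches. The alignment kernel is Biostrings' Smith–Waterman; tests
compare the seeded result against a seeding-free full-DP alignment of the
whole replicon and require identity agreement within 0.005.

# Syntenic clusters and the pangenome partition

Confirmed candidates are grouped by coordinates in a single declared
reference annotation: genes on the same replicon chain into one cluster
while the inter-feature gap (`next start − current end − 1`) is at most
3 kb; chains of ≥ 2 genes are clusters. We measure the gap between feature
bounds (not start-to-start) and treat 3,000 bp as inclusive; both choices
are exposed in the configuration. Cluster presence in a strain defaults to
"all members present", with a fraction rule available. Cluster–trait
effects are tested by a two-sided pooled-variance t test on strain-mean
biomass between carrier and non-carrier strains (Welch by config).

Pangenome gene groups are partitioned by presence fraction f across
strains: **core** (f > 0.99), **shell** (0.15 ≤ f ≤ 0.95), **cloud**
(f < 0.15). The printed bins leave (0.95, 0.99] undefined; we assign it to
shell — the conservative choice, since it avoids inflating the core — and
report how many groups the rule touched (`n_gap_shell`).

# Coexpression networks

Networks are built per organism from strain means of logCPM
(`log2((count + 0.5) / (lib + 1) * 1e6)`, averaged over replicates on the
log scale). Genes with median raw count < 10 across all samples are
excluded; the host network uses the 5,000 most variable genes (ties broken
lexicographically for determinism). Adjacency is `|cor|^beta` (unsigned by
default; a signed option exists), with beta chosen as the smallest power on
the grid 1–12 whose connectivity distribution reaches a signed scale-free
fit R² ≥ 0.8, falling back to the argmax when none does — planted-block
data is not scale-free, so the fallback is the common path on simulated
inputs, and it is deterministic. Topological overlap is
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`.

Modules come from average-linkage clustering of `1 − TOM`, cut at the 0.99
quantile of merge heights; clusters below 10 genes (the smallest module
size we aim to resolve) are left unassigned. Module eigengenes are the
first left singular vector of the z-scored member-gene matrix over strains
(unit norm, sign-oriented toward the members), and modules whose eigengenes
correlate above 0.75 (signed, so anti-correlated modules never merge) are
iteratively merged to a fixpoint. The static quantile cut replaces WGCNA's
Dynamic Hybrid algorithm deliberately: it is fully specified, parameterized
by one number, and sufficient for planted-structure recovery; the
cut-deep-then-merge combination supplies the robustness that dynamic
cutting otherwise provides.

One behavior of the unsigned default is worth knowing: two planted modules
whose strain factors are strongly *anti*-correlated (e.g. both coupled to
the partner-quality axis with opposite sign) are recovered as a single
module, because `|cor|` erases the sign. This is the textbook
signed-vs-unsigned distinction, not an artifact; the signed option
separates them.

Module–trait association is the Pearson correlation between eigengenes and
strain-mean traits with raw p-values (|r| > 0.6, P < 0.05 by default), as
is conventional for module–trait heatmaps; a flag adds BH adjustment.
Cross-kingdom edges are eigengene correlations between the host and
symbiont networks over identically ordered strains (|r| > 0.7), with strain
order mismatches a hard error rather than a silent realignment. Category
enrichment is the upper-tail hypergeometric test against the network gene
universe (the post-prefilter set, matching common WGCNA practice), BH
across all module × category pairs.

# The synthetic-data generator

`sim_params()` fixes the study conditions; `simulate_dataset()` draws a
pangenome, counts, phenotype, and (on request) per-strain assemblies, all
from one seed, and asserts that expression truth, sequence truth and the
recorded ground truth never contradict each other.

**Pangenome.** Per replicon, genes are split into core/shell/cloud in
deterministic proportions calibrated to the replicon profiles (chromosome
56.1% core, pSymA 19.9%, pSymB 67.9%); core genes have frequency 1, shell
frequencies are Uniform(0.15, 0.95), cloud Uniform(1/n, 0.15). Presence is
Bernoulli per strain (a gene drawn absent everywhere is forced into one
random strain so every emitted group is observed). Because a shell gene can
by chance be present in all strains, the realized core fraction sits
slightly above the target (~1 point on pSymA) — an inherent property of the
frequency mixture, reported as-is. An accessory plasmid is carried by 8 of
20 strains. Gene lengths are LogNormal(log 900, 0.3) bp; gaps inside
planted clusters are 50–500 bp and between layout units 4–20 kb, so the
3-kb rule separates background genes by construction.

**The partner-quality axis.** A latent strain factor u ~ N(0,1) organizes
all trait-linked structure, mirroring the real system where cluster PAV and
module expression align on the same biomass axis. Trait-linked planted
clusters (default: one positive and one negative, 4 and 10 genes, both at
frequency 0.5 on pSymA) take their presence patterns by thresholding ±u
plus noise (SD 0.3), so carrier sets of opposite-effect clusters are
anti-correlated — as observed for the high- and low-quality-associated
clusters in nodule data. Trait-coupled modules draw their strain factors as
ρ·u + √(1−ρ²)·w. An additive model with mutually independent cluster
patterns and module factors cannot make two clusters and two modules all
clear their correlation cuts simultaneously (the squared trait correlations
of independent regressors cannot exceed 1); the shared axis is what makes
the published effect sizes jointly possible, and it is the biologically
faithful choice.

**Modules.** Symbiont modules partition the true core genes (8 modules,
30% down to 3% of the set); host modules partition all host genes (5
modules). Module factors beyond their planted coupling to u are made
exactly orthonormal (joint Gram–Schmidt over both organisms), so planted
modules are identifiable at n = 20 strains — with only 20 observations,
independently drawn factors can correlate at 0.5 by chance, which would
make module recovery a property of the seed rather than of the method.
Per-gene loadings are 0.5 log2-units jittered by ±30%, with signs balanced
within each module: a module with all-positive loadings shifts the total
library size of strains where it is active, which leaks anti-correlation
into every other gene through CPM normalization. Balanced signs remove the
compositional artifact (and unsigned networks group both halves anyway).

**Counts.** `count ~ NB(mean = lib · 1e-6 · cpm_g · 2^(loading · factor),
size = 1/0.1)` with baseline CPM LogNormal(log 150, 1) for the symbiont and
LogNormal(log 80, 1) for the host; libraries Uniform(2–8M) and (8–20M)
reads. Absent genes have mean `δ · lib · 1e-6` with δ = 0 by default (δ > 0
stress-tests the absence caller).

**Phenotype.** Strain-mean shoot biomass is `μ0 + Σ effect_c · presence_cs
+ Σ γ_m · factor_ms + ε`, with the genetic part standardized to 85% of the
target variance and ε filling the rest; the target CV is 0.60 around a
0.26 g mean, matching the observed strain-level variability. Values below
0.01 g are clipped with a warning (about one strain per draw; real
low-quality strains approach zero biomass). Correlated secondary traits
(root biomass, chlorophyll, height, leaf number, and a negatively
correlated nodule number) populate the trait-correlation matrix, and a
10-replicate table (within-strain CV 0.25) supports the strain ANOVA.

**Assemblies.** Each gene gets an i.i.d. A/C/G/T reference sequence;
strain replicons concatenate random spacers with the genes truly present,
each copy mutated at 0.5% per site and reverse-complemented with
probability 0.1. Absent genes leave no copy, so the 98%/98% rule and the
100%-agreement filter have a planted answer. Assemblies are generated on
demand — at the full 6,000-gene scale with multi-kb spacers they would be
~1 Gb of sequence, which nothing downstream needs; sequence-confirmation
behavior is validated at alignment scale instead.

# What the simulation does and does not show

Passing the planted-recovery tests shows the pipeline's rules — the
replicate absence rule, the on/off window, the correlation cuts, the 3-kb
chaining, TOM clustering — recover structure of the planted kind at the
study's sample sizes and noise levels. The generator does **not** emulate:
phylogenetic relatedness among strains (presence patterns are exchangeable;
the tree-based mobility analysis is out of scope), host–symbiont read
cross-mapping, ortholog-inference errors in the gene-group table,
GC/length-dependent coverage bias, or scale-free degree structure. Module
counts on real nodule data (31 in the reference analysis) are therefore a
shape target, not a reproduction target — the exact WGCNA parameters behind
that count are not recoverable from the publication.

# Numerical choices and degenerate inputs

* logCPM prior 0.5; the library-size denominator adds 2·prior.
* Strain means average per-sample logCPM (log first, then average).
* PCA centers genes, does not scale by default; both are flags. A
  zero-variance decomposition reports 0 explained rather than NaN.
* Constant presence vectors and constant traits yield degenerate records
  flagged and excluded from FDR, never silent NAs.
* Variance-ranking ties break lexicographically by gene id.
* The among-strain variance component uses the method of moments
  `(MS_strain − MS_error)/n_reps`, floored at 0 — closed-form and checkable
  by hand, unlike REML.
* All randomness flows from a single integer seed; the analysis stages
  contain no randomness at all, so a rerun on the same inputs is
  bit-identical.

# Problem sizes used in the test-suite

Unit tests run a ~10×-reduced simulation (590 symbiont genes, 400 host
genes, same 20 × 4 design and class profiles). The acceptance checks run
one full-scale default simulation (~6,000 symbiont and 5,000 host genes)
through the whole pipeline, 50 reduced passes for the module-flagging rate
(using planted memberships, since re-clustering 50 networks adds nothing
over the single-run ARI check), 10 pangenome draws at 22 strains for the
replicon calibration, and 1,000-replicate permutation nulls for the
type-I-error checks. These sizes were chosen so the whole suite stays
comfortably interactive while every statistical claim retains enough
replication to be meaningful.
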