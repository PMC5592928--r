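---
title: "Methods: TF-family characterization in a polyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-family characterization in a polyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`polynac` chains seven stages: a synthetic data generator, TF annotation
by evidence union, homeolog triad construction, NAC-domain phylogeny with
group propagation, CTD motif scanning, coexpression module detection, and
module-level term enrichment. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic validation demonstrates.

## The synthetic generator

`sim_config()` / `simulate_dataset()` emulate a hexaploid genome organized
in A/B/D homeolog triads together with two diploid relatives (`REF1`,
`REF2`) and an expression compendium.

**Triads and retention.** Each of `n_triads` triads draws a retention
class from `retention_probs`, by default `(0.58, 0.33, 0.09)` for complete
(1:1:1), single-loss (1:1:0) and other — the genome-wide pattern observed
for NAC triads in hexaploid wheat. The "other" class is realized half as a
tandem duplication in one subgenome and half as loss of two homeologs;
both configurations fall outside complete/single-loss by construction, so
the planted class always equals the classified one. Homeologs diverge by
independent point substitution at `within_divergence` (default 0.02 per
site); diploid orthologs at `diploid_divergence` (0.05). Substitutions
always change the residue, so the rates are realized divergences.

**NAC genes.** A NAC gene is an N-terminal domain — a mutated copy of a
fixed, built-in 150-residue consensus standing in for subdomains A–E —
followed by a random-background C-terminal domain (`ctd_length = 120`)
carrying the motifs planted for its phylogenetic group, verbatim at
recorded positions. Groups a–h each descend from their own ancestor
(`group_divergence = 0.15` from the consensus) with within-group
divergence 0.03; the 5× separation between within- and between-group
distances is what makes reference-guided group propagation well-posed,
mirroring the clear group structure of the real family. The consensus and
the 16-motif table (13 motif groups; ii, iv and ix carry two motifs each)
are synthetic stand-ins, clearly not the published sequences, and both are
overridable through the config.

**Expression.** Gene-level log2 expression is
`mu + loading * factor + noise`: each module has an i.i.d. standard-normal
latent factor per sample, `loading / sd(noise) = module_snr` (noise sd
fixed at 0.5 log2 units), and values are exponentiated, giving strictly
positive, heavy-tailed tpm-like values (log-normal noise — the simplest
model with both properties of real RNA-seq tpm). Genes split into 1–3
transcripts with flat-Dirichlet proportions (the symmetric choice, since
nothing constrains it), so transcript tpms sum exactly to the gene value.
A `low_expr_fraction` of genes is emitted at mean log2 tpm −4 with no
module coupling, guaranteeing they fall below the 0.5-tpm/3-sample filter.
Module membership is sampled so the expected NAC share among
module-assigned TFs matches `nac_module_enrichment` (default 0.08, the
average NAC share of module TFs in the study this package's defaults
emulate). The default 308 samples in 15 studies match that compendium's
shape; tests and the acceptance script use 30–60 samples, which is
sufficient for the correlation estimates at the planted signal-to-noise
ratios.

**What the generator does not emulate:** indels (the truth alignment is
substitution-only, plus optional N-terminal truncations), GC/codon
structure (no nucleotide level at all), mapping noise, batch effects
between studies, and correlated module factors. Passing the recovery tests
therefore shows the algorithms are correct under clean conditions, not
that they are robust to alignment error or confounded expression data.

## TF annotation

Candidates come from three streams: Smith–Waterman similarity to known TF
peptides (BLOSUM62, gap open 11 / extend 1 — classical blastp settings;
exact dynamic programming is affordable at desk scale, so no heuristic
seeding), ortholog tables, and domain content. The union is then filtered:
a gene is called a TF only when the family rule table assigns it to
exactly one family (required domain alternatives satisfied, no forbidden
domain present). Similarity- or ortholog-only candidates failing the rules
are dropped rather than kept as "family unknown" — this mirrors the final
prediction-server-style re-check such pipelines apply. Genes satisfying
several families are reported as `ambiguous` (families sorted
alphabetically) and excluded from family counts; the literature is silent
on this case, so ambiguity is surfaced rather than resolved.

Ranking ties at the `max_targets = 10` cutoff break by lexicographic gene
id, for determinism. The family-size ratio test is a 1-df goodness-of-fit
of `(n_polyploid, n_diploid)` against `(r/(r+1), 1/(r+1))`, default
`r = 3` for a hexaploid/diploid comparison, without continuity correction;
at counts (13, 10) it gives χ² ≈ 4.19, p ≈ 0.041.

## Homeology

Reciprocal best hits require each gene to be the other's *unique* best
match; a tied best score disqualifies the gene, because "best" is
undefined under ties and determinism is required. Triads are connected
components of the homeolog graph — a deliberate choice: component
semantics is the simplest rule that handles duplications (two same-
subgenome genes stay in one triad, classified `other`) and is the
package's own definition, since multi-copy grouping has no canonical
definition. Retention classification is total: every non-empty slot
configuration maps to exactly one of the three classes.

## NAC phylogeny and group propagation

The alignment is trimmed to columns with ≥ 10 % occupancy (inclusive) and
all-gap rows dropped. Distances are p-distances with *pairwise* deletion —
listwise deletion would discard the sparse columns the 10 % trim
deliberately retains; pairs sharing no columns get distance 1 with a
warning. The tree is Saitou–Nei neighbor joining with negative branch
estimates clamped to zero. NJ on uncorrected p-distances is a deliberate
simplification: it recovers additive trees exactly (verified against all
topologies up to 6 taxa) and the synthetic divergences are far from
saturation; maximum-likelihood inference, model selection and bootstrap
support are out of scope.

**Group propagation.** After midpoint rooting (displayed NAC trees are
conventionally rooted but no rooting rule is canonical, and midpoint needs
no outgroup), each unlabeled leaf takes the group of the innermost
enclosing clade containing labeled reference leaves, provided those labels
are unanimous. The conflict rule guards against misplaced references: if
the next enclosing clade (below the root) that adds labeled leaves is
unanimously labeled with a *different* group and carries at least as many
labels as the inner clade, the query is left unassigned. This
operationalizes "the reference disagrees with the rest of the clade" —
informal in the source material — as one consistent reading; it is
isolated in `propagate_groups()` so alternatives can be swapped. The
root-level exception keeps sibling groups at the top of the tree from
vetoing each other. On conflict-free synthetic trees the rule assigns
100 % of polyploid NACs correctly; planting one mislabeled reference
inside another group's clade leaves its polyploid sisters unassigned.

## CTD motif scanning

IUPAC patterns become position probability matrices: allowed residues
share `1 − ε` equally, disallowed residues share `ε = 0.01` (avoiding
−∞ log-odds); scores are log2 odds against background frequencies counted
over the whole proteome with a pseudocount of 1 per amino acid. Scanning
is restricted to the CTD — residues strictly after the NAC domain end.

Per-window p-values are exact: position scores are discretized to
1/1000-bit bins (bounded table size at FIMO-like precision) and the null
score distribution under i.i.d. background is built by convolution; the
observed window score is computed with the same integers, so ties land on
the same side of the threshold. The DP tail equals exhaustive word
enumeration (verified for widths ≤ 3 over the full alphabet).

**q-value universe.** Presence requires `p < 0.05` *and* BH `q < 0.05`,
both strict. q-values are computed per motif across **all scanned
windows** of all genes (a gene inherits the q of its best window), which
is FIMO's correction universe. Correcting instead over per-gene best-hit
p-values is offered (`q_universe = "genes"`) but not default: a best of
~100 windows is stochastically far below uniform, so gene-level BH at 0.05
would flag nearly every gene and destroy the false-presence guarantee.
With the window universe, planted motifs are recovered at ≥ 99 %
sensitivity with ≤ 5 % false presence on the synthetic data.

Group membership combines motifs as declared: groups ii and iv accept any
of their motifs, group ix requires both (its motifs having historically
been split into separate groups x and xi, a single one is not diagnostic).

## Coexpression

Correlations are computed on `log2(tpm + 1)` — unstated upstream, chosen
because variance stabilization before correlation is standard practice and
the offset keeps zeros finite; Pearson is the default, biweight
midcorrelation (without outlier-fraction capping) optional. Adjacency is
signed hybrid, `max(cor, 0)^β`; β is the smallest candidate whose
scale-free fit R² (squared correlation of log-frequency vs log-mean
connectivity over 10 bins) reaches 0.8, falling back to the argmax —
planted-module data is not scale-free, so the fallback is the common path
and the choice is deterministic either way.

Module detection is average-linkage clustering on `1 − TOM` with a
*static* cut (default height 0.99) instead of a dynamic hybrid cut: the
validation target is planted-module recovery, not bit-compatibility with
any particular dendrogram-splitting heuristic, and the static cut is
transparent and deterministic. Clusters under `min_size = 30` go to module
0; modules whose eigengenes (first principal component of standardized
module expression, sign-aligned to the mean profile — a PC's sign being
arbitrary) correlate above `1 − 0.15` merge iteratively; final modules are
renumbered by decreasing size with ties broken by smallest gene id. At
signal-to-noise 3 with five planted modules of ~200 genes the assignment
matches truth at adjusted Rand index > 0.8 (in practice 1.0).

The NAC overrepresentation test compares a module's (NAC, non-NAC TF)
split against the global NAC fraction among module-assigned TFs by 1-df
χ² without continuity correction (consistent with the ratio test), BH
adjusted across modules; modules without TFs are skipped with `p = NA`.

## Enrichment

Per module, each term's p-value is the exact hypergeometric upper tail
(equivalently one-sided Fisher), with BH control across the terms of the
module and a strict 0.05 cut. The default universe is all module-assigned
genes, not the whole proteome — enrichment "within modules" is most
naturally benchmarked against genes that could have been co-assigned — and
the universe is an explicit argument. GO-graph propagation and
length-bias weighting are out of scope.

## Degenerate inputs and edge policies

* Empty sequences score 0 in local alignment; invalid residues are errors.
* CTDs shorter than a motif: score `NA`, `p = 1`, never present.
* Constant genes: min-max normalization maps them to zeros; correlation 0
  with a warning.
* Empty triads (all slots empty) are invalid; empty groups are reported as
  missing, not 0/0.
* All retention/normalization/trim operations are idempotent where the
  contract implies it, and all stochastic stages are reproducible from
  `sim_config(seed = ...)` alone.

## Problem sizes

The test suite and `scripts/acceptance.R` use 60–80 triads (≈ 150–200
polyploid genes) for annotation, phylogeny and motif stages, 2000 triads
for retention-fraction convergence, 600 triads × 60 samples for module
recovery, and 200 replicates for the overrepresentation power estimate —
sizes at which every stage's output is exactly checkable against planted
truth while the whole validation remains a desk-scale computation.

## Known limitations

* The similarity stream ranks by raw Smith–Waterman score; no e-value
  model, so scores are comparable only within a query.
* Homeology ignores synteny; connected components can chain distinct loci
  through shared best hits in adversarial inputs.
* The phylogeny stage consumes an existing alignment; it does not align.
* The group-propagation conflict rule is one consistent reading of an
  informally stated criterion; alternatives plug into the same interface.
* Static tree-cutting can split elongated modules that a dynamic cut
  would keep together; the eigengene merge recovers most such splits but
  is not guaranteed to.
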