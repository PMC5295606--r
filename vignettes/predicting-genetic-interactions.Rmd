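---
title: "Predicting genetic interactions from functional gene modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting genetic interactions from functional gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgi)
```

## The model

Experimentally mapping genetic interactions — gene pairs whose combined
perturbation produces a phenotype markedly different from what the single
perturbations predict (synthetic lethality, phenotypic enhancement and
suppression, dosage effects, ...) — scales quadratically in the number of
genes and is far from complete outside *S. cerevisiae*. `netgi`
operationalises a guilt-by-association hypothesis: genes that participate
in the same biological process tend to share genetic interaction partners.
If the known partners of a query gene cluster tightly in a functional gene
network, the other members of that cluster are credible novel partners.

The inputs are a weighted, undirected functional gene network whose edge
weights are log likelihood scores (LLS) of shared function, and a table of
known genetic interactions of one class. A query gene $X$ together with
its known partners $P = \{p_1,\dots,p_k\}$ is a *seed set*. Every gene $g$
in the network receives the score

$$ s(g) = \sum_{p \in P} \mathrm{LLS}(g, p), $$

with $\mathrm{LLS}(g,p) = 0$ when no edge exists. Because the network has
no self-edges, $s(p_i)$ omits the term $\mathrm{LLS}(p_i,p_i)$: each
partner is scored only by its connectivity to the *other* partners, which
makes the ranking an implicit leave-one-out cross-validation. Pairing the
score vector with the 0/1 label vector marking the true partners yields an
ROC curve; its area (AUC) measures how tightly the partners cluster, and
therefore how predictive the seed set is. Seed sets with AUC $\ge 0.9$
are treated as highly predictive, and their top-scoring unlabelled genes
are reported as ranked candidate partners (`rank_candidates()`).

Two companion analyses complete the picture. First, enrichment of
genetic interactions inside protein complexes: for a complex with $m$
members in the analysis universe, the number of interacting member pairs
$k$ among the $n = \binom{m}{2}$ possible pairs is compared with a
binomial null $X \sim \mathrm{Bin}(n, p)$, where $p$ is the proportion of
all possible universe gene pairs known to interact; the p-value is the
exact upper tail $P(X \ge k)$, with Benjamini–Hochberg control at FDR 5%
across complexes. Second, a withholding simulation: known interactions
are progressively removed — by interaction degree of their endpoints or
uniformly at random — and the number of significantly enriched complexes
is recorded at each step, quantifying how much interaction knowledge the
enrichment signal actually needs.

## Key parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `min_partners` | 2 | `filter_policy()` | seed sets backed by a single interacting pair carry no cross-validation signal and are dropped |
| `min_auc` | 0.9 | `rank_candidates()`, `run_config()` | AUC gate for calling a seed set highly predictive |
| `fdr` | 0.05 | `enrich_complexes()` | BH false-discovery level for complex enrichment |
| `lls_cutoff` | 3.0 | `extract_display_cluster()` | only edges with LLS above this are displayed |
| `min_links` | 2 | `extract_display_cluster()` | a non-partner gene is displayed only with at least this many supra-cutoff partner links |
| `year_cutoff` | off | `filter_policy()` | excludes records published before the cutoff, for networks built from pre-cutoff evidence (the yeast protocol uses 2006) |
| `exclude_pairs_in_network` | on | `filter_policy()` | drops seed–partner pairs that are themselves network edges (circularity guard) |

All quantities are dimensionless; LLS weights are log likelihood scores
on whatever base the source network uses — the AUC is rank-based and
invariant to any strictly increasing rescaling of the weights.

## Numerical and design choices

**Tie handling.** `roc_auc()` is the Mann–Whitney statistic with
midranks: the probability that a random positive outscores a random
negative, ties counting ½. Summed-LLS scores tie often (most genes score
exactly 0), and midranks make a signal-free seed set score exactly 0.5,
matching the reading of AUC ≈ 0.5 as "no better than random". A
trapezoidal ROC integral agrees with this choice up to tie interpolation.

**The seed gene itself.** When the query gene happens to be a network
node it is removed from both vectors rather than scored as a negative
(`exclude_seed = TRUE` in `evaluate_seed_set()`): it is the one gene that
is definitionally an interactor. The flag is exposed for sensitivity
analysis.

**Zero-score genes** are retained as negatives. Dropping them would
shrink the negative set to the functional neighbourhood of the partners
and inflate every AUC; random AUCs are not an artifact of edge-free
genes.

**Candidates.** Only label-0 genes with strictly positive score are
eligible (a zero score means no functional evidence at all); ordering is
score-descending with gene-id tie-breaks, so candidate lists are
byte-reproducible. Scores are reported raw, plus a derived per-seed
percentile column for cross-seed comparison.

**Exact binomial tail.** Complexes are small, so the tail is computed
exactly (via the incomplete-beta-backed `pbinom`), never by normal
approximation. $P(X \ge 0) = 1$ identically, so a complex with no
internal interactions is never called enriched.

**The enrichment universe** (which genes define "all possible pairs")
changes $p$ materially and is therefore an explicit, logged parameter:
the default is the union of complex-catalog and interaction genes
(`"catalog"`), with `"network"` or an explicit gene list available.

**Withholding.** Degrees for degree-based withholding are computed once
on the full interaction set: interaction degree is a property of the
original data, and a gene's hub status should not change as pairs are
removed. The background rate $p$ is recomputed on each reduced set —
the simulation pretends the withheld pairs are unknown — which also
guarantees the curve ends at zero significant complexes under full
withholding; the fixed-$p$ alternative sits behind
`recompute_background = FALSE` and its state is recorded in the output
attributes. The universe stays fixed across points: the hypothetical is
"fewer known interactions", not "fewer genes". Random-mode points are
independent seeded draws (20 replicates by default) reported as
mean/min/max.

**Duplicate records.** Duplicate network edges keep the maximum weight
(with a warning on conflict); duplicate interaction records keep the
earliest publication year, so a year-based circularity filter excludes a
pair whenever *any* report of it predates the cutoff. Interaction-class
labels match case-insensitively and the vocabulary is open — nothing is
hard-coded to BioGRID's class names, though the default column map reads
BioGRID TAB 2.0 headers.

## What the synthetic worlds emulate

`world_spec()` / `generate_world()` build benchmark worlds in which every
downstream claim has a known truth: disjoint functional modules rendered
as complete cliques at `within_module_lls = 4.0` over an
Erdős–Rényi background (`background_edge_prob = 0.01` at
`background_lls = 0.5`, deliberately straddling the 3.0 display cutoff);
coherent seed genes whose partners come from a single module, and control
seeds drawing partners uniformly; protein complexes that either carry a
planted internal interaction rate (0.5) or only the genome-wide
background rate (0.005). The default world has 500 genes, 10 modules of
15, 20 coherent and 20 control seed sets of 6 partners each — sizes at
which a seed-set evaluation is exact and fast, and chosen so the module
signal is strong but not degenerate. Seed genes live outside the modules
and no seed–partner pair is ever emitted as a network edge, mirroring the
circularity guard used with real inputs.

Two generator semantics deserve explicit statement. First,
`partner_noise` is realised as `floor(partner_noise * partners_per_seed)`
out-of-module partners per seed — a fraction of a finite set, rounded
down. The analysis behind this choice: an out-of-module partner is
functionally unlinked to the rest of the set, scores 0, and ties with the
large zero-score mass, so its pairwise contribution to the AUC is capped
at ½; a single such partner in a 6-partner set caps the AUC just below
0.9 regardless of how clean the module is. A fractional parameter
interpreted per-partner (Bernoulli) would therefore make the default
world's coherent seeds fail the 0.9 band about half the time — not a
property of the method but of the noise encoding — whereas the
floor reading keeps noise a deliberate, integer-valued stressor
(`partner_noise = 0.5` puts exactly 3 of 6 partners outside the module).

Second, with module cliques larger than the partner set, non-partner
module co-members *outrank* the partners under leave-one-out: a co-member
connects to all $k$ partners, a partner only to the other $k-1$. In a
noise-free, background-free world the coherent AUC is therefore exactly
$(n_\mathrm{zero}) / (n_\mathrm{negatives})$ — slightly below 1 — rather
than 1.0; the test suite asserts this closed form. This is faithful to
the method: the top-ranked non-partner co-members are precisely the novel
candidates the approach exists to propose.

What the worlds do *not* emulate: overlapping modules and complexes
(truth labels would become ambiguous), realistic degree distributions,
continuous LLS spectra, and ascertainment bias in which interactions get
tested — all present in real BioGRID/HumanNet-scale data. Passing the
synthetic recovery tests shows the machinery is correct and calibrated,
not that any particular organism's interactions are predictable; the
organism-scale results require the external databases and are out of
scope here.

## Problem sizes used in validation

The test suite and the acceptance script validate at deliberately modest
scales: AUC oracle equivalence on 1,000 random instances of up to 300
genes with heavy ties; exact binomial-tail agreement for all $n \le 25$
against rational-arithmetic reference values; BH flags against a direct
step-up scan on 500 random vectors; seed-set recovery pooled over 100
replicate default worlds; null calibration of the enrichment pipeline
over 200 replicate worlds with no planted signal (mean flagged fraction
at or under the nominal 5%, in practice far under it because the binomial
test is discrete and conservative at small $n$); and withholding curves
checked for exact identity at proportion 0, exact degeneracy at
proportion 1, and monotone decay in between. These sizes make the full
validation run in well under a minute per component on a single CPU while
leaving each statistical check comfortably powered.

## A worked example

```{r example}
w <- generate_world(world_spec(rng_seed = 7))
sets <- truth_seed_sets(w, "coherent")
res <- evaluate_seed_set(w$network, sets[[1]])
res
head(rank_candidates(res), 3)
```

The top candidates are the seed's module co-members that were not drawn
as partners — exactly the genes the guilt-by-association hypothesis
nominates.

## Limitations

* The method presupposes a reasonably complete functional network;
  partners missing from the network are unusable and are dropped (with
  per-seed accounting) before evaluation.
* Labels are strictly per-seed-set: a gene known to interact with a
  *different* seed still counts as a negative, so reported AUCs are, if
  anything, conservative.
* The binomial enrichment model treats member pairs as exchangeable
  trials; overlapping complexes are tested independently, and a shared
  interacting pair counts once per complex containing it.
* Interaction presence is binary; quantitative interaction scores
  (e.g. SGA growth scores) are not modelled.
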