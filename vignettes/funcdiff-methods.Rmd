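---
title: "Methods: annotation-driven functional comparison of community members"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-driven functional comparison of community members}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcdiff)
```

## Scope and model

`funcdiff` compares organisms and metagenome samples through their
functional gene annotation only: a mapping of genes (or ORFs) to KEGG
Ortholog groups, plus a pathway ontology giving each pathway's member KO
set.  The working assumption is that the *genotypic potential* visible in
KO content — which pathways an organism can in principle run, which
functions a community's genera contribute — is informative about niches and
interactions, with the caveat that the absence of a pathway is more
conclusive than its presence (expression is context-dependent).  No flux
model, gap-filling or biomass composition is involved.

Five matrices carry the analysis.  For isolates: the binary KO
presence/absence matrix **K** and the pathway coverage matrix **P** with
entries `|KOs(organism) ∩ members(pathway)| / |members(pathway)|`.  For
metagenomes: genus read abundance **G**, KO-genus read abundance **A**, and
pathway-genus coverage **PM**.  Coverage is a fraction of *distinct*
orthologs, never read-weighted: **PM** mirrors the isolate-side **P**
definition so the two branches are directly comparable.  Rows and columns
are sorted lexicographically everywhere, making all outputs bit-stable.

## Normalizations

Metagenome counts are made comparable in two steps, in a fixed order:

1. **per-million**: `g_ij ← g_ij / g_j × 10⁶`, where `g_j` is the sample's
   total; every column then sums to exactly 10⁶.
2. **complement adjustment** (optional, for an inoculated genus): with
   `f_j` the focal genus' relative abundance in sample `j` (computed from
   the per-million matrix, so it reads as a fraction), every non-focal
   entry is divided by `1 − f_j` and the focal rows are removed.  Column
   sums return to 10⁶.  Computing `f_j` *after* per-million scaling is a
   deliberate ordering choice; the two normalizations do not commute
   entry-wise and the complement formula is only meaningful on relative
   abundances.

Per-sample totals `g_j` count KO-annotated reads by default.  Reads on
unannotated ORFs (typically about half of them) can be conserved under the
reserved genus `"unclassified"` and included via
`build_genus_abundance(include_unannotated = TRUE)`; missing genus labels
are likewise mapped to `"unclassified"` rather than dropped so totals are
conserved.

## Clustering

Similarity is Pearson correlation by default, Bray–Curtis similarity
(`1 − dissimilarity`, via `vegan`) as the alternative for non-negative
abundance profiles; neither is inferred automatically.  Clustering is
affinity propagation: damped responsibility/availability message passing
with the preference (diagonal similarity) governing the number of
exemplars.  Numerical choices:

* damping 0.9, at most 1000 iterations, convergence declared after 100
  iterations of stable exemplar decisions — common practice for the
  algorithm; all three are arguments;
* a seeded symmetric noise at relative scale 10⁻¹² breaks degeneracies on
  tied similarities, so results are deterministic given the seed;
* after convergence, each cluster's exemplar is refined to the member
  maximizing total within-cluster similarity, and the reported net
  similarity (sum of similarities to exemplars plus exemplar preferences)
  is computed on the clean, noise-free matrix.

On small instances the implementation is checked against
`exhaustive_net_similarity()`, a brute-force search over all exemplar
subsets; the test suite requires agreement to 10⁻⁹ on nine- and ten-point
fixtures.

Instead of manually inspecting a dendrogram to choose a cutoff,
`tune_preference()` bisects the preference between the minimum and maximum
off-diagonal similarity (extending the bracket outward when the target lies
beyond it) until the requested cluster count is reached, within 50
evaluations; failure to attain the exact count is flagged and warned about,
never silent.  `agglomerate_clusters()` still exports the full merge tree
for human inspection: clusters are merged pair-wise by maximal joint
exemplar fitness (the best mean similarity of a single member to the rest
of the union), heights are the negated fitness with a running-maximum guard
against reversals, and any coarser partition can be cut out.

## Discriminative analysis

Pathways are ranked by the standard deviation of their coverage across the
selected units (sample SD, `n−1` denominator — the convention choice is
ours, the magnitude ordering is insensitive to it), ties broken
lexicographically.  A pathway absent from one organism and complete in the
others has SD ≈ 0.35–0.41 for panels of 5–8 units, far above the noise
floor induced by the generator's default 2% KO leak rate, which is why a
single planted absence reliably ranks first.

Feature selection against sample classes is a shadow-feature random-forest
wrapper (forest delegated to `ranger`): each run appends a freshly shuffled
copy of every feature, fits a forest (500 trees, z-scored permutation
importance by default, impurity importance as an option, class-balanced
case weights), and scores a *hit* for every undecided feature whose
importance exceeds the **running maximum** shadow importance.  Hit counts
are tested two-sided binomially at significance `1 − confidence`
(default 0.01) with Bonferroni correction across the features under test;
features are confirmed or rejected, the rest stay tentative and are
reported as such.

Two design choices here depart from the textbook scheme and deserve their
rationale:

* *Running-maximum threshold.*  Comparing against the per-run shadow
  maximum gives the strongest chance-correlated feature a hit probability
  above ½ — at `n = 60` samples and 200 noise features the winner of the
  chance-correlation race reaches |cor| ≈ 0.45, beats the per-run shadow
  max in the large majority of runs, and is eventually "confirmed" by the
  binomial test, whose null assumes hit probability ≤ ½ for irrelevant
  features.  Scoring against the best shadow seen so far keeps every fixed
  null feature at or below ½ and restores the calibration the binomial
  test needs; the cost is conservatism toward genuinely weak features.
* *Stationary design matrix.*  Rejected features stay in the forest (they
  are merely no longer tested), and the shadow pool is padded to the
  original feature count.  If the model shrinks as features are rejected,
  the importance competition thins out and the late-run shadow null is
  much weaker than the early one, again inflating confirmations.

`max_runs` defaults to 2000; with the running-maximum rule decisions settle
in 15–30 runs on the simulation sizes used here, so tests and the
acceptance script cap it at 100.

## The synthetic community generator

The generator is first-class, tested code; its defaults *are* the study
conditions everything else is validated under.

* **Ontology**: 20 pathways of 4–12 KOs each, pairwise-disjoint blocks.
  Disjointness keeps brute-force coverage oracles exact; the real KEGG
  ontology overlaps, so fixtures idealize that aspect.
* **Isolates**: 30 organisms in 8 functional groups (a kefir-like panel:
  two *L. kefiranofaciens*-like organisms missing four amino-acid-like
  pathways, four other lactobacilli missing one, and six further genera
  with their own absence sets).  An organism carries every KO of its
  non-absent pathways; KOs of absent pathways leak in at rate 0.02
  (annotation noise), and unannotated genes are appended so the
  KO-annotated fraction is 0.5, the typical annotatable share of a
  bacterial genome.
* **Metagenome series**: 3 grape varieties (two red, one white) × 3
  fermentations (one inoculated with *Lactobacillus*, boost ×30) × 8
  timepoints = 72 samples.  Baseline genus dynamics follow a plausible
  fermentation arc (yeast rising to dominance, grape DNA decaying,
  late malolactic genera); several genera are class-exclusive (e.g.
  *Pantoea* and *Gluconobacter* only in white, *Dyella* and *Acetobacter*
  only in red).  Reads (default 10⁵ per sample, a desk-scale problem size)
  are drawn multinomially over (genus, KO) cells — each genus' share split
  uniformly over its KO repertoire — so expected shares equal the planted
  abundances exactly and binomial error bounds are available in closed
  form.  A Dirichlet-multinomial option adds the overdispersion real
  metagenomes show; it is off by default to keep oracles exact.

What passing tests on these fixtures do **not** show about real data:
KEGG's overlapping pathway structure, read-mapping and binning artifacts,
overdispersed and compositional count noise, chimeric assignments, and
genus labels that are themselves uncertain.  The fixtures validate the
arithmetic and the recovery logic, not the upstream annotation.

## Degenerate inputs and edge policies

Zero-sum sample columns, constant vectors under Pearson, all-focal
complement columns, empty pathway member sets, malformed KO tokens
(anything but `K` + five digits), duplicate gene ids and negative read
counts are all hard errors naming the offending unit or line — format
drift should surface, not vanish.  `top_n` larger than the row count
returns everything with a warning.  A row subset of a per-million matrix
is relabeled `raw`, since the column-sum property no longer holds.

## Known limitations

* The leave-genus-out robustness check guarantees stability when the
  dropped genera are class-neutral *and* not jointly the community's depth
  backbone: removing all dominant neutral genera at once changes the
  per-million renormalization enough that the clustering can legitimately
  reorganize along a different planted axis (e.g. red/white instead of
  inoculated/control).  The shipped check therefore drops individual major
  genera, mirroring how such robustness is usually probed.
* The running-maximum shadow threshold trades sensitivity to weak features
  for null calibration; features near the detection boundary end tentative
  rather than confirmed, and are reported as such.
* Affinity propagation's preference/cluster-count relation is monotone
  only piecewise; `tune_preference()` can fail to attain an exact count on
  adversarial similarity structures and then returns the closest
  achievable clustering with a warning and an explicit flag.
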