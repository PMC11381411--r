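---
title: "Calling clonal duplicates from dominant SSR band matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling clonal duplicates from dominant SSR band matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrclone)
```

## The problem and the data model

Clonally propagated crops are conserved in genebanks as living accessions,
and the same clone frequently enters a collection more than once — under a
local synonym, as a re-donation, or through mislabelling. Molecular
fingerprints settle the question. For autotetraploids such as potato, SSR
electropherograms are hard to read as genotypes with allele dosage, so the
field scores them *dominantly*: each amplified fragment (band) across all
markers becomes one binary column — present, absent, or missing when the
call was uninterpretable. A study of a few hundred accessions with ~60
markers typically yields ~500 band columns.

`ssrclone` represents this as a `band_matrix`: an integer matrix of
0/1/`NA` with unique accession and fragment ids, optionally carrying a
locus label per fragment. Accession passport data (name, collection,
country, clonal type) live in a separate sidecar CSV keyed by accession id;
keeping the matrix purely binary makes it trivial to exchange between
scoring tools, and `read_band_matrix()` exposes dialect options (separator
and the three state tokens; `?`, `NA` and the empty string all read as
missing, `?` is emitted on write) because scoring software does not agree
on a single layout.

## Distance: raw mismatches under pairwise deletion

For each unordered pair the package counts the bands scored in **both**
members (pairwise deletion) and, among those, the bands where the two
fingerprints disagree. Three choices deserve emphasis:

* **Per band, not per locus.** Each amplified product is scored
  individually, so a single allele substitution at one SSR locus usually
  changes *two* bands (one lost, one gained) and contributes 2 to the
  mismatch count. Thresholds must be read with this in mind.
* **Monomorphic bands stay in.** They contribute zero mismatches but keep
  the band total literal, so "1 difference in 493 bands" means exactly
  that.
* **Fixed denominator.** The divergence proportion divides by the total
  band count, not by the per-pair compared count, so proportions remain
  comparable across pairs with different missingness. The per-pair
  alternative is available (`proportion_matrix(d, "compared")`) but is not
  the default.

A pair with *no* mutually scored band has an undefined distance; with tens
of markers this indicates a corrupt matrix, so it raises an error naming
the pair rather than propagating an `NA`.

The mismatch computation itself is three dense cross-products on the
presence, absence and observed indicator matrices — exact integer counts,
validated in the test suite against a brute-force per-cell recount on
random matrices up to 10×20.

## Duplicate calling

The difference histogram of a clonal collection is bimodal: pairs at 0–5
differences (re-donated clones, somatic mutants, scoring error), then a
sparse band, then the bulk of distinct genotypes. The default threshold is
**5 band differences** — about 1% on ~500 bands — and `suggest_threshold()`
reads the first empty histogram bin as a data-driven suggestion without
ever applying it silently.

Clusters are the **connected components** of the ≤-threshold graph (single
linkage). This is the only rule that never leaves an accession ambiguously
assigned, and it is consistent with published censuses in which a cluster's
internal difference range can reach or exceed the threshold through
chaining (e.g. a reported range of 1–5 inside one group). The census
therefore reports each cluster's min–max observed differences, making
chained clusters visible. An all-pairs-within-threshold alternative
(`linkage = "complete"`) is exposed for sensitivity analysis; it cuts a
complete-linkage dendrogram at the threshold height.

Cluster labels `C-1, C-2, …` are assigned by decreasing size, ties broken
by smallest member id, so reruns are reproducible. Bookkeeping identities —
`unique genotypes = singletons + clusters`, and the within-cluster pair
mass at ≤ *t* equalling the histogram mass at 0…*t* — hold by construction
and are asserted on every pipeline run.

## Trees and bootstrap support

UPGMA (average linkage on the raw mismatch counts, merges at half the
average between-cluster difference, hence ultrametric) and neighbor joining
(standard Q-criterion, unrooted) are built with `stats::hclust`/`ape`.
Trees use raw difference counts, not proportions, so branch lengths are in
band units. NJ's occasional negative branch estimates are clamped to zero
— standard practice — with the count and total deficit recorded on the
tree object for the run log. Tie-breaking follows `hclust`'s deterministic
scan order, so identical inputs give identical trees.

Branch support resamples the **band columns** with replacement (the matrix
is band-level, and character bootstrap is what distance-matrix programs
do); whole-locus block resampling is available via `resample = "locus"`
when bands within a marker should be kept together. Per replicate the
pairwise-deletion distances are recomputed and the tree rebuilt; a
replicate whose column draw leaves some pair with no scored band is
rejected and redrawn, with the redraw count reported. Support is the
percentage of replicate trees containing each internal edge's leaf
bipartition (clade, in the rooted UPGMA case), mapped onto the
point-estimate topology — the convention behind "one tree with support
values" figures — rather than a majority-rule consensus.

`collapse_branches()` contracts internal edges below the support threshold
(default 75%) into polytomies, adding each contracted edge's length to its
children so root-to-leaf depths are preserved; surviving supports are
untouched. `to_newick()` writes branch lengths with integer supports as
internal node labels.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe a Nordic-scale clonal potato collection:
62 SSR loci with 3–12 alleles each (≈460–500 band columns), 1–4 present
bands per locus per genotype (tetraploid, dosage-free), 140 unique
genotypes of which 31 found clonal groups sized 21×2, 4×3, 3×4, 1×5, 1×8,
1×10 (89 grouped accessions + 109 singletons = 198), group members 0–5
band flips from their founder, and 1% missing cells.

Within a locus, allele frequencies decay geometrically
(`allele_skew = 0.65`). This is the one deliberately tuned default: with
uniform allele choice, independent genotypes would share too few bands and
differ by ~200 of ~460 columns; with the skew, realized between-genotype
differences fall in the 70–140 band range with mean ≈ 100–105, the regime
observed in real dominant-SSR potato data. The generator never forces the
gap — a helper in the tests measures whether every between-genotype pair
exceeds the threshold, and the rare seeds violating it are counted and
excluded from recovery claims rather than hidden.

Clone perturbation flips band presence directly (exactly *k* toggled
positions, without replacement) instead of mutating the allele model: the
pipeline's distance is band-level, so flips give exact control over planted
distances. The founder is always the group's first member, so every member
is within the flip range of it and single linkage keeps the group
connected even when two members are up to twice the flip range apart.
Missing cells are applied after perturbation, uniformly at random, since no
specific missingness mechanism is being modelled.

The simulator does **not** model pedigree relatedness between distinct
genotypes (no "sibling varieties" at intermediate distances beyond what
the allele model produces), locus-correlated scoring failure (a whole
marker failing in one sample), or skin-colour-mutant style phenotype
divergence — so a pipeline that passes on synthetic data has demonstrated
correct *bookkeeping and recovery under the stated regime*, not robustness
to every artefact of real electropherogram scoring. On real data the
sparse 5–40-difference band may contain genuinely ambiguous pairs
(seedlings, close breeding lines) that no threshold rule can resolve;
the census is a report for curators, not a rejection decision.

## Numerical and scale choices

* Exact integer mismatch counts; no floating-point distance is ever
  thresholded.
* UPGMA ultrametricity is asserted to 1e-9 in the tests; depths preserved
  by collapsing are checked to 1e-12.
* The test suite and the acceptance script run at the defaults above:
  study-scale collections of 198×(~460–500), 500 bootstrap replicates
  (seconds on one core, thanks to the cross-product distance kernel), 20
  independent seeds for the recovery claim, and small matrices (≤10×20,
  ≤12 leaves) where brute-force oracles or exact tree recovery are the
  reference.
* All randomness (simulation, bootstrap) is governed by explicit seeds;
  identical configuration and seed give byte-identical artifacts, which
  the pipeline tests assert file by file.

## Known limitations

* Dominant scoring cannot separate clones differing only at loci outside
  the marker panel; identical fingerprints mean "identical at these
  bands", not "genetically identical".
* Single linkage can chain distinct genotypes through an intermediate if
  the gap is not clean; the reported min–max ranges and the
  complete-linkage flag are the diagnostic tools.
* Bootstrap support on near-zero-length internal edges of very similar
  accessions is inherently unstable; the collapse step is how such edges
  are meant to be read.
* The PHYLIP distance export uses the relaxed (whitespace-delimited)
  variant of the square format; tools insisting on fixed 10-character
  names may need adjustment.
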