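---
title: "Methods: domain-based binding-frequency estimation in dombind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-based binding-frequency estimation in dombind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`dombind` treats a protein domain family as a profile HMM whose match states
define structurally analogous positions across all instances of the family.
Given a collection of protein–ligand co-complex structures, each domain
instance contributes, for every match state it maps, the minimum Euclidean
distance between the mapped residue's heavy side-chain atoms and any heavy
atom of the ligand. Pooling instances gives a per-state distribution of
minimum distances; the estimator distills each distribution into a binding
frequency: the sequence-weighted fraction of instances within a contact
cutoff. The working assumptions are that (i) match-state alignment identifies
positions with comparable structural roles, (ii) side-chain proximity is an
adequate proxy for a binding contact, and (iii) the available structures
sample the family's binding modes. Assumption (iii) is the weakest: a
position scored 0 may simply be unobserved in complex; cross-validation is
the package's device for detecting families whose binding modes are too
heterogeneous to aggregate.

## Parameters and defaults

| parameter | default | role |
|---|---|---|
| `distance_cutoff` | 3.6 Å | contact definition: spans hydrogen bonds (2.6–3.3 Å) and van der Waals contacts (2.8–4.1 Å) while excluding the longer water-mediated bridges |
| `tanimoto_cutoff` | 0.9 | FP2 fingerprint similarity for calling a small molecule metabolite-like or drug-like |
| `max_folds` | 10 | cross-validation folds (capped at the instance count) |
| `min_precision` | 0.5 | pooled precision a pair must reach to enter the confident set |
| `bootstrap_reps` | 1000 | resamples for per-state standard errors |
| `consistency_reps` | 10 | split-half repetitions for the interface-consistency PCC |
| `identity_threshold` | 0.90 | single-linkage grouping for the stricter fold mode |
| `min_nr_instances` | 3 | sequence-distinct instances required before evaluation |
| `glycine_mode` | `ca_proxy` | see below |

Instance inclusion applies four independent filters: family gathering
threshold on the bit score, residues present at the first and last match
states, the modal amino acid at every state whose emission information
content is ≥ 4 bits (relative to a uniform background, `log2(20) − H`; a
distribution with ~95% mass on one residue sits just above this bar), and at
least one annotated binding residue. Information content against the
family's own null model is a conceivable alternative normalization; the
uniform background is used because the 4-bit threshold is calibrated to the
"one residue at ~95%" reading.

## Numerical and design choices

**Glycine.** The distance definition requires side-chain heavy atoms, which
glycine lacks. By default its Cα is used as a side-chain proxy
(`glycine_mode = "ca_proxy"`), keeping the position scoreable; with
`"exclude"`, such residues return a `NA` sentinel and the state is treated as
unmapped for that instance. Both behaviours are exposed because neither is
forced by the distance definition itself.

**Alternate locations, models, waters.** The highest-occupancy conformer is
kept per atom (ties: first in file order); only the first coordinate model of
multi-model entries is used, since aggregation is across entries rather than
across conformers of one entry; waters are never ligands. Peptide chains of
≤ 30 residues and nucleic-acid chains double as ligand instances; nucleic
ligands are split into base and backbone atom sets by the standard
phosphate-plus-sugar name table (base-contacting positions read out
specificity, backbone-contacting positions stability, so the two are scored
separately).

**Henikoff weights and redundancy.** Position-based weights are computed on
the match-state alignment; gap cells contribute no residue type and receive
no column score (a deletion carries no emission evidence). Weights are
recomputed inside every bootstrap resample by default — the resample is a new
instance set and its redundancy structure differs from the original — with
`recompute_weights = FALSE` available for the cheaper fixed-weight variant.
One property worth stating precisely: *uniform* duplication (every instance
copied the same number of times) leaves the weighted frequencies exactly
unchanged, and this is what the generator's `redundancy` parameter emits and
what the redundancy test asserts at 1e-9. Duplicating a *single* instance is
only approximately neutralized — position-based weights split a duplicated
sequence's mass within its group but the group total can still drift when
other instances share residue types at some columns — so exact invariance
should not be expected, or tested, for selective duplication.

**PR curves and the confident threshold.** AUPRC uses average-precision
(step) integration; trapezoidal interpolation between PR points is
optimistic and is not used. Equal-scored pairs cross each threshold
together. The headline AUPRC is the mean of per-fold average precisions
(folds without a positive pair are skipped); `pool = "overall"` switches to
the pooled curve. The confident threshold is chosen from the pooled curve as
the frequency maximizing recall subject to precision ≥ `min_precision`, with
ties broken toward higher precision — equivalently, the highest-precision
point among those achieving the best attainable recall under the constraint.
Held-out states absent from the training folds score 0 rather than being
dropped, so a novel binding mode in the held-out fold counts against the
model instead of being silently ignored.

**Poisson binomial.** The overlap test's PMF is computed by exact O(N²)
convolution over trials; at the site-list sizes the package targets this is
faster to trust than a characteristic-function approximation, and an FFT
path could be added behind the same contract. Tail p-values of exactly zero
are reported as 1e-15. Each site's success probability is its protein's
binding-site fraction (binding residues / protein length); the alternative
reading — normalizing by some restricted site universe — would need
information the site lists do not carry, so the protein-length denominator
is used and stated here.

**Fisher's exact test** is computed by direct hypergeometric summation
(one-sided tails; two-sided as the sum over tables no more likely than the
observed one), which keeps the test suite's comparison against
`stats::fisher.test` a genuine two-route check. Odds ratios are plain
`ad/bc` with no continuity correction; zero in a denominator cell is an
error rather than a silently corrected value.

## The synthetic-data generator

`make_toy_family()` emulates the geometry the estimator consumes, not
protein physics: residues are two-atom stubs (Cα plus one side-chain atom),
the ligand is a compact 3–8 heavy-atom pseudo-molecule, and the side-chain
atom of each residue is placed along its own direction at the support point
of the ligand's hull, which makes the planted minimum distance *exact* by
construction. Binding states draw distances from a truncated normal below
the 3.6 Å cutoff, non-binding states from one above it; sequences are
mutated from a random consensus (glycine excluded from the alphabet so the
side-chain stub is never ambiguous). `make_toy_proteome()` draws per-protein
binding fractions uniformly in ±50% of the nominal fraction so that
Poisson-binomial success probabilities vary across proteins, and places
interest sites independently with a weight of `enrichment` inside binding
sites; `enrichment = 1` is exactly the null hypothesis of the overlap test.

What passing tests on these fixtures shows is that the machinery — mapping,
weighting, scoring, cross-validation, calibration — is correct; what it does
not show is robustness to the things real structures do: missing side-chain
density, crystal-packing contacts, alternative binding modes, biased
deposition of popular families, or annotation noise in the binding tables.

**Problem sizes.** The test and acceptance simulations use families of 3–12
instances with 12 match states, proteomes of ~12 proteins of length 80–160,
and these study sizes, chosen so each check measures what it claims:
the calibration study uses 500 independent proteomes with 600 interest sites
each, enough sites that the discrete Poisson-binomial tail is dense and its
conservative steps do not masquerade as miscalibration in a
Kolmogorov–Smirnov comparison; the bootstrap-trend study plants binding
distances near the cutoff (mean 3.4 Å, sd 0.5 Å) because positions with
intermediate frequencies are where bootstrap uncertainty is informative, and
it averages the per-family mean SE over replicate families (24 at n = 3,
8 at n = 12) because a single 3-instance family often shows a unanimous
contact pattern and hence zero bootstrap variance.

## Known limitations

Symmetry mates and biological assemblies are not reconstructed, so contacts
across asymmetric-unit boundaries are invisible. Competing overlapping
domain hits are not arbitrated (no clan resolution); the hit table is taken
as given. The mmCIF reader covers the `atom_site` category only, which is
sufficient for coordinates but ignores entity-level metadata. Transfer keeps
all overlapping annotations (with a per-residue maximum view) rather than
deciding which domain "owns" a residue; downstream consumers should choose
the view that matches their question.
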