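# dombind

Domain-based aggregation of protein–ligand co-complex structures to estimate
per-domain-position ligand-binding frequencies.

## The problem

Protein domains mediate most interactions a protein makes — with DNA, RNA,
peptides, ions, metabolites and other small molecules — but only a minority of
positions within a domain touch the ligand, and a single co-complex structure
is a noisy witness of which ones. `dombind` aggregates many structural
instances of the same domain family: each instance's residues are mapped to
the family's profile-HMM match states, residue-to-ligand proximity is measured
per match state, and the evidence is pooled across instances into a
real-valued *binding frequency* per position and ligand class. The package is
for structural bioinformaticians who want to build such a resource from their
own co-complex collections, evaluate it, and project it onto unannotated
protein sequences.

## The estimator

For a domain–ligand pair with structural instances *i* = 1…*n* and match
states *s* = 1…*L*, let *d<sub>is</sub>* be the minimum Euclidean distance
between the heavy side-chain atoms of the residue instance *i* maps to state
*s* and any heavy atom of the ligand (for nucleic-acid ligands, restricted to
base or backbone atoms). The binding frequency at state *s* is the weighted
fraction of instances in contact,

  f<sub>s</sub> = Σ<sub>i : d<sub>is</sub> ≤ c</sub> w<sub>i</sub> / Σ<sub>i : s mapped</sub> w<sub>i</sub>,  c = 3.6 Å,

where *w* are Henikoff–Henikoff position-based sequence weights, so redundant
sequences do not dominate. The 3.6 Å cutoff captures hydrogen bonds and van
der Waals contacts while excluding water-mediated interactions. Uncertainty
comes from bootstrap resampling of instances (1000 resamples by default);
quality control comes from split-half interface consistency (Pearson
correlation of per-state mean distances) and up-to-10-fold cross-validation
scored by precision–recall curves against held-out structures. Pairs reaching
cross-validated precision ≥ 0.5 at some frequency threshold form the
*confident* set used for transfer onto query proteins, and overlap between
transferred binding sites and any site list of interest is tested exactly
with a Poisson-binomial model (one Bernoulli trial per site, success
probability = the binding-site fraction of that site's protein).

## Worked example

Everything below runs on synthetic data generated by the package itself — a
toy family of 10 single-chain co-complexes with a ligand planted within
3.6 Å of match states 3, 5 and 9:

```r
library(dombind)

fam <- make_toy_family(family_spec(seed = 42), "toy_fam")
inst <- load_family_instances("toy_fam/structures", "toy_fam/model.json",
                              "toy_fam/hits.tsv", "toy_fam/annotation.tsv")

fit <- bindfreq(inst, bootstrap = 1000, seed = 42)
fit
#> <bindfreq> TOYDOM / SMALL_MOLECULE: 12 match states, 10 instances, cutoff 3.6 A
#>   positive-frequency states:
#>     state   3: 1.000 +/- 0.000 (n=10)
#>     state   5: 1.000 +/- 0.000 (n=10)
#>     state   9: 1.000 +/- 0.000 (n=10)

cv <- cross_validate(inst, seed = 42)
cv
#> <cv_result> TOYDOM / SMALL_MOLECULE: 10 folds (instance), AUPRC 1.0000, baseline 0.2500 (4.0x)

confident_threshold(cv)
#> <confident_interaction> TOYDOM / SMALL_MOLECULE: threshold 1.0000 (precision 1.000, recall 1.000)

round(as.numeric(consistency_pcc(inst, seed = 42)), 3)
#> [1] 0.997
```

The fit recovers the planted interface exactly: frequency 1 at the three
planted states, 0 elsewhere, zero bootstrap SE (the contact pattern is
unanimous). Cross-validation scores held-out instances perfectly (AUPRC 1
against a 0.25 baseline — a 4-fold improvement), the pair enters the
confident set at precision 1, and split-half distance profiles correlate at
0.997. `write_bindfreq(fit, "freq.tsv")` exports the release-shaped table;
`transfer_frequencies()` then projects it through domain hits onto query
proteins and `overlap_test()` compares any site list against the transferred
sites. `run_pipeline()` (or `inst/cli/dombind.R`) drives the same stages from
files.

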