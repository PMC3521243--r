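---
title: "Mapping small-molecule binding to Pfam-A domains: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping small-molecule binding to Pfam-A domains: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmap)
```

This vignette documents the model behind `ligmap`, the parameters that
matter, the numerical choices, and the design decisions taken where the
problem left genuine freedom. It states no empirical result beyond what the
package's own tests and `scripts/acceptance.R` compute.

## The seed-domain heuristic

The unit of annotation is the Pfam-A family: a curated profile-HMM domain
model with non-overlapping, 1-based inclusive start/end coordinates on the
Uniprot sequence. The mapping problem is: given a measured bioactivity
against a full-length protein, decide which of the protein's domains
mediated the binding.

The heuristic rests on one observable: when a protein consists of a single
domain family, any ligand measured against it necessarily binds (at or
near) that family. Families validated this way — by occurring as the sole
distinct family of some target with a qualifying activity — form the *seed
set*. Multi-domain targets are then resolved by seed content: a target with
exactly one distinct seed family (copy number does not matter) assigns all
of its qualifying activities to that family; a target with none, or with
two or more distinct seed families, receives no mapping. The refusal to
guess in the conflict case is deliberate: the cost of a false domain
assignment (propagating ligands to the wrong family) outweighs the loss of
coverage, and conflicts are instead surfaced in a report for manual review.

### The qualifying-activity filter

A record qualifies when all of the following hold:

| parameter | default | meaning |
|---|---|---|
| assay type | `B` | binding assay, direct and unambiguous (multi/complex flags 0) |
| activity types | Ki, Kd, IC50, EC50, −Log Ki, pKd, pA2, pI, pKa | controlled vocabulary |
| potency threshold | 5·10⁻⁵ M (50 µM) | records at least this potent are kept, boundary inclusive |

Concentration-type values are converted to molar using their unit (M, mM,
µM/uM, nM, pM); log-scale types carry no unit and are compared against
−log10(5·10⁻⁵) ≈ 4.301. Two readings of the threshold ("at least as strong
as" vs "weaker than is removed") agree on keeping the 50 µM boundary, and
the filter implements that inclusively. pA2, pI and pKa are accepted as
log-potency values because they share the vocabulary and the threshold with
pKd, even though their physical meaning differs; kept records of these
types are noted in the log. Records with an unsupported unit are rejected
with a logged reason — the filter never guesses a unit. Rejection counts
are returned with the filtered table, so row conservation
(`input == kept + rejected`) is checkable.

### Manual curation inputs

Two curation lists are configuration, not code: accessions excluded before
seeding (protein fragments annotated as targets, where the binding domain
is missing from the fragment and the mapping would land on a bystander
domain — the packaged default list carries the one documented case,
a phosphodiesterase-5 N-terminal fragment), and families forced into the
seed set (the packaged default adds the tyrosine-kinase family, which
essentially never occurs alone and therefore cannot be seeded from data,
while its ligand binding is beyond doubt). The co-occurrence report exists
to find further candidates of the second kind: families that never occur
alone, ranked by how many targets contain them, flagged at a configurable
threshold (default 100 targets).

## Validation by residue overlap

Binding-site annotations come in two dialects: sparse expert-curated key
residues, and complete ligand-contact residue lists from crystal
structures, both in Uniprot coordinates (coordinate translation from PDB
numbering is out of scope and assumed done upstream). For a predicted
family, the score is the fraction of binding residues inside the union of
that family's intervals; ≥ 0.5 counts as correct. Per-family shares are
always computed for every family on the target; shares need not sum to one
(residues may fall outside all domains, and copies may overlap after
curation mistakes), so no renormalization is applied.

Interface binding — one ligand contacting two or more families
substantially — is flagged when at least `min_families` (default 2)
families each hold a share of at least `min_share` (default 0.30). No
published cutoff exists for this; 0.30 was chosen because curated
structural examples of interface binding show per-domain ratios of 0.30
and above, and both knobs are exposed.

Two reporting conventions avoid arbitrary choices: the within/outside
ratio used for survival curves is kept as `Inf` when all residues fall
inside (the all-within mass is reported separately rather than capped),
and sequence coverage merges overlapping or contiguous intervals before
counting, making it invariant to how an annotation splits one region into
sub-intervals.

## Discrete power-law analysis

Counts (family occurrences, ligands per family, ligands per target) are
positive integers, so the discrete zeta-normalized law
\(p(k) = k^{-\alpha} / \zeta(\alpha, x_{\min})\) is the primary model,
estimated by the standard maximum-likelihood recipe:

1. for fixed \(x_{\min}\), \(\hat\alpha\) maximizes the tail
   log-likelihood (solved by 1-D numerical optimization to tolerance
   10⁻⁶, checked in tests against a dense grid search);
2. \(x_{\min}\) ranges over observed values and minimizes the KS distance
   between the tail empirical CDF and the fitted CDF, ties going to the
   smallest candidate (the tie rule is a convention; it favors the larger
   tail);
3. goodness of fit is the fraction of semi-parametric bootstrap replicates
   (body resampled empirically, tail drawn from the fitted law, each
   replicate re-fit with free \(x_{\min}\)) whose KS statistic is at least
   the observed one; the replicate count defaults to 1,000 and a seed is
   mandatory;
4. alternatives (lognormal, exponential, Weibull) are fit by MLE on the
   same tail and compared with the Vuong-style normalized log-likelihood
   ratio \(R/(s_d\sqrt{n})\), positive sign favoring the power law, with a
   two-sided normal p-value for whether the sign is interpretable. Raw
   statistics are reported; no yes/no decision rule is imposed.

The Hurwitz zeta function is evaluated by direct summation of 25 terms
plus an Euler–Maclaurin tail correction (through the \(B_6\) term), giving
absolute errors far below 10⁻¹⁰ over the exponent range used
(1 < α ≤ 25); tail probabilities therefore sum to one well within the
10⁻⁶ the tests assert. Sampling uses inverse-CDF lookup over a cumulative
table, with rare deep-tail draws resolved by bisection on the exact CDF so
no truncation is introduced.

The alternative models are *discretized* by survival-function differences,
\(P(k) = (S(k-\tfrac12) - S(k+\tfrac12))/S(x_{\min}-\tfrac12)\), which
normalizes exactly over the integers ≥ \(x_{\min}\). This differs from
comparing against the continuous densities directly; the discretized form
was chosen so both competitors are genuine distributions on the same
support, which the Vuong statistic presumes.

Experiment design note: the likelihood-ratio *direction* experiments (data
generated from a known model must push the statistic toward that model)
fix \(x_{\min}\) at the generating law's support bound. With a free
\(x_{\min}\) scan the fit trims non-power-law data to a short tail on
which any smooth alternative is locally power-law-like and the sign is
dominated by noise — informative about the scan, not about the test.

## Chemical-space profiling

The six descriptors are molecular weight (Da), ALogP (Ghose–Crippen
octanol/water partition estimate), polar surface area (Å²), and rotatable
bond / H-bond donor / acceptor counts. Choices where the procedure was
underdetermined:

* **Trimming** is two-tailed at the 1st and 99th percentiles (a literal
  "hundredth percentile" cut would remove only the maxima); percentiles
  are computed once over the full input, and a compound is removed when
  *any* descriptor violates its cutoffs — rows are the only coherent unit
  of removal for PCA. Cutoffs are configurable; trimming is a single pass
  and is not iterated.
* **Scaling** includes mean-centering alongside division by the sample
  standard deviation (n−1), i.e. the default behavior of the standard PCA
  routine the analysis is built on.
* **PCA** is computed once over the pooled compounds of all profiled
  families, not per family, so scores live in one shared space. The sign
  of each loading column is fixed by making its largest-magnitude element
  positive, which makes loadings tables comparable across runs. Tests
  verify equivalence with an independent eigendecomposition of the
  covariance matrix to 10⁻⁸.
* **Family comparison** uses Welch (unequal-variance) two-sample t-tests
  on PC1 scores for every family pair, Bonferroni-multiplied by the number
  of pairs and capped at 1. Families with fewer than 3 compounds are
  excluded with a warning. A compound mapped to several families is
  counted once, under its first mapping, and the case is logged.

## The synthetic generator

The generator plants a complete ground truth so every claim the pipeline
makes can be checked exactly. Its defaults are the study conditions the
package is designed around: families receive usage weights drawn from a
discrete power law with exponent 2.07 (the exponent observed for
proteome-wide Pfam family frequencies), and a target is multi-domain with
probability 0.5 (about half of annotated drug targets carry more than one
domain). Each target's planted binding family is the family the heuristic
can in principle recover — its unique seed family when it has one — which
makes noise-free benchmarks exact by construction rather than by luck.
Binding sites place `k` residues (default 10) inside the planted family
and `round(k·f/(1−f))` outside, so the within-fraction is `1−f` up to
rounding and the verdict boundary can be hit exactly (f = 0.5). Activity
distractors violate exactly one filter dimension each (wrong assay type,
flagged, too weak, disallowed type), in known proportions.

What the generator does **not** emulate: real potency value distributions
beyond the filter-relevant dimensions, correlated domain architectures
(families are drawn independently per target), inter-species redundancy,
or annotation errors other than the planted noise. Passing tests therefore
demonstrate correctness of the *method* under its stated assumptions, not
performance on any particular database snapshot; the published headline
accuracies depend on specific database versions and are not reproducible
at fixture scale.

Problem sizes used by the test-suite experiments were chosen to keep the
whole suite in the minutes range while leaving comfortable statistical
margins: 100 random fixtures of 60 targets for oracle equivalence, 20
simulations of n = 5,000 for exponent recovery (the MLE's standard error
there is ≈ (α−1)/√n ≈ 0.02, against an asserted mean error of 0.05), 200
replicates of n = 300 with 100 bootstrap draws for goodness-of-fit
calibration, and 1,000 random cases per overlap invariant.

## Known limitations

* Seeding is blind to families that never occur alone; the co-occurrence
  report plus manual curation is the only recourse, and the packaged
  manual list carries a single family.
* Conflict targets (two or more seed families) are never resolved
  automatically, by design.
* Interface binding is reported, not resolved: a ligand genuinely bound
  across two domains will at best be mapped to one of them, and the 0.5
  rule scores such predictions fairly but cannot represent "both".
* The activity filter treats pA2/pI/pKa on the same log-potency scale as
  pKd; for pKa in particular this is a vocabulary decision, not chemistry.
* Pfam accession↔identifier resolution, coordinate translation from PDB
  numbering, and live database queries are all out of scope; inputs must
  arrive as flat files in Uniprot residue coordinates.
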