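---
title: "Methods: signature-based combination screening and median-effect synergy"
author: "comboscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-based combination screening and median-effect synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

## The problem

Diseases driven by several signaling pathways are rarely controlled by one
molecule. `comboscreen` searches a compendium of drug-treatment expression
profiles for *pairs* of molecules whose combined transcriptional footprint
opposes a disease signature across the disease's enriched pathways, and then
quantifies the synergy of a chosen pair from wet-lab dose-response data with
the Chou–Talalay median-effect framework.

The screening side works entirely on ranks: each treatment instance is a
permutation of all probe sets, rank 1 the most up-regulated probe relative
to the instance's control. Working with rank permutations makes the
compendium platform- and normalisation-agnostic and gives the permutation
null an exactly exchangeable reference.

## The screening procedure

Four steps, each a pure function of its inputs and the seed:

1. **Pathway selection.** The disease signature (disjoint up/down probe
   lists) is tested for over-representation in every pathway gene set with
   the upper-tail hypergeometric test on the joint up ∪ down set; pathways
   with raw p < 0.01 are selected. We test the union rather than each
   direction because directionality only becomes meaningful at the KS stage;
   a separate-mode flag exists for users who prefer per-direction testing.
   No multiple-testing correction is applied by default — the raw-p cut is
   the method's convention — but a Benjamini–Hochberg flag is available.
   Selected pathways overlapping the signature in fewer than 3 probes are
   flagged `low_overlap` and excluded downstream: a KS tag set with 1–2
   members is dominated by lattice noise.

2. **Connectivity scoring.** For each selected pathway and each profile, the
   signature is restricted to the pathway's members (tag-set restriction
   only; the KS statistic always runs against the full-length rank column,
   because the profile representation *is* the full rank-ordered list — a
   `restrict_ranks` flag re-ranks within the pathway for sensitivity
   analysis). With tag positions $V(1)<\dots<V(t)$ among $n$ ranks,
   $$a = \max_j\left(\frac{j}{t}-\frac{V(j)}{n}\right),\qquad
     b = \max_j\left(\frac{V(j)}{n}-\frac{j-1}{t}\right),$$
   and the score is $a$ if $a \ge b$, else $-b$ (the exact tie returns the
   non-negative branch). The raw enrichment score of a profile is
   $\mathrm{ks}_{up}-\mathrm{ks}_{down}$ when the two directional scores
   disagree in sign (or either is zero) and 0 otherwise: a connected profile
   must move the up- and down-tags in opposite directions. Raw scores are
   normalised per pathway — positives by the maximum positive, negatives by
   |minimum negative| — so that the fixed ±0.5 ranking thresholds are
   comparable across pathways. Profiles whose restricted up- or down-tag set
   is empty are excluded from that pathway's ranking and counted in a QC
   attribute.

3. **Drug-set scoring.** Profiles are ordered by descending normalised ES
   (ties by lexicographic instance id, so the ordering is reproducible).
   A molecule's set is all of its instances; a pair's set pools the
   instances of both molecules. The same KS statistic, applied to the set's
   positions within the ES ordering, gives the set-level score; significance
   is a two-sided add-one permutation p-value against uniformly random
   subsets of the same size. Subset permutation (rather than re-shuffling
   whole rank matrices) preserves the ES distribution exactly and is the
   natural exchangeable null here; a full-matrix shuffle would only add
   Monte-Carlo noise at far higher cost. Because that null depends only on
   (number of ranked profiles, set size), draws are cached and shared across
   same-sized sets within one scoring call — with 10,000 permutations per
   distinct size this is what keeps a full pair screen tractable.

4. **Ranking.** For each candidate, the number of significant pathways with
   score strictly above the positive threshold (0 for singles, +0.5 for
   pairs) is counted; candidates are ranked by descending count. Pathways
   below the negative threshold (0 / −0.5) are listed as potential adverse
   matches. Equal counts are broken by descending summed |score| over the
   significance-eligible pathways, then by name; the summed-|score| key is
   our choice where several are defensible, picked because it rewards
   breadth of strong matching. Significance (p < 0.01) is required before a
   pathway is counted; `require_significance = FALSE` disables this.

**Orientation.** When the input signature describes the disease state, a
therapeutic candidate should *reverse* it. The default orientation swaps the
up/down lists before scoring so that candidates of interest appear at
positive scores; `orientation = "mimic"` scores the signature as given.

**Pair universe.** By default pairs are formed only among molecules that are
individually significant in at least one selected pathway. This is not just
a cost cut (it removes the quadratic blow-up): the +0.5 pair threshold has a
hard geometric consequence discussed below, and the restricted universe is
what makes the pair ranking behave sensibly. Full enumeration is available
via `pair_universe = "all"`.

## Why +0.5 is a hard bar for a pair, and what that implies

Suppose a pair's set has $2k$ instances among $m$ ranked profiles and only
one member molecule truly matches the pathway, so $k$ instances sit at the
very top and the other $k$ fall uniformly. The KS deviation at $j=k$ is
$\tfrac12 - \tfrac{k}{m}$ — strictly below 0.5, however strong the planted
half is. A pair therefore crosses +0.5 in a pathway only when *both*
members' profiles are enriched there. This is by design (the pair score is
meant to reward complementarity within each pathway), but it means a pair of
two single-pathway specialists is recovered through the significant-singles
pair universe and the summed-|score| tie-break, not through the count. The
end-to-end recovery test reflects exactly that mechanism.

The same geometry drives a power requirement: with only half the set
extreme, the observed deviation is ≈ $\tfrac12 - \tfrac{t}{2m}$, and the
two-sided permutation tail at that deviation is roughly
$2\exp(-2t(\tfrac12 - \tfrac{t}{2m})^2)$. For p < 0.01 this needs a set size
$t \gtrsim 14$, i.e. at least 7 instances per molecule. The canonical
pair-recovery scenario therefore uses 10 instances per molecule (the
generator's general default stays at 5, a typical desk-scale choice).

## What the synthetic generator emulates — and what it does not

`gen_compendium` draws unplanted columns as uniformly random permutations:
the simplest exchangeable null, exactly matching the permutation test's
assumptions. A planted instance adds large latent-score offsets (jitter sd
`noise`) to a `strength` fraction of the signature-within-pathway probes
before ranking, so columns remain valid permutations while the targeted
probes move to the extremes; direction `reverse` sends disease-up probes to
the bottom ranks and disease-down probes to the top.

Instance identifiers are assigned in seeded random order across molecules,
the way accession numbers accrue across batches in real compendia. This
matters more than it looks: profile-level ES values contain many exact zeros
(the same-sign rule), ES ties are broken lexicographically, and if id order
tracked molecule identity, a molecule's tied instances would cluster inside
the zero block and inflate set-level scores under the null. With scattered
ids the subset-permutation p-values are well calibrated (the null-compendium
test holds the empirical p < 0.01 rate within [0.005, 0.02]).

The generator does **not** mimic microarray probe-level noise, batch
effects, correlated gene modules outside the planted pathways, or real dose
ladders. Passing tests therefore demonstrate the statistical machinery —
calibration, recovery of planted signal, determinism — not performance on
real compendia, where correlated background transcription makes nulls
heavier-tailed than uniform permutations.

## Median-effect synergy

The median-effect equation $f_a/f_u = (D/D_m)^m$ is linear in log–logit
coordinates; `median_effect()` fits it by ordinary least squares, returning
$D_m$ (the IC50), the slope $m$, and the correlation $r$ of the transformed
points. We do not claim bit-compatibility with commercial median-effect
software, whose fitting weights are unpublished; on noiseless data the
estimates are exact to numerical precision, and under 5% multiplicative
noise the median relative error stays below 5%.

For a fixed-ratio combination (ratio is a required input; typical designs
use 1:1 or 2:1 molar mixes), `synergy_curve()` computes at each effect
level the single-agent doses, the ratio-split component doses of the
combination, the dose-reduction indexes $\mathrm{DRI}_X = D_{X,\,alone} /
D_{X,\,combo}$, and the two-term (mutually exclusive) combination index
$$\mathrm{CI} = \frac{D_{A,\,combo}}{D_{A,\,alone}} +
  \frac{D_{B,\,combo}}{D_{B,\,alone}} = \frac{1}{\mathrm{DRI}_A} +
  \frac{1}{\mathrm{DRI}_B}.$$
CI < 1 is called synergism, CI > 1 antagonism, with an additive band of
±0.02 (configurable) around 1 to absorb fitting noise.

`gen_combo_table` builds combination tables analytically from two
single-agent fits: at effect $f_a$ the Loewe-additive total dose of a
mix with drug-A fraction $\rho$ solves
$\rho D/D_A(f_a) + (1-\rho)D/D_B(f_a) = 1$, and the generated combination
reaches each effect at `ci_target` times that dose. With equal slopes the
construction is itself a median-effect curve and CI recovery is exact; with
unequal slopes the combination curve is only approximately log-logit-linear
and recovered CIs are accurate to a few percent at the interior effect
levels.

## Numerical choices and edge cases

- Observed $f_a$ outside $(10^{-3}, 1-10^{-3})$ is clipped with a warning
  before the logit transform (the transform is undefined at 0/1).
- KS ties $a = b$ return the non-negative branch; strict inequalities at the
  ranking thresholds (a score of exactly 0.5 is not counted).
- Rank-list reversal negates the KS score only up to a $1/n$ lattice shift
  (reversal maps $a' = b - 1/n$, $b' = a + 1/n$); the property suite asserts
  this exact form rather than idealised antisymmetry.
- Empty tag sets are an error at the statistic level and a skip (with QC
  count) at the pipeline level; flat dose-response curves and zero dose
  variance are errors in `median_effect`.
- All generators and both permutation entry points restore the caller's RNG
  state; identical seeds give byte-identical outputs end to end.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale: a 1,000-probe universe, 10
pathways of 20–40 probes, 20 molecules (10 instances each in the
pair-recovery scenario, 5 elsewhere), 2,000 permutations per null, and 2,100
(pair, pathway) tests in the calibration study; exhaustive oracles cover all
tag configurations up to $n = 12$ and the full hypergeometric grid up to a
universe of 30. These sizes were chosen so that the statistical properties
under test (calibration bands, recovery margins) are informative while a
full run stays comfortably interactive.

## Known limitations

- The unweighted KS statistic ignores expression magnitudes by construction;
  a correlation-weighted variant is deliberately out of scope.
- Per-pathway ES normalisation makes scores comparable across pathways but
  ties a profile's score to the cohort scored with it; scores are not
  transferable across screens.
- The pair score pools instances without dose matching; molecules profiled
  at many doses weigh more than sparsely profiled ones.
- Only the two-term mutually exclusive CI is implemented; conservative
  (three-term) isobologram variants and Bliss/HSA models are out of scope.
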