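---
title: "Detecting dual-light-chain B cells and the serum decoration confound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dual-light-chain B cells and the serum decoration confound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(b2rscan)
library(dplyr)
```

# The two measurements and why they disagree

Two assays estimate the frequency of B cells expressing two light
chains. Flow cytometry gates CD19+ cells on surface Ig kappa versus Ig
lambda and counts double positives. Single-cell V(D)J sequencing
reconstructs the expressed heavy and light chain transcripts of each
cell barcode and counts cells with two distinct productive light
chains. In healthy blood both land in the low single digits of percent.
In a subset of lupus patients flow cytometry reports 4–40%+ double
positives while sequencing of the same donors stays near 2%.

`b2rscan` implements the sequencing-side classification as a tested
pipeline and pairs it with a generative model of the flow side that
reproduces the discrepancy mechanistically: circulating B-cell-reactive
IGHV4-34 IgM autoantibodies (detected by the 9G4 idiotype reagent) coat
the B-cell surface. A coated cell carries its own light chain plus the
serum antibody's, and whenever the two isotypes differ the cell falls
into the kappa/lambda double-positive gate without expressing two
receptors.

# Clonotype classification

## Rules

A cell barcode is **analyzable** when it has

1. exactly one productive heavy-chain contig (cells with two productive
   heavy chains are excluded outright rather than treated as dual-heavy
   receptors);
2. an unambiguous isotype: constant-region gene starting `IGHM`/`IGHD`
   is unswitched (`IgMD`), `IGHG`/`IGHA`/`IGHE` is `switched`, anything
   else (including a missing call) is `ambiguous` and excludes the
   cell. IgD-only cells are merged with IgM into one unswitched class;
3. one or two *called* light chains.

Light-chain calling is where the only genuinely free threshold in the
classifier lives. Contigs on IGK/IGL are ranked by UMI count (ties by
read count, then contig id, so classification is a pure function of the
input set and never of row order). The top-ranked productive contig is
the primary chain. Any further productive contig is called only when
its UMIs reach

```
max(min_secondary_umis_abs, ceiling(min_secondary_umis_frac * primary_umis))
```

with defaults 3 and 0.10 (`calling_params()`). Droplet data carry
ambient contigs at 1–2 UMIs; a genuine second chain is expressed at
depth comparable to the primary. The default absorbs the former while
keeping the latter, and the generator emits both populations so the
threshold is genuinely exercised. Raising the absolute floor can only
demote dual calls to single calls, never the reverse — this
monotonicity is tested. Cells with three or more called chains are
excluded as unresolvable multiplets. Non-productive light contigs never
support a call by default; `require_productive_lc = FALSE` exists for
sensitivity analysis. Whether the original spreadsheet-based analyses
required productivity of the second chain is not documented anywhere we
know of; productive-only is this package's choice, recorded here rather
than attributed.

Analyzable cells partition into `single_kappa`, `single_lambda`,
`dual_kappa`, `dual_lambda` and `kappa_lambda` by the locus multiset of
called chains. The IGHV4-34 flag compares the heavy V gene after
stripping the IMGT `*NN` allele suffix, case-insensitively; stored gene
names are never modified, keeping I/O lossless.

An independently written brute-force classifier (plain per-barcode
loops over the rule text) is kept in the test suite and must agree with
the vectorised implementation on 1,000 randomised barcodes per run.

## Summary statistics

`summarize_repertoire()` uses these denominators: V-gene usage over
cells with exactly one productive heavy chain; light-chain class
fractions, switched fraction and heavy CDR3 length over analyzable
cells; Jkappa usage over called kappa chains (a dual-kappa cell
contributes two). CDR3 length is the length of the delivered amino-acid
string including the flanking C and W/F residues — conventions differ
between tools, so the package does no trimming. Jkappa usage defaults
to unswitched (IgM/D) clonotypes, the compartment in which
receptor-editing history is least overwritten by selection; a
`jk_subset` argument exposes switched-only and all-cell variants
because the restriction is a choice, not a law.

The patient-level rule `high_kl_threshold()` returns the control mean
plus three standard deviations. Two readings of "3 times the SD over
the mean" are arithmetically possible; mean + 3·SD is used because with
the healthy flow values (mean 0.73%, SD 0.47%) it gives 2.14%, which
separates the elevated patients (≥4%) from every control (<2%), whereas
3·SD/mean would not define a frequency at all. Sample SD (n − 1) is
used as the values are a cohort sample. The H call is strict
(`freq > threshold`).

`mann_whitney_u()` is authored in the package: U from midrank sums; the
p value by full enumeration of rank assignments when the smaller group
has ≤8 observations and no ties, otherwise a normal approximation with
tie-corrected variance and a 0.5 continuity correction. The base-R
implementation serves as an independent cross-check in the tests, to
1e-6 over a thousand random datasets, but is never called by the
package path. `linear_regression()` wraps `stats::lm()`; a constant
response returns slope 0, r² = 0, p = 1 explicitly since the 0/0
r-squared is undefined in the limit.

# The synthetic repertoire

`generator_config()` defaults define the study conditions and are not
tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `p_kl`, `p_kk`, `p_ll` | 0.02, 0.02, 0.01 | inclusion rates: ~2% kappa/lambda, ~5% dual overall |
| `p_lambda` | 0.5 | ~1:1 kappa:lambda among single-chain cells |
| `p_vh434` | 0.05 | ~5% IGHV4-34 heavy-chain usage |
| `p_switched` | 0.20 | class-switched fraction of circulating B cells |
| `jk_prior` | .40/.25/.15/.10/.10 | initial Jkappa rearrangement preference, proximal-biased |
| `edit_mean` | 0.5 | mean editing rounds (geometric); doubled for included cells |
| `umi_mean_primary/secondary` | 30 / 15 | negative-binomial UMI depth per chain |
| `nb_dispersion` | 2.0 | UMI variance inflation: var = 2 × mean |
| `ambient_rate` | 0.05 | spurious non-productive contigs per cell (Poisson) |

The dispersion parameter is a variance-inflation factor (NB size =
mu/(phi − 1)), chosen over the raw NB `size` parameterisation so that
the secondary-chain UMI distribution keeps almost all of its mass above
the calling threshold: a generator whose genuine second chains are
routinely indistinguishable from ambient noise would make the
configured inclusion rates unrecoverable by construction, which is a
property of the generator, not a finding about data.

Receptor editing is modelled as a distal walk on the kappa locus:
an initial Jkappa from `jk_prior`, then a geometric number of editing
rounds, each re-drawing a segment strictly downstream of the current
one from the renormalised prior, halting at IGKJ5. Included cells draw
twice the mean rounds, encoding the interpretation that inclusion
arises *during* editing. This is one admissible mechanism, labelled as
a stand-in — no quantitative editing-round distribution has been
measured — but it delivers the two observable signatures: depleted
IGKJ1 and enriched IGKJ5 in dual cells. The walk's exact post-editing
distribution is computable from its transition matrix, and the sampler
is tested against that closed form at 10⁵ draws.

Subset labels (naive 50%, switched memory 25%, MZ-like 10%, DN 7%, BND
5%, activated naive 3% — an unremarkable circulating composition) are
drawn independently of the receptor genotype; their only role is to
carry decoration susceptibility. Gene pools are 30 IGHV, 12 IGKV and 10
IGLV symbols with a truncated power-law heavy prior — adequate for
usage statistics without a germline database. The generator does not
model nucleotide sequences, somatic hypermutation or clonal expansion
(each barcode is an independent clonotype), so passing tests say
nothing about lineage-level analyses on real data.

# The decoration model

`stain()` produces one flow event per cell on three log10-intensity
channels. Primary chains always stain above their gate. A genuine
secondary chain exceeds its gate with probability
`detection_efficiency` (default 0.35) — a calibration, not a
measurement: it is the value at which a true 2% kappa/lambda rate reads
out at roughly 0.7% by flow, matching the healthy flow-versus-
sequencing gap. Cells intrinsically expressing IGHV4-34 IgM stain on
the 9G4 channel.

Decoration happens per cell with probability

```
min(1, titer * p_decorate_base * susceptibility[subset] * attenuation)
```

The decorating antibody carries kappa or lambda with equal probability
(`p_opposite_lc = 0.5`), reflecting that B-cell-binding VH4-34
antibodies are not light-chain skewed; one dominant serum clone per
cell adds intensity to exactly one light-chain channel, producing the
kappa-high/lambda-positive and kappa-positive/lambda-high patterns
rather than uniform double-brightness. Susceptibility defaults (BND 0;
naive, activated naive, MZ-like, DN 1; switched memory 0.3) are ordinal
readings of the observed subset distribution — anergic BND cells are
spared, switched memory partially susceptible — exposed as
configuration rather than asserted as measured values.

Numerical choices: background intensity is clipped just below the
default gates and positive draws sit strictly above them, so gate
membership is an exact function of expression and decoration. This
deliberately omits false-positive background staining; it buys exact
identities — at titer 0 the apparent kappa/lambda rate *equals* the
detected true rate, decoration-created double positives are a subset of
9G4+ events, and apparent rates are non-decreasing in titer under
common random numbers — all of which are tested as exact or
deterministic properties rather than approximate ones.

The documented profiles: `healthy_serum()` has titer 0 (no
B-cell-reactive VH4-34 content). `sleh_serum()` has relative titer 16 —
near the geometric middle of the elevated-titer band reported for
kappa/lambda-high patients (≈5–105 relative units) — giving a
decoration probability of 0.8 for fully susceptible subsets. With the
default subset mix this yields an expected apparent kappa/lambda
readout of ≈33% (inside the observed 4–42% range) and ≈70% 9G4+
(inside the 40–93% band), computed from the closed form
`E[apparent] = detected_true + (1 − dual) · p_dec · p_opposite` before
any simulation was run. `simulate_serum_transfer()` multiplies the
decoration probability by 0.5 by default, compressing the two stated
reasons short cold in-vitro incubation under-decorates (duration and
temperature) into one scalar.

# Problem sizes and runtime

The package's own checks use 20,000-cell repertoires for rate recovery
(3 binomial SDs of 2% at that size is ±0.30 percentage points, tight
enough to catch a biased caller), 10⁵ cells/draws for closed-form
agreement of the decoration expectation and the editing walk, 18
simulated controls of 5,000 cells — the cohort structure of the
flow-cytometry comparison — for the healthy calibration, and 1,000
random barcodes per run for oracle equivalence. The full suite runs in
under two minutes on one CPU.

# Known limitations

* The generator's inclusion categories are independent of isotype and
  subset; real editing history correlates with developmental stage.
* Decoration is all-or-none per cell with a single serum clone; partial
  coating and multi-clone decoration are not modelled (a configuration
  extension would add them).
* No compensation/spillover or background false positives in the flow
  model, as discussed above.
* IgG-isotype decoration is omitted: the observed decorating activity
  is predominantly IgM.
* `mann_whitney_u()`'s exact branch requires tie-free data; heavily
  tied small samples fall back to the corrected normal approximation.
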