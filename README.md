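# b2rscan

Detection of dual-antibody (dual light chain, "B2R") B cells in
single-cell immunoglobulin V(D)J repertoires, and a mechanistic model of
why flow cytometry can badly over-count them.

## The problem

A small fraction of human B cells escapes allelic/isotypic exclusion and
expresses two light chains (two kappa, two lambda, or one of each).
Measuring that fraction matters in systemic autoimmunity: some SLE
patients appear, by flow cytometry, to carry kappa+lambda+ B-cell
frequencies an order of magnitude above the healthy range. Single-cell
V(D)J sequencing tells a different story — the genuine dual-light-chain
rate is similar in patients and controls (~2% kappa/lambda, ~5% dual
overall). The discrepancy is explained by *decoration*: B-cell-reactive
IGHV4-34 (9G4) IgM autoantibodies in patient serum coat the B-cell
surface, so a kappa-expressing cell coated by a lambda-bearing serum
antibody stains double positive without expressing two receptors.

`b2rscan` implements both sides of this analysis as tidyverse-style R
functions:

* **Contig I/O** — `read_contigs()` / `write_contigs()` for the AIRR
  Rearrangement TSV and 10x Genomics `filtered_contig_annotations.csv`
  dialects; `write_clonotype_table()` for classified cells.
* **Clonotyping** — `assemble_cells()` groups contigs per cell barcode
  and applies the filtering rules: exactly one productive heavy chain,
  IgM/D or class-switched isotype (`classify_isotype()`), one or two
  called light chains with a UMI evidence threshold for secondary chains
  (`calling_params()`), the IGHV4-34 flag (`flag_vh434()`). Every
  analyzable cell lands in exactly one of five light-chain classes:
  `single_kappa`, `single_lambda`, `dual_kappa`, `dual_lambda`,
  `kappa_lambda`.
* **Repertoire statistics** — `summarize_repertoire()` (V usage, Jkappa
  usage, class fractions, CDR3 length), `high_kl_threshold()` (the
  control mean + 3 SD rule used to call patients kappa/lambda-high),
  `mann_whitney_u()` and `linear_regression()`.
* **Synthetic repertoires** — `generate_repertoire()` draws ground-truth
  cells and emits dialect-valid contig tables, with a receptor-editing
  walk (`sample_jk_with_editing()`) that skews the Jkappa usage of
  included cells toward distal segments, negative-binomial UMI noise and
  ambient contamination.
* **Decoration model** — `stain()` simulates kappa/lambda/9G4 surface
  staining under a `serum_profile()`; `apparent_frequencies()` applies a
  `gate_set()`; `simulate_cohort()` and `simulate_serum_transfer()`
  reproduce the patient-level readouts and the serum-incubation
  experiment; `run_end_to_end()` ties the stages into one reproducible
  run with a hashed manifest.

Results are tibbles (or small objects with `tidy()`/`glance()` methods),
so everything chains with the pipe; `plot_vh_usage()`,
`plot_jk_usage()`, `plot_flow_events()` and `autoplot()` give ggplot2
figures.

## Worked example

Simulate one subject, classify the repertoire, then stain the same cells
under a healthy serum and under a high-titer VH4-34 serum:

```r
library(b2rscan)

rep   <- generate_repertoire(generator_config(n_cells = 20000, seed = 7))
cells <- assemble_cells(rep$contigs)
summ  <- summarize_repertoire(cells, sample_id = "subject-01")
summ
#> <b2r_repertoire_summary> sample: subject-01
#>   cells: 20000  analyzable: 20000
#>   kappa+lambda+: 1.98%  total dual-LC: 5.11%  VH4-34: 4.84%
#>   switched: 19.9%  CDR3 length: 15.5 +/- 3.0 aa

apparent_frequencies(stain(rep$truth, healthy_serum(), gate_set(), seed = 8))
#>   n_events kl_apparent_pct g4_pct
#> 1    20000           0.715   3.88
apparent_frequencies(stain(rep$truth, sleh_serum(), gate_set(), seed = 8))
#>   n_events kl_apparent_pct g4_pct
#> 1    20000            31.8   63.6
```

Sequencing sees 1.98% genuine kappa/lambda cells either way. Under the
healthy serum the flow readout is 0.72% (secondary chains are only
detected at the surface ~35% of the time); under the high-titer serum
the *same cells* read out at 31.8% apparent kappa+lambda+ and 63.6%
9G4+, although nothing about their receptors changed — that is the
decoration confound. The Jkappa table of the same summary
(`summ$jk_usage`) shows the editing-driven distal skew, with IGKJ5 usage
well above its initial-rearrangement prior in unswitched cells.

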