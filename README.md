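# circuitseq

Genetic circuit characterization and debugging from strand-specific RNA-seq.

Synthetic transcriptional logic circuits fail in ways a fluorescent
reporter cannot localize: a single output distribution says nothing about
which internal promoter, terminator or insulator misbehaved, in which input
state. RNA-seq reads out every nucleotide of the circuit in every state at
once. `circuitseq` is for synthetic biologists who have such data (or want
to rehearse the analysis on simulated data): it converts strand-specific
fragment alignments into per-nucleotide transcription profiles, removes the
systematic coverage dip at transcript ends, and extracts quantitative part
and device parameters with small biophysical models.

## The model

The transcription profile M(x) counts sequenced fragments covering
nucleotide x (arbitrary units, au). At steady state the RNA-polymerase flux
past x is

    J(x) = γ · M(x),        γ = 0.0067 s⁻¹ (mRNA degradation rate)

and parts are quantified as localized changes in J with n = 10 nt averaging
windows at the part boundaries:

* promoter activity δJ = (γ/n)(Σ M downstream − Σ M upstream), background
  subtracted; for ribozyme-insulated promoters the downstream window sits
  just past the cleavage site,
* terminator strength Ts = (mean M before) / (mean M after), read-through
  ≈ 1/Ts,
* ribozyme cleavage efficiency p_c = 1 − (net flux before the cut)/(net
  flux after the cut),
* NOT/NOR gate response δJ_out = δJ_min + (δJ_max − δJ_min)·Kⁿ/(Kⁿ + J_inⁿ),
  fitted by log-scale least squares across circuit states; tandem promoter
  pairs are deconvolved from per-state combined activities.

Coverage near transcript ends is biased low because fragments cannot
overhang the transcript; a seeded Monte-Carlo model built from the
fragment-length distribution produces the correction factor profile C(x)
that restores flat coverage, with the closed form
min(x, L, N−x+1, N−L+1) as its analytic oracle. A forward simulator
generates complete multi-state experiments with known ground truth so every
estimator can be validated end to end.

## Worked example

Simulate a five-part circuit (promoter → ribozyme → gene → terminator →
downstream gene) whose ground truth is δJ = 2.01 au/s, Ts = 20, p_c = 0.9,
sample 2×10⁵ fragments, and run the measurement pipeline on the sampled
fragments:

```r
library(circuitseq)

parts <- data.frame(
  name      = c("Pdemo", "RzDemo", "gene1", "Tdemo", "gene2"),
  part_type = c("promoter", "ribozyme", "cds", "terminator", "cds"),
  start     = c(101L, 136L, 310L, 1620L, 1700L),
  end       = c(135L, 300L, 1600L, 1680L, 2800L),
  strand    = "+",
  cut_site  = c(NA, 285, NA, NA, NA),
  tss       = c(135, NA, NA, NA, NA))
ann   <- circuit_annotation(parts, "demo", 3000L)
truth <- ground_truth(
  promoter_activities = list(s1 = c(Pdemo = 2.01)),
  terminator_Ts = c(Tdemo = 20), ribozyme_pc = c(RzDemo = 0.9))
fl    <- fld(c(80L, 100L, 120L), c(0.25, 0.5, 0.25))

ex  <- simulate_experiment(ann, truth, "s1", fl, depth = 2e5, seed = 31)
rec <- recover_parameters(ex, "s1", reference_gene = "gene1", draws = 2e5)
print(rec$measurements, digits = 3)
#>     part state      metric  value    units filtered reason
#> 1  Pdemo    s1     delta_J  2.118     au/s    FALSE   <NA>
#> 2  Tdemo    s1          Ts 21.995     fold    FALSE   <NA>
#> 3 RzDemo    s1         p_c  0.916 fraction    FALSE   <NA>
#> 4  gene1    s1 antisense_J  0.000     au/s    FALSE   <NA>
#> 5  gene2    s1 antisense_J  0.000     au/s    FALSE   <NA>
```

The recovered promoter activity (2.12 au/s), terminator fold-drop (22.0)
and cleavage efficiency (0.92) sit within sampling error of the generating
truth; the antisense rows confirm no spurious minus-strand signal. A
bundled 46-part three-input logic circuit
(`example_circuit_annotation()`, `inst/extdata/circuit_synthetic.gff3`,
synthetic coordinates) exercises the full annotation → simulate → profile →
parts → devices pipeline; `run_pipeline()` or the thin
`inst/scripts/circuitseq` command-line wrapper orchestrate the same steps
over files with run metadata (seed, config hash) written beside every
output.

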