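# clonekinetics

Tools for cellular-barcoding studies of clonal competition in
oncogene-driven leukemia. The package covers the full computational side of
such a study:

- **Synthetic data** — degenerate barcode libraries (default: 32-nt
  cassettes, >80,000 sequences), transduced clone populations, stochastic
  in vitro culture drift with passage bottlenecks and sorts, and
  error-bearing 83-bp amplicon reads with Phred qualities, all seeded and
  byte-reproducible.
- **Barcode quantification** — FASTQ loading with per-record validation,
  mean-Phred filtering (Q>30), flank-anchored barcode extraction with a
  mismatch budget, and greedy count-ranked Hamming-distance error
  correction (`max_dist = 4`, `min_ratio = 10`) that conserves read counts
  and is idempotent.
- **Clonal statistics** — richness, fractional abundances, Shannon
  diversity, declarative monoclonal/biclonal dominance calls
  (`t_mono = 0.90`, `t_minor = 0.10`), and the ΔΔCt fold change
  `2^-ΔΔCt`.
- **Niche-competition model** — a single-cell stochastic model of
  hematopoietic tissue maintenance with a quiescent niche compartment `A`
  and a cycling compartment `Ω`. Each cell's attachment affinity `a`
  regenerates in `A` (×`r`/h) and attenuates in `Ω` (÷`d`/h); transitions
  occur with probabilities `α = (a/a_max)·f_α(N_A/N̄_A)` and
  `ω = (a_min/a)·f_ω(N_Ω/N̄_Ω)` (sigmoid crowding feedback, per-class
  leukemic modifiers); cells divide every 24 h in `Ω` and differentiate
  out below `a_min`.
- **In silico transplantation** — multinomial graft sampling, class-specific
  Beta-distributed engraftment affinities with a 48-h attachment window on
  an unconditioned steady-state host, a declared leukemia criterion
  (leukemic cells ≥ 20% of stem pool + output by the horizon), cohort
  aggregation over replicate recipients, and maximum-binomial-likelihood
  calibration of the free engraftment parameters against observed animal
  counts.

The scientific question the package addresses: why did two clones that made
up barely 1% of a barcoded BcrAbl graft produce monoclonal leukemias in a
minority of recipients at 10,000 transplanted cells, none at 1,000 cells,
and biclonal leukemias in all recipients once the graft was enriched? The
model's answer — implemented and tested here — is a low, clone-biased
per-cell engraftment probability: disease incidence follows
`1 − (1 − p)^n`, and the sampling lottery over ~100 driver cells decides
whether none, one, or both drivers engraft.

## Worked example

```r
library(clonekinetics)

# a barcoded experiment, end to end
lib <- generate_barcode_library(80000, barcode_pattern(), seed = 1)
pop <- simulate_transduction(lib, 158, seed = 2)
reads <- simulate_reads(pop, 30000, read_error_model(substitution_rate = 0.003),
                        seed = 3)
counts <- quantify_reads(reads, q_min = 30, max_dist = 4, min_ratio = 10)
counts
#> Barcode counts: 158 distinct barcodes, 29998 reads (0 filtered, 2 unextractable of 30000 total)
library_overlap(counts, lib)
#> Library overlap: 158 of 158 sample barcodes in library (100.0%)

# an in silico transplantation cohort with the shipped calibrated model
cfg <- shipped_config("calibrated")
cohort <- run_cohort(graft_d29(10000), cfg$engraftment, cfg$params,
                     R = 100, seed = 11,
                     horizon_days = cfg$horizon_days,
                     criterion = cfg$criterion)
cohort
#> Cohort 'd29_10000': 100 replicates
#>   no leukemia: 54.0%  monoclonal: 39.0%  biclonal: 7.0%  polyclonal: 0.0%
#>   leukemia incidence: 46.0%
#>   dominant clones:  A (13), A+B (7), B (25), bulk (1)
```

The quantification recovers exactly the 158 simulated clones — every
barcode the pipeline reports is a true clone, the two unextractable reads
carried too many flank errors, and all 158 recovered sequences are present
in the 80,000-barcode library (100.0%; on real data a fraction of clones
falls outside the sequenced library, e.g. 148 of 158 = 93.7%). The cohort
summary shows the outcome spectrum with the day-29 graft (clone A at
0.47%, clone B at 0.65%) and 10,000 cells: here 46 of 100 in silico
recipients developed leukemia (the marginal incidence over many cohorts is
about 37–40%), mostly monoclonal and dominated by clone A or clone B —
the composition observed in vivo.

Configurations are plain YAML (`inst/extdata/model-default.yaml`,
`model-calibrated.yaml`); `read_model_config()` / `write_model_config()`
round-trip them.

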