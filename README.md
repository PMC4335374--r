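# ampliphase

Minor-variant calling, per-molecule clonal phasing and splice-isoform
detection for single-molecule long-read (CCS) amplicon sequencing of fusion
transcripts — the analysis behind PacBio-based *BCR-ABL1* p210 resistance
monitoring in chronic myeloid leukemia, where each read spans the entire
1,578 bp amplicon and therefore represents one cDNA molecule.

Because one read = one molecule, the package can

* call point mutations (T315I, F359C, …, in clinical ABL1 codon numbering)
  down to sub-percent frequencies against a sequencing-error floor:
  a variant is emitted when its alternate count k at coverage n satisfies
  a Bonferroni-corrected one-sided binomial test
  P(X ≥ k | n, p₀) < α / (3L) against the per-alternative error floor p₀,
  plus minimum-frequency (0.5%) and minimum-count (10) guards;
* separate **compound** mutations (same molecule) from **independent**
  clones by recording each read's mutational signature, counting only reads
  whose 20 flanking bases around every variant site match the reference
  perfectly;
* detect splice isoforms (e.g. the recurrent 35 nt insertion between ABL1
  exons 8 and 9) from full-length reads, requiring at least two supporting
  molecules, with frame and truncation annotation;
* quantify assay sensitivity by simulating serial dilutions of clone
  mixtures with a CCS-like per-base error model and optional PCR-chimera
  generation.

It is a tidyverse-native package: every step takes a data frame and returns
a classed tibble, so stages chain with the pipe; results have
`tidy()`/`glance()` and `autoplot()` methods. The alignment core (banded
affine-gap semi-global DP with deterministic tie-breaking and left-aligned
indels) is implemented in C++ via Rcpp.

A fully synthetic ~1.6 kb reference mimicking the real amplicon
architecture (exon structure, published primer sites, anchored clinical
codon numbering) ships with the package, so everything below runs without
downloads. For real data, supply the real reference mRNAs in the same YAML
format.

## Worked example

Simulate a patient-like sample — a dominant T315I clone, a minor F359C
clone and residual wild type — then align, call, and phase:

```r
library(ampliphase)

amp <- toy_amplicon()                       # 1578 bp synthetic reference
t315i <- aa_substitution(amp, "ABL1", 315, "I")
f359c <- aa_substitution(amp, "ABL1", 359, "C")

clones <- list(
  clone_spec(0.90, mutations = t315i),
  clone_spec(0.06, mutations = f359c),
  clone_spec(0.04, label = "WT")
)
reads <- simulate_sample(amp, clones, n_reads = 5000, seed = 42)

aln <- align_reads(reads, amp)
glance(aln)
#> # A tibble: 1 × 6
#>   n_reads n_mapped pct_mapped n_full_length pct_full_length mean_identity
#> 1    5000     5000        100          5000             100         0.972

calls <- call_variants(pileup(aln))
calls[, c("position", "ref", "alt", "coverage", "frequency", "freq_adjusted", "label")]
#> # A tibble: 2 × 7
#>   position ref   alt   coverage frequency freq_adjusted label
#> 1      542 C     T         4287    0.877         0.889  T315I
#> 2      674 T     G         4226    0.0724        0.0692 F359C
```

`frequency` is the raw alternate-read fraction (inflated by ~0.4% of
sequencing error); `freq_adjusted` subtracts the estimated error floor and
recovers the simulated clone fractions (90% and 6%) within binomial noise.

Phasing shows the two mutations live in different molecules:

```r
sig <- read_signatures(aln, calls)   # perfect-20-flank rule per read
composition(sig)
#> # A tibble: 4 × 3
#>   signature     n_reads frequency
#> 1 "T315I"          1412    88.6
#> 2 "F359C"           115     7.22
#> 3 ""                 61     3.83
#> 4 "T315I+F359C"       5     0.314
attr(composition(sig), "pairs")
#> # A tibble: 1 × 6
#>   label1 label2 class       n_both n_only1 n_only2
#> 1 T315I  F359C  independent      5    1412     115
```

The 0.3% of double-positive reads are error-induced (a dominant-clone read
with a clean substitution error at the second site) and stay far below the
compound-call evidence bar; `chimera_diagnostic(sig)` reports them next to
the independent-assortment expectation.

One call runs the whole pipeline and writes TSV/VCF/JSON/FASTA reports:

```r
run_pipeline(run_config(
  reference  = system.file("extdata", "synthetic_reference.yaml", package = "ampliphase"),
  reads      = reads,
  output_dir = "results/sample1"
))
```

A thin command-line interface wraps the same functions
(`simulate | align | call | phase | isoforms | sensitivity | run`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","ampliphase",package="ampliphase"))') \
  run --reference ref.yaml --reads sample.fastq --out-dir results/sample1
```

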