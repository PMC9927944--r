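---
title: "Fine-mapping regulatory variants with MPRA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping regulatory variants with MPRA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpravar)
library(dplyr)
```

# The problem

Genome-wide association studies identify loci, not causal variants: a lead
SNP tags a haplotype on which dozens of variants travel together in linkage
disequilibrium (LD), and any of them may be the functional one. Massively
parallel reporter assays (MPRA) resolve this by testing each candidate
variant's two alleles for differential transcriptional activity. Every
candidate is embedded at the center of a short genomic fragment cloned
upstream of a reporter gene; each fragment copy is tagged with a random
barcode, and activity is read out as the abundance of each barcode in
reporter mRNA (cDNA) relative to the transfected plasmid pool (pDNA).

`mpravar` implements this workflow end to end: oligo design with full
allelic permutations, barcode-dictionary construction from association
reads, count normalization and filtering, per-fragment allele-specific
activity tests, and LD-based prioritization against lead GWAS SNPs. A
synthetic-data generator with known ground truth makes every stage testable
without sequencing data.

# Fragment design

Each variant is centered in a fragment whose variable region is 137 bp: the
variant base flanked by 68 reference bases on each side. When other
variants fall inside that window, one fragment is synthesized for every
combination of alleles (the Cartesian product over {ref} ∪ alts per
variant), so a window with *k* biallelic SNVs yields 2^k fragments,
including exactly one all-reference fragment that serves as the comparison
baseline for that window.

Decisions where the design space was genuinely open:

* **Window membership.** A neighboring variant joins a window when its
  reference span overlaps the 137 bp interval — a pure overlap rule, with
  no extra distance parameter to tune.
* **Indels.** Strict-SNV mode is the default: every allele must be a single
  base, so all variable regions are exactly 137 bp. With
  `design_params(strict_snv = FALSE)` indel alleles are substituted by
  reference span and the region length may differ from 137; the variant
  stays centered by its reference coordinate.
* **Explosion guard.** A window holding more than 6 variants stops with an
  error instead of silently emitting 2^k fragments;
  `max_variants_per_window` raises the limit deliberately.
* **Combination order.** Combinations enumerate deterministically: variants
  ordered by position, the reference allele first within each variant, the
  leftmost variant varying slowest — so the all-reference fragment is
  always combination 1 and reruns are byte-identical.
* **Coordinates.** Variant input is 1-based (VCF convention); internal
  windows are 0-based half-open; everything is handled on the forward
  strand. Adaptor sequences are configurable placeholders, since vendors
  prescribe their own cloning arms.

Fragments from different windows can be textually identical;
`dedupe_and_catalog()` collapses them, keeps every contributing fragment in
a `provenance` column, and appends the adaptors to form full oligos.

# Barcode dictionary

The association library links each random 16 bp barcode to the fragment it
tags. One mate of each read pair carries the barcode, the other the
fragment sequence; read layout (which mate, offsets) is configuration,
since it is a property of the library construct, not of the method.
Fragment segments are matched against the catalog exactly first, then by
Hamming distance with at most `max_mismatch = 2` substitutions, keeping
only unique best hits. Barcodes themselves are matched exactly — they are
random tags with no reference to correct towards.

A barcode observed with reads from two or more fragments is a template
switch or collision. The dictionary keeps such a barcode only when one
fragment accounts for at least 90% of its reads (`purity = 0.9`), otherwise
it is quarantined in an `ambiguous` table and never contributes activity.
A 50/50 split is therefore always ambiguous. The minimum read support per
barcode defaults to 1; both values are declared defaults rather than
inferred ones, and are single arguments away.

# Activity quantification

Counts are summarized per barcode and library, scaled to a common depth,
and log2 transformed:

    value = log2(count / library_size * scale + pseudocount)

with `scale = 1e6` (counts per million) and `pseudocount = 1`. Very low
normalized values behave like Poisson shot noise, so cells with a value
below the lower-end cutoff 0.5 are removed. The boundary is strict-below:
exactly 0.5 is retained. The cutoff applies per cell in pDNA and cDNA
alike, and a barcode's activity

    a = normalized_cDNA − normalized_pDNA   (log2 units)

exists only where the barcode survived in both members of a pair. When
several cDNA replicates are present, activities are pooled by averaging per
barcode (each barcode counts once); a `per_replicate` mode keeps them
separate. Activities are ascribed to fragments through the dictionary, and
fragments with fewer than 12 activity-bearing barcodes are excluded from
testing — 12, like the 0.5 cutoff, is an empirical operating point for this
assay family, and both are plain arguments.

# Allele-specific activity testing

Each variant-carrying fragment is compared with its window's all-reference
fragment by a two-tailed two-sample t-test on the barcode activities. The
default is the pooled-variance (Student) form; Welch's correction is
available behind `variant = "welch"`. Significance defaults to raw
p < 0.05; Benjamini–Hochberg q-values are an optional extra column and are
never silently substituted, because each fragment's barcodes are
independent measurements of one construct and the assay's convention is
per-construct calls.

A significant fragment carrying several variant alleles implicates all of
them — the assay cannot deconvolve a combinatorial construct — so
`summarize_variants()` reports, per variant, both any-construct evidence
and whether a *single*-variant construct was significant, and
`construct_class_counts()` tallies significant constructs as
single/double/triple both per fragment and per window.

# LD grouping and prioritization

Pairwise LD is computed directly from phased haplotype frequencies:
D = p11 − p1·q1, r² = D²/(p1(1−p1)q1(1−q1)), and D′ = D/Dmax with the usual
sign-dependent Dmax. Grouping is seed-anchored: each lead SNP starts a
group, seeds in mutual LD above the threshold merge (union-find), and every
other variant joins its best seed's group when that r² exceeds the
threshold (default 0.70, exceeded strictly). The threshold comparison
subtracts an epsilon of 1e-12 so that r² values equal to the threshold only
up to floating-point error — exact column duplicates at a threshold of 1.0
being the canonical case — count as exceeding it, while any genuinely
smaller value stays out. Variants linked to no seed remain ungrouped rather
than being forced into a partition.

`prioritize_variants()` then joins MPRA calls with group membership into
four strata: lead & significant, linked & significant, significant only,
and not significant — the order in which one would take variants forward to
functional validation.

Unphased genotypes are not accepted: phased input (or a 0/1 haplotype
matrix) is the contract, since two-locus EM phasing adds an estimation
layer the rest of the pipeline cannot audit.

# The synthetic-data generator

`sim_region()` emulates an intron-scale locus: by default a 58 kb
uniform-random sequence carrying 336 biallelic SNVs, most spaced at least
150 bp apart, with 15% planted 10–60 bp from another variant so the design
stage must emit combinatorial windows. `sim_mpra_libraries()` draws
barcodes per fragment as Poisson with mean 25 (the `default` profile; about
99.8% of fragments then clear the 12-barcode filter, matching the >98%
regime of a full-size library), plasmid counts as negative binomial (mean
60, dispersion 0.1 — Poisson-like at low counts but overdispersion-capable
for stress tests), and cDNA counts as Poisson around
`pdna_count · 2^(μ0 + Σδ + N(0, σ))` with σ = 0.3 log2 units, so the
expected per-barcode activity equals the fragment's true activity. Allelic
effects δ are additive in log2 space across the variant alleles a fragment
carries — the simplest model consistent with combinatorial constructs.
The `full_scale` profile raises the barcode regime to ~936 per fragment
(~1.5 million barcodes over ~1,600 fragments); the default profile is
deliberately about two orders of magnitude smaller so a full
design→dictionary→quantify→test cycle runs in seconds on one core.

What the generator does *not* emulate: transfection biology and cell-state
effects, sequencing quality decay along reads (errors are uniform
substitutions), barcode synthesis biases, PCR jackpotting, and real LD
ancestry structure (haplotype blocks are exchangeable flips around an
anchor). Passing tests on generator output therefore demonstrate the
pipeline's correctness and calibration under a faithful noise model, not
the biological reproducibility of any particular locus.

`sim_haplotypes()` builds block-structured haplotypes: within a block each
column is the anchor with entries flipped at rate (1 − sqrt(r²))/2, giving
pairwise correlation near sqrt(r²) at allele frequency 0.5; blocks are
independent.

# Numerical and degenerate-input behaviour

* Normalization errors on a zero-size library by name; zero counts are
  finite via the pseudocount.
* A t-test needs two barcodes per side; two constant equal groups return
  t = 0, p = 1 rather than NaN.
* Monomorphic loci make two-locus LD undefined and raise an error; D = 0
  defines D′ = 0.
* Ties in dictionary matching (two catalog fragments at equal Hamming
  distance) discard the read rather than guessing.
* All seeded generators produce byte-identical output per seed, and the
  design stage is deterministic end to end.

# A worked example

```{r example}
reg <- sim_region(length = 8000, n_variants = 10, seed = 42,
                  frac_close = 0.2)
frags <- build_fragments(reg$variants, reg$reference)
catalog <- dedupe_and_catalog(frags)
effects <- tibble::tibble(variant = reg$variants$id[1:2], delta = 1.0)
sim <- sim_mpra_libraries(catalog, effects, sim_profile(), seed = 43)
bm <- build_barcode_map(sim$reads, catalog)
glance(bm)

out <- run_mpra_pipeline(sim$counts, catalog, pairing = sim$pairing,
                         map = bm)
glance(out$results)
summarize_variants(out$results, catalog) |>
  filter(any_significant)
```

The flagged set recovers the two injected variants (plus, occasionally,
window partners of a true effect — the combinatorial attribution described
above). `autoplot(out$results)` draws the volcano plot;
`autoplot(bm)` the barcode-coverage histogram.

# Known limitations

* Fragment matching is catalog-restricted; reads from contaminating
  constructs can only be unmatched, never flagged as foreign.
* The per-window reference fragment is the sole baseline; there is no
  shrinkage across windows and no dispersion modelling, by design — the
  method is the assay's own t-test convention, not a count model.
* Combinatorial constructs implicate all their variants; deconvolution
  requires the single-variant constructs, which the per-variant summary
  surfaces but cannot manufacture.
* LD grouping depends on the haplotype panel supplied; with a panel from
  the wrong ancestry the groups are the panel's, not the study
  population's.
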