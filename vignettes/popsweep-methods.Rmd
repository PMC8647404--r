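---
title: "popsweep: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popsweep: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

# Scope

`popsweep` re-implements, as one tested toolkit, the computational chain of
a three-population whole-genome resequencing study: hard filtering of a
variant call set, SNP/InDel summarization, genomic-region and coding-effect
annotation, a windowed π/Fst selective-sweep scan with gene assignment,
PCA and neighbor-joining population structure, and 2^−ΔΔCt qPCR
quantification. It starts from a VCF (plus reference FASTA and GFF3); read
alignment and genotype calling are upstream of its scope. A synthetic-data
module generates every input with known ground truth, which is what the
test suite and the demonstration pipeline run on.

# The synthetic world

The generator emulates the sampling design of the motivating system — three
populations of 10 diploid individuals, two of them genetically close and
one diverged — with the Balding–Nichols model: per site an ancestral
alternate-allele frequency $p \sim \mathrm{U}(0.05, 0.95)$, per population
$k$ a drifted frequency

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F_k}{F_k},\;(1-p)\,\frac{1-F_k}{F_k}\right),$$

and diploid genotypes $\mathrm{Bin}(2, p_k)$ under Hardy–Weinberg
equilibrium. Balding–Nichols was chosen because it is simple and has the
closed-form calibration $\mathbb{E}[F_{ST}] \approx F$, which the test
suite verifies directly (genome-wide Hudson Fst within ±0.02 of $F = 0.1$
at 20 000 sites and 50 diploids per population). The default drift vector
$F = (0.02, 0.25, 0.03)$ for (AP, LP, SP) reproduces the published
topology: AP close to SP, LP distant.

Remaining defaults and their motivation, each fixed once:

* `snp_density = 0.002`/bp — a few hundred usable sites per 100 kb window,
  the order observed in mid-depth fish resequencing after filtering.
* `indel_fraction = 0.37` — the genome-wide InDel/(SNP+InDel) proportion
  implied by call-set totals of ~1.9 M InDels against ~3.2 M SNPs.
* `ti_prob = 0.56` — probability that a SNP is a transition, giving
  Ti/Tv ≈ 1.27 as printed for this kind of call set; a uniform alternate
  choice would give 0.5.
* InDel lengths 1–10 bp from a truncated geometric favoring length 1,
  matching the published length spectra where mononucleotide indels
  dominate; the exact distribution is not stated anywhere, so the simplest
  monotone one is used.
* `metric_fail_rate = 0.05` per metric — QUAL/QD/MQ/FS are drawn from their
  passing ranges with a 5% violating fraction so the filter module always
  sees both classes; only the thresholds, not the metric distributions, are
  published.
* `missing_rate = 0.01` missing genotypes, to keep every downstream stage
  honest about missing data.
* Sweeps are injected by resampling the target population's minor-allele
  frequency from $\mathrm{Beta}(0.02K, 0.98K)$, $K = 50$, mapped onto the
  major allele. Real sweep strength is a free parameter nowhere quantified
  in the source material; this default makes contained windows show
  Fst ≈ 0.3 against an $F = 0.05$ background — comfortably past the
  published thresholds without being a fixed difference.

What the generator does **not** emulate: linkage (sites are independent, no
coalescent or recombination structure), sequencing error, mutation-rate
heterogeneity along the genome, UTRs/alternative transcripts, and overlap
between genes. A green test therefore establishes that the estimators and
the calling logic are correct on HWE data of realistic density and drift —
not that the pipeline is robust to alignment artifacts or LD, which are
out of scope by construction.

# Filtering

The seven published hard-filter rules are applied with a fixed order and
first-reason reporting: (1) SNP within 5 bp of an InDel / InDel within
10 bp of another InDel, (2) more than 2 variants in any 5 bp window (all
members removed), (3) QUAL < 30, (4) QD < 2.0, (5) MQ < 40, (6) FS > 60.
The source lists the rules without an order, so one was fixed for
determinism; every rule is evaluated against the full input (not the
survivors of earlier rules), which makes the rule set order-independent in
its *membership* — order only decides which reason is reported. Proximity
is measured between VCF POS coordinates, the anchor point being otherwise
undefined. Records with an absent metric skip that metric's rule, and the
skip is logged.

# Summaries

Ti/Tv and the Het-ratio are reported **truncated** (not rounded) to two
decimals: the published count pairs are consistent with truncation but not
with rounding (e.g. 1 800 730/1 407 176 = 1.2797 printed as 1.27, and
968 651/3 176 204 = 30.497% printed as 30.49%). Zygosity is tallied per
sample-site genotype call carrying the alternate allele and summed over
samples; the published per-population numbers do not state their
aggregation, so this choice is documented rather than assumed unique.
Multi-allelic sites are split into biallelic records at the reader boundary
and everything downstream consumes split records; summaries are invariant
to pre-splitting (tested).

# Annotation

Regions follow the precedence CDS > splice donor/acceptor > splice region >
intron > intragenic > upstream/downstream > intergenic. Flanks are 5 kb and
the splice region is intronic bases 3–8 plus the 3 exonic bases at each
junction — the conventions of the annotation tool whose category vocabulary
the output tables use; both are configurable because the source states
neither. Coding effects mutate the codon on the coding strand under the
standard genetic code; InDel effects are decided after left-normalizing the
variant against the reference (codon alignment is meaningless on an
unnormalized indel). In-frame InDels that create a premature stop or remove
the terminal stop override to STOP_GAINED/STOP_LOST — the published InDel
table contains such rows without defining the rule, so the override is this
package's documented reading. Across transcripts one highest-severity call
is reported per variant, because the published tables count variants, not
transcript-effect pairs; the severity order is fixed in `popsweep:::.SEVERITY`.
Internally all intervals live in the 1-based closed convention of
`IRanges`, converted once at the VCF/GFF boundary and back to 0-based
half-open in BED-style outputs.

# Sweep scan

Windows are 100 kb sliding by 10 kb, full windows only. Per-site π uses the
unbiased pairwise estimator $2\frac{k}{n}(1-\frac{k}{n})\frac{n}{n-1}$ over
called alleles and the window π divides by the *full window length*
(monomorphic bases contribute zero), the per-bp convention of standard
windowed scans. Hudson's ratio-of-averages is the default Fst estimator —
robust to rare variants and standard for window scans; Weir–Cockerham is
provided for comparison, and no estimator is named in the source. Pi ratios
are oriented numerator = first-named population, so "AP vs LP" means
π(AP)/π(LP); a zero denominator with a positive numerator counts as above
the high threshold, two zeros make the window ineligible, as does
`n_sites < 10` (a noise guard not in the source, config-exposed).
Thresholds (Fst > 0.25, ratio > 2 or < 0.5) are applied to raw values as
printed, strictly; selected windows merge into maximal regions per
low-diversity population, and genes are assigned by ≥1 bp overlap.

# Structure

PCA drops monomorphic variants, imputes missing entries to the variant
mean, centers by $2\hat p$ and scales by $\sqrt{2\hat p(1-\hat p)}$, and
eigendecomposes the sample kinship matrix — the variance-standardized
convention of the standard SNP PCA tools. PC signs are fixed by forcing the
largest-magnitude loading positive. The NJ tree is built on allele-sharing
distances $d(i,j) = \mathrm{mean}\,|g_i - g_j|/2$ over shared called sites
(no distance is named in the source; allele sharing is the simplest
standard choice for dosage matrices), using the Saitou–Nei agglomeration of
the `ape` package; negative branch estimates are clamped to zero with the
deficit moved to the sibling edge so path lengths through the parent are
preserved. Bootstrap resamples variants (columns) — the natural unit when
samples are the taxa — and supports are percentages of replicates
containing each internal bipartition of the full-data tree; the published
"bootstrap 1000" does not state the unit, so this choice is documented
here. NJ is exact on additive matrices, which the tests exploit as a
closed-form oracle.

# Expression

The 2^−ΔΔCt chain averages technical triplicates, normalizes each sample by
the arithmetic mean of three housekeeping Cts — identical to normalizing
expression by their geometric mean under the method's own 100%-efficiency
assumption — and references ΔCt against the calibrator-group mean, so the
calibrator's geometric-mean RQ is exactly 1. The calibrator defaults to the
alphabetically first group and is configurable, the source not naming one.
Group comparison uses one-way ANOVA plus *unadjusted pairwise Welch tests*
with compact significance letters at α = 0.05; the original analysis used
Duncan's multiple-range test, which is underspecified here and statistically
disfavored, so this substitution is a deliberate, documented deviation.
Amplification efficiency is fixed at 2 with no correction.

# Numerical and degenerate-input conventions

* Truncation (floor) at two decimals for the reported ratios, as above.
* Fst may be negative and is reported raw; windows with ΣD = 0 are
  excluded from calling rather than forced to zero.
* Undefined Ti/Tv (no transversions) is `NA`, never `Inf`.
* All randomness flows from explicit integer seeds; the pipeline splits
  one root seed per stage, and rerunning any configuration reproduces
  byte-identical outputs (hash-checked in the tests).
* Cluster membership marks *all* members of an offending window, matching
  the behavior of the filtering tools the thresholds come from.

# Known limitations

No LD-aware sweep statistics (XP-EHH, iHS), no GO/KEGG enrichment, no
model-based clustering, no primer-efficiency estimation, no VCF writing
beyond the simulator's emitter. π and Fst are computed from biallelic
dosages; half-called genotypes are treated as missing. The annotation module
handles one level of gene → mRNA → exon/CDS and does not model UTRs or
canonical-transcript selection.
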