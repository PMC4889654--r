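---
title: "LD decay, Beta-distribution LD outliers, and selection screens for ddRAD SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD decay, Beta-distribution LD outliers, and selection screens for ddRAD SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Reduced-representation sequencing (ddRAD) of structured insect populations
— the motivating case is tsetse flies sampled from a handful of Ugandan
collection sites — yields tens of thousands of biallelic SNPs across
thousands of assembly scaffolds, typed in a few dozen individuals. Three
analysis needs recur with such panels:

1. **Cleaning.** Genotypes are unreliable at low read depth, sites and
   samples vary widely in call rate, and rare variants are dominated by
   genotyping error. A fixed cascade of depth, missingness and
   allele-frequency filters produces the working SNP set.
2. **Linkage disequilibrium (LD) structure.** Association studies need to
   know how fast LD decays with physical distance: it determines marker
   density and mapping resolution. With unknown and heterogeneous local
   recombination rates, pairwise `r²` is compared within narrow physical
   distance bins, and a smoothed decay curve summarizes the genome.
3. **Selection candidates.** With very small samples, Bayesian Fst outlier
   scans lack power. Unusually high LD is an orthogonal signature of
   selection, so SNPs that rank high in the external scan *and* sit in an
   LD-outlier pair are promoted to candidates, and genes near them are
   reported.

The package implements all three stages plus a synthetic-data generator
whose LD decay rate, population differentiation and planted signals are
known exactly, so every stage can be validated against ground truth.

# Models and estimators

## Filtering cascade

Order matters and is fixed: per-genotype depth mask, then site filters,
then the sample filter, then a re-pass that drops sites left monomorphic.

* depth: a genotype is kept only if `DP > 7` (strict; depth 7 is masked).
  The depth rule is applied as a *mask* — the site survives if its call
  rate, recomputed after masking, still clears the threshold. Whether to
  mask genotypes or drop whole sites is genuinely open with this kind of
  recipe; masking is the behaviour of the standard VCF tools and is what
  the tests pin down.
* sites: biallelic SNPs only (indels and multi-allelic records dropped);
  call rate at least 0.80 *and* missing fraction below 0.30 (both stated
  rules applied; the stricter binds); minor allele frequency strictly
  above 0.05, computed over non-missing calls only. Half-calls (`0/.`)
  count as missing.
* samples: individuals genotyped at fewer than 80% of surviving sites are
  removed ("at least 80%" keeps a sample at exactly 0.80). Sites that
  were polymorphic only in the removed individuals are then re-dropped.

## Diversity and differentiation

* Observed heterozygosity per individual is the heterozygous fraction of
  its non-missing genotypes; population values are means over members.
* Windowed nucleotide diversity sums the unbiased per-site estimator
  `2p(1-p)·n/(n-1)` (`n` = non-missing allele count) over SNPs in
  non-overlapping windows and divides by window length.
* Tajima's D per window uses the 1989 constants computed from `2N`
  sequences (unphased genotypes, random union of gametes), the
  pairwise-diversity estimator with each site's own allele count, and
  `S/a1`. Windows with no segregating sites are undefined. Two
  genome-wide averages are reported, because both conventions exist:
  counting undefined windows as zero ("all windows"), and averaging only
  SNP-containing windows. The two can differ by an order of magnitude;
  which one a given study reports is often unstated, so both are emitted.
* The exact Hardy–Weinberg test enumerates all heterozygote counts
  compatible with the observed allele counts and sums the probabilities of
  configurations no likelier than the observed one; flags are given after
  Bonferroni and Benjamini–Hochberg adjustment at 0.05.
* Weir–Cockerham Fst is computed from the per-site variance components
  `a, b, c` with unequal sample sizes. Both conventions are reported:
  the mean of per-site ratios, and the sample-size-correcting "weighted"
  ratio of sums `Σa / Σ(a+b+c)`. The pairwise population matrix carries
  the mean above the diagonal and the weighted estimate below it.

## LD decay

`r²` is the squared Pearson correlation of dosage vectors over
pairwise-complete samples — the genotype-based estimator appropriate for
unphased data. Pairs need at least 5 complete observations; zero-variance
pairs are dropped. Pairs are formed only within a contig, binned by
physical distance into half-open 50-bp bins (`floor(d/50)`), and the
per-bin mean `r²` is smoothed by count-weighted loess (degree 2) on bin
midpoints. `r²max` is the maximum of the *fitted* curve (the raw bin-mean
maximum is also reported), and the half-decay distance `d_half` is the
first crossing of `r²max/2` past the maximum, located by linear
interpolation on a 1-bp grid. If the curve never crosses within the
observed range, `d_half` is reported as undefined.

**Span choice.** The loess span is the one consequential smoothing
parameter. A span that averages over windows much wider than the decay
scale flattens the curve and systematically inflates `d_half`; on a pure
exponential the estimate converges to the analytic value as the span
shrinks. The default therefore selects the span from
{0.1, 0.15, 0.2, 0.3, 0.5} by the bias-corrected AIC of the
count-weighted fit; any fixed span can be forced. On noiseless
exponential input the selected fit recovers the analytic half-decay to
within ~4% (the residual bias comes from reading `r²max` at the first
observed bin midpoint rather than at distance zero, which is outside the
observed range).

## The Beta-distribution LD-outlier test

Within each distance bin, the `r²` values are bounded by 0 and 1, often
bimodal near both ends, and clearly non-Gaussian, so each bin is modeled
with a Beta distribution. Because empirical `r²` hits 0 and 1 exactly and
the Beta has open support, every value is first shrunk symmetrically about
0.5:

`x' = ((x − 0.5)·θ) + 0.5`, with θ = 0.999 by default,

which maps 0 to 0.0005 and 1 to 0.9995, preserves order, and is exactly
invertible. No jitter is added; the transform is the entire treatment of
boundary values. Shapes are estimated by maximum likelihood initialized
at the method-of-moments values (falling back to moments, flagged, if the
optimization fails). Each pair's upper-tail probability is
`p = 1 − CDF(x')` under its own bin's fit (the pair's value is included in
the fit; no leave-one-out). Bins with fewer than 10 pairs are merged with
the next bin upward before fitting, since the Beta MLE is unstable in
tiny samples; merged ranges are recorded.

Flags are assigned where the Benjamini–Hochberg-adjusted probability is
at most 0.01. The correction is applied **globally across all retained
pairs** by default, which makes the genome-wide flagged count a single
FDR statement; a per-bin scope is also implemented, because the
description of this procedure in the field is ambiguous between the two
readings. Under the null (pairs truly drawn from their bin's Beta) the
raw probabilities are uniform and the raw 1% line passes about 1% of
pairs — both properties are pinned by tests.

## Selection screen

The per-SNP `alpha` table of an external Bayesian Fst scan is parsed in
row order against the SNP list (a row-count mismatch is a hard error; the
external tool identifies loci only by index). The top fraction (default
10%) by alpha is taken, with boundary ties all included; ranking uses
signed alpha by default, with an absolute-value option, since either
convention is defensible for a diversifying-selection scan. Top SNPs that
are members of at least one flagged pair become candidates — both pair
members are eligible — annotated with their best partner. Genes from a
GFF3 track within 1000 bp of a candidate are reported with signed
distances (0 inside the gene, positive downstream, negative upstream);
the window is inclusive at exactly 1000 bp, and strand never affects
distance. Candidate sets from different comparisons can be intersected
to find shared outliers.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline is validated.

* **LD with a closed-form decay.** Haplotypes follow a copying chain on
  latent uniforms: the latent value at a site is copied from the previous
  site with probability `ρ^d` (`ρ` = retention per bp, `d` = inter-site
  distance) and redrawn otherwise; the allele is the indicator that the
  latent value falls below the site's population frequency. Marginal
  frequencies are exact by construction, and for equal-frequency sites
  the allelic correlation at distance `d` is exactly `ρ^d`, so expected
  `r² = ρ^(2d)` and the true half-decay distance is
  `ln 2 / (2 ln(1/ρ))`. This closed form is what makes decay estimation
  testable without an external simulator. A latent-uniform chain is used
  rather than copying allele values directly because value-copying with
  site-varying frequencies distorts the marginals (and with them the
  differentiation target); the latent construction avoids that entirely.
* **Structure.** Per-population site frequencies follow the
  Balding–Nichols construction: Beta-distributed around the ancestral
  frequency with variance `F·p(1−p)`, so the expected Weir–Cockerham Fst
  over many sites is the configured target. Ancestral frequencies are
  uniform on `[maf_floor, 1−maf_floor]` so that the MAF filter has
  survivors.
* **Planted signals.** High-LD pairs are planted by duplicating one
  site's alleles at a partner site ~2 kb downstream with 1% independent
  flips (near-unit `r²` without degeneracy). High-differentiation sites
  get alternating 0.05/0.95 population frequencies. The mock alpha table
  assigns the top ranks to all planted sites; the gene track places one
  gene near each planted anchor at offsets cycling through 0 bp (SNP
  inside the gene), 500 bp, and exactly 1000 bp, so the inclusive window
  boundary is exercised end to end. A tab-separated truth file records
  every planted identity and model parameter.
* **Noise.** Depths are Poisson (mean 40, matching a typical ~40×
  study); genotypes with depth ≤ 7 are *written anyway* — the depth
  filter under test must remove them. Missingness is per-genotype
  Bernoulli (default 5%).
* **Defaults.** Three populations of 16 diploids mirror a small
  multi-site ddRAD study design (a few dozen flies from three analyzable
  sites); 20 contigs of 10 kb at ~50 bp SNP spacing give ~4000 SNPs and
  ~300k within-contig pairs, large enough for stable per-bin Beta fits
  yet small enough that the full pipeline runs in seconds. Retention
  0.999/bp puts the true half-decay at ~346 bp, comfortably inside the
  observed distance range.

What the generator does **not** emulate: realistic demographic histories,
recombination hotspots, sequencing-error models, indels, multi-allelic
sites, linked selection, or any property of real tsetse populations.
Passing tests demonstrate that the estimators recover known truths under
a well-specified model — not that any particular biological dataset would
yield particular values.

# Numerical choices and degenerate inputs

* Validation sizes: oracle-equivalence tests run on ≤50-sample toys
  (exact, 1e-12) and 10-sequence windows (1e-9); decay recovery uses 200
  haplotypes on 10-kb contigs (~190k pairs); Fst recovery uses 2×50
  samples at ~5000 SNPs (tolerance 0.02 on a target of 0.2); Beta
  calibration uses 5000 draws for shape recovery (15% relative) and 10⁴
  pairs for null uniformity.
* Boundary conventions, all tested: depth 7 masked / 8 kept; sample call
  rate 0.80 kept; MAF 0.05 dropped; distance 49 in bin 0, 50 in bin 1;
  gene gap 1000 included, 1001 excluded.
* A site whose surviving calls are monomorphic has MAF 0 and is dropped;
  an all-sites-dropped filter result is a warning plus an empty matrix,
  not an error. Individuals with zero calls get `NA` heterozygosity.
  Monomorphic sites have HWE p = 1. Fewer than 4 sequences makes
  Tajima's D an explicit error; pairs below 5 complete observations are
  never formed.
* Essentially constant Beta input (variance < 1e-12) is represented by a
  sharply concentrated Beta at the mean and flagged as non-converged.
* Determinism: all generator randomness flows from the single seed in the
  configuration; the analysis pipeline itself contains no randomness, so
  identical inputs give byte-identical output trees (no timestamps are
  written).

# Known limitations

* The loess-based `r²max` is read at the smallest observed bin midpoint,
  not extrapolated to distance zero; with 50-bp bins this biases `d_half`
  upward by up to ~25 bp plus a sampling-noise floor of order `1/n`.
* Genotype `r²` (composite LD) rather than haplotype EM `r²` is used
  throughout; the two differ when genotypes are far from
  Hardy–Weinberg proportions.
* The Beta fit includes each pair's own value (no leave-one-out), so in
  very small bins a single extreme pair inflates its own null slightly;
  the minimum occupancy of 10 bounds this effect.
* Whether per-population Hardy–Weinberg testing should re-filter MAF per
  population is left to the caller: statistics are computed on whatever
  matrix subset is supplied.

# Running the pieces

```{r example}
library(ldscreen)

cfg <- sim_config(seed = 1)
panel <- simulate_haplotypes(cfg)
paths <- emit_fixtures(panel, "fixtures")

res <- run_all(run_config(
  vcf = paths[["vcf"]], out_dir = "results",
  popmap = paths[["popmap"]], gff = paths[["gff"]],
  alpha_table = paths[["alpha"]], comparison = "demo"))

res$ld$curve          # fitted decay curve, r2max, d_half
res$scan$summary      # flagged pairs after BH
head(res$report)      # candidates with genes and signed distances
```

A thin command-line front-end over the same functions ships in
`inst/scripts/ldscreen.R` with `simulate`, `filter` and `run-all`
subcommands.
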