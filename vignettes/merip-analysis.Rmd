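---
title: "Models and methods behind meripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`meripr` analyses m⁶A-IP sequencing (MeRIP-seq) experiments: an
antibody-enriched (IP) library is compared with a matched input library,
and regions where IP coverage exceeds the input-scaled expectation mark
methylated RNA. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data generator
does and does not emulate.

## Gene models and region segmentation

All transcript exons of a gene are collapsed into their interval union
(internally via `IRanges::reduce`), with internal coordinates 0-based
half-open; GTF/GFF3 input (1-based inclusive) is converted on read.
The union is segmented at the *outermost CDS boundaries over all
transcripts*: exonic bases 5′ of the outermost CDS start are 5′UTR,
bases between the outermost boundaries are CDS, bases 3′ of the
outermost CDS end are 3′UTR (strand-aware). Annotated UTR features are
deliberately ignored: conflicting per-transcript CDS/UTR annotations
(one transcript's CDS overlapping another's UTR) make a feature-union
definition ambiguous, while the outermost-CDS rule is deterministic for
any annotation dialect and guarantees that 5′UTR + CDS + 3′UTR lengths
partition the exonic bases exactly.

Genes enter the metagene analysis only if both UTRs are present and at
least `min_utr = 30` bp and the CDS is at least `min_cds = 100` bp;
genes with no CDS (lncRNAs) are excluded. Exclusion reasons are assigned
in the fixed order `missing_utr`, `utr5_short`, `utr3_short`,
`cds_short`, so reports are reproducible when several rules fail.

## Metagene binning and enrichment

Each 5′UTR and 3′UTR is tiled in 30 and the CDS in 100 evenly spaced
bins on the spliced transcript axis. When a region length is not
divisible by its bin count, the first `length %% n` bins in transcript
orientation are 1 bp wider — a deterministic remainder rule; widths
never differ by more than 1 bp. A read increments **every** bin whose
genomic footprint it overlaps by ≥ 1 bp (overlap counting, not
fractional apportionment), the counting unit is the aligned read, and
paired mates count independently. Intron-only alignments count nowhere.

Normalisation is `value = count / bin width / library size × 10⁶`
(a reads-per-million-per-bp). Because the width divides out, uniform
per-base coverage yields identical values in all 160 bins regardless of
the uneven widths — a property the test suite asserts to 1e-9 relative.

Enrichment matrices sum replicate raw counts per bin within each sample
type, renormalise with the summed library sizes, and take the ratio
`(IP + pc) / (input + pc)`. Summing counts before division (rather than
averaging per-replicate ratios) weights replicates by depth. The
pseudocount `pc = 0.25` guards zero-input bins; it is configurable and
recorded on the result. Genome-browser tracks are per-base
`log₂((IP_cpm + pc)/(input_cpm + pc))` written as bedGraph.

## Peak calling

For every 50-bp window over the spliced exonic bases, the IP count *x*
is tested against the input count *y* with a one-sided binomial test:
under no enrichment, `x ~ Binomial(x + y, L_IP / (L_IP + L_input))`
where the *L* are library sizes. P-values are BH-corrected across all
non-empty windows; maximal runs of adjacent significant windows merge
into peaks carrying the pooled enrichment and minimum adjusted p.
Reported peaks must also reach `min_enrichment = 2` pooled fold
enrichment — the customary fold-change requirement of MeRIP peak
callers. Without it, each isolated null window that reaches BH
significance (an expected handful at FDR 5% on thousands of windows)
would surface as a spurious single-window peak; with it, the planted
recovery tests run at ≤ 5% spurious calls while sensitivity to planted
8-fold peaks is unaffected. Peak calling is fully deterministic.

A peak is assigned to the region holding the largest exonic share of
its span; exact ties go to the fixed priority 5′UTR > CDS > 3′UTR
(configurable), reflecting the 5′UTR-dominant biology of the system the
package targets.

## Differential methylation

For every window, each replicate's methylation level is
`m = log₂((IP_cpm + pc)/(input_cpm + pc))`, pairing replicate *r*'s IP
with replicate *r*'s input. Treatment and control are compared with a
two-sample t-test on these levels; `beta` is the mean difference
(treatment − control), i.e. a log₂ fold change of enrichment. Windows
whose summed raw IP count is below `min_count = 15` in either condition
are excluded before testing, and BH correction runs across the tested
windows only. A window is *dependent* (methylation lost in knockdown)
iff adjusted p < 0.05, |beta| ≥ 0.5, and the log₂ fold change is below
−1 from control to knockdown; the fold-change direction convention is a
documented flag (`direction`), as is its log scale (`lfc_cutoff` on
log₂). Genes with ≥ 1 dependent window form the m⁶A gene set — the
aggregation rule is deliberately the simplest one and is documented
rather than inferred.

The default statistic is the **pooled-variance** Student t with
`nT + nC − 2` degrees of freedom, not Welch. The reason is numeric, not
philosophical: with three replicates per condition, the
Welch–Satterthwaite degrees of freedom can collapse towards 2 whenever
the two sample variances are unbalanced, and with df ≈ 2 even t = 30
gives p ≈ 1e-3 — a floor that BH correction across ~2,000 windows can
never clear, capping sensitivity regardless of effect size. The pooled
statistic keeps df = 4, lets replicate variability enter the test, and
is available to switch back via `var_equal = FALSE`. With two
replicates per condition either test is severely underpowered; three or
more are recommended. Windows with zero variance in both conditions get
p = 1 when beta = 0 and p = 0 otherwise.

## Set statistics and motif surrogate

DE tables are classified at adjusted p < 0.05: `up` and `down` by the
sign of the log₂ fold change, `ns` otherwise (a significant gene with a
fold change of exactly 0 has no direction and stays `ns`). The skew
test builds the 2×2 table of class membership × direction **among
significant genes** and computes the one-sided Fisher p for
over-representation of `up` in the class; an alternative margin
(class-up against the rest of the universe) is exposed behind the
`margin` flag since the table construction is a genuine design choice.
The overlap test is the one-sided hypergeometric `P(X ≥ overlap)`; its
universe defaults to all genes with detectable expression. Both tests
are computed as vectorised hypergeometric upper tails
(`fisher_p_greater()`), which the test suite checks against exhaustive
factorial enumeration on every 2×2 table with margins ≤ 30 and against
`stats::fisher.test` on random tables.

Motif discovery is out of scope; the surrogate scores every k-mer of
lengths 5–7 by a presence/absence 2×2 (sequences containing the k-mer,
peak vs background) with the same one-sided test and BH correction.
Presence/absence rather than occurrence counts keeps the 2×2 exact.
Backgrounds are length-matched per peak and drawn uniformly from the
peak-free exonic space of expressed genes (peaks subtracted exactly; a
flanking buffer is configurable and defaults to 0 bp), deterministic
under a seed; minus-strand sequences are reverse-complemented.

## qPCR and RNA decay

ΔΔCt: per sample `ΔCt = Ct_target − Ct_reference`, then
`ΔΔCt = mean ΔCt(treated) − mean ΔCt(control)` and
`fold = 2^(−ΔΔCt)`; the fold change is invariant to any constant added
to all Ct values. Decay series are fit by least squares of
`log N(t) = log N₀ − k t` — deterministic and closed-form, which is
adequate for 4–5 timepoints; both a free intercept (default) and
`N₀ = 1` fixed (`fix_n0 = TRUE`, regression through the origin on the
log scale) are exposed since data normalised to a no-drug control at
t = 0 motivate either convention. A fitted k < 0 is returned flagged
`no_decay` with an undefined half-life rather than silently clipped.
The fraction remaining at 4 h is `e^(−4k)` in fit mode or the measured
ratio in raw mode, and genotypes are compared with a pooled two-sample
t-test.

## The synthetic data generator

The generator emulates the study design the analysis assumes: 200 genes
by default (UTRs 60–600 bp, CDS 300–3,000 bp, uniform), one chromosome
per 25 genes, 0–2 introns per gene, 1–3 transcripts sharing a CDS core;
three replicates per library; mean input coverage 30×; single-end 50-bp
spliced reads. A fraction (default 0.15) of filter-passing genes
carries one planted peak (default 100 bp), placed wholly within a
region drawn with weights (0.9, 0.07, 0.03) for (5′UTR, CDS, 3′UTR) —
echoing the 5′UTR-dominant biology without hard-coding any reported
percentage. Planted IP enrichment is 8-fold; knockdown collapses
dependent peaks to 1-fold; heat shock multiplies 5′UTR peak folds by
1.5, a deliberately modest boost matching a "slight" global increase.
IP read-start weights take the value γ when the read's *centre* falls
in a peak, so coverage is ≈ γ inside the peak with ramp zones of half a
read length at the edges. DE tables draw each gene significant with
probability 0.5 and upregulated with probability 0.8 (modified) vs 0.4
(other); null genes draw adjusted p uniformly *above* 0.05 so the truth
composition is exact. Decay half-lives default to 1 h (control) vs 4 h
(knockdown) for modified transcripts, with 10% lognormal noise and six
replicates over timepoints 0, 0.5, 1, 2, 4 h.

What the generator does **not** model: sequencing errors and quality
scores, fragment-size distributions, alignment ambiguity, paired-end
fragments, overdispersion beyond Poisson counts, isoform-level effects,
or boundary-spanning peaks (unless configured). Passing recovery tests
therefore demonstrates correctness of the statistical machinery under
the stated generative model, not robustness to every artefact of real
libraries.

## Problem sizes and determinism

The shipped tests exercise the pipeline at desk scale — 40–200 genes,
30× depth, 20-seed recovery batches, 1,000-run null calibrations —
sizes chosen so the whole suite completes in minutes on one CPU while
keeping planted-recovery margins interpretable. Every random step takes
an explicit seed (`withr::with_seed` internally), and the end-to-end
pipeline writes byte-identical outputs across runs of the same seed.

## Known limitations

The peak caller and differential test are transparent surrogates; they
honor the published thresholds (bin count 15, cutoff 0.05, beta cutoff
0.5, fold change < −1) but are not expected to reproduce the numerical
output of HMM- or random-effect-based callers on real data. Gene-level
aggregation is presence-of-any-dependent-window; no multi-chromosome or
trans-spliced genes; no single-nucleotide resolution; no
amplification-efficiency correction beyond ΔΔCt.
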