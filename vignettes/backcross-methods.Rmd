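---
title: "Methods: allele-specific expression and eQTL mapping in a mouse backcross"
author: "aseqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression and eQTL mapping in a mouse backcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseqtl)
```

# The experimental design this package models

Two inbred mouse strains — C57BL/6J ("B6") and CAST/EiJ ("Cast") — differ at
roughly one SNP every 120 bp. Crossing them yields F1 hybrid embryos that are
heterozygous B6/Cast at every autosomal locus; backcrossing (B6 x Cast)F1
animals to B6 in reciprocal directions yields N2 embryos that are B6/B6 or
B6/Cast at each locus, with the maternal genotype differing by cross
direction (F1 mother versus B6/B6 mother) while every N2 embryo carries B6
mitochondria. 3'-biased RNA-seq of whole embryos, with reads mapped against
both parental genomes, gives two kinds of measurement per gene and embryo:

* **total expression** — exon-overlapping read counts, normalized to reads
  per million (RPM), and
* **allele-specific votes** — fractional read votes for the B6 or Cast
  allele from reads covering strain-distinguishing SNPs, summarized as the
  B6 allele fraction, BAF = B6 votes / (B6 + Cast votes).

Four genetic mechanisms leave distinct signatures in these measurements, and
each has a dedicated testing module:

| mechanism | signature | test |
|---|---|---|
| cis-regulatory variation | BAF away from 0.5 in heterozygotes, same in both cross directions | paired t-test on library-normalized allelic differences |
| imprinting | BAF bias that flips between reciprocal crosses | pooled binomial test with opposite-direction requirement |
| maternal effect | total expression depends on the mother's genotype class | Mann-Whitney U between maternal classes |
| cis/trans eQTL | total expression depends on the embryo's genotype at a marker | Wilcoxon rank-sum per (gene, marker region), permutation FDR |

# Allele votes and the read-level filters

Reads are preprocessed by a quality-weighted poly(A) trimmer: for each
candidate number of kept bases, the removed suffix scores the sum of the
quality values of its A bases minus three times the quality values of its
non-A bases, and the highest-scoring cut is applied if it removes at least
three bases (ties keep more bases; N counts as non-A). Candidate alignments
are filtered by an edit-distance margin — if the second-best alignment at a
different genomic position is within 3 edit-distance units of the best (1
per mismatch, 2 per indel), or equally good alignments disagree on the
genomic position, the read is discarded; equal-best hits that project to
the same genomic locus (e.g. a spliced-transcript hit and its genomic
counterpart) are consolidated.

A read covering n usable SNPs contributes 1/n vote per SNP to its gene's
B6, Cast or "other" tally, which tolerates occasional sequencing errors at
SNP positions. Usable SNPs are high-quality calls at least 50 bp from any
annotated Cast indel. "Other" votes are excluded from the BAF denominator.

Gene-level analyses use genes with mean expression of at least 5 RPM, at
most 5% of reads removed by the ambiguity filter, no retrogene-list
membership, and autosomal location. Embryo sex is called by 2-means
clustering of Xist RPM (females express it robustly, males barely); when
the two cluster means are not separated at least fourfold the distribution
is treated as unimodal and all embryos are returned as unknown.

# Genotyping sparse allele votes

N2 genotypes are inferred from the votes themselves. A gene with at least
20 informative votes gets a preliminary call: homozygous when the B6
fraction is at least 0.9, heterozygous otherwise (with a per-vote error
rate around 0.002, the two classes' binomial distributions are separated
at 100 votes with error below 1e-6; the paper-stated 20-vote floor keeps
errors rare while covering most genes). A two-state hidden Markov model
then smooths each chromosome per embryo: known calls are emitted by the
matching state with probability 1 − epsilon (default epsilon = 0.02,
matching the homozygous vote error scale), unknown genes emit uniformly,
and switching state costs probability t per gene step (default 1e-4,
chosen so that false breakpoints per chromosome are rare at realistic
coverage). Inter-gene distances are ignored because no genetic-distance
model is available at this resolution. Viterbi decoding yields a single
best path; genes with few votes lying between the confident calls that
flank a breakpoint are reset to unknown, since they carry no evidence for
either side.

Adjacent genes with compatible genotype vectors across all embryos are
merged into marker regions; with a recombination budget of zero this makes
region boundaries exactly the union of per-embryo breakpoints. The
consensus genotype per (region, embryo) is the majority call; when
homozygous and heterozygous calls are nearly tied (difference of at most
one, and neither side unanimous) it is unknown. We deliberately keep
unanimous single-gene regions callable — a region supported by one
confident call is evidence, not a tie.

# The statistical tests

**ASE.** For each embryo heterozygous at a gene, d = (Cast votes − B6
votes) / library size × 1e6; a one-sample t-test asks whether the d values
deviate from zero across the pooled F1 + N2 heterozygotes. This weighs
deeply sequenced F1s and shallow N2s on a common scale. Significance
requires Bonferroni p < 0.01 over tested genes (≥3 contributing embryos)
and a mean BAF outside [0.45, 0.55]. On null simulations the test is
nominal-to-conservative, consistent with its described behavior relative
to resampling.

**Imprinting.** Votes of heterozygous embryos are pooled within each cross
direction. Under no parent-of-origin effect, the expected maternal-allele
fraction is determined by the gene's direction-pooled B6 fraction (which
controls for cis effects); the pooled maternal-allele count is tested
against it with a two-sided binomial test, and significance additionally
requires the two directions to deviate in opposite allele directions.
Fully imprinted genes land at cross differences near ±1, cis-biased genes
near 0.

**Developmental trends.** Spearman correlation of BAF (heterozygotes, ≥10
embryos spanning ≥5 somite stages) or of RPM against somite count, with
Benjamini-Hochberg q-values (q < 0.10 for allelic trends, q < 0.05 for
total expression).

**Maternal effects.** Two-sided Mann-Whitney U on RPM between B6-mother
and F1-mother N2 embryos, Bonferroni-corrected over tested genes. The
confound battery re-tests each hit within female embryos, on litter means,
within somite tertiles (direction must agree), and against embryonic
genotype at each supplied imprinted locus — a smaller rank-test p for any
locus genotype grouping than for the maternal grouping flags a candidate
trans effect downstream of imprinting. The mitochondrial confound is
excluded structurally: the design requires every N2 cross to have an
(B6 x Cast)F1-derived or B6 parent arrangement, which `validate_mitochondrial_design()`
asserts on the metadata rather than testing statistically.

**eQTL.** Expression is normalized by regressing log(RPM + 1) on sex,
sequencing batch and somite count (missing somite counts mean-imputed),
then removing the top k principal factors of the residual matrix (default
k = 5). This linear covariate + hidden-factor residualization is this
package's own normalizer standing where factor-analysis tools are commonly
used; the scan conclusions are not sensitive to the choice, though broad
coherent trans effects can be absorbed by the factors — hence the hotspot
analysis below runs with k = 0. Each (gene, marker region) pair is tested
by a two-sided Wilcoxon rank-sum between heterozygous and homozygous
embryos (computed via the tie-corrected, continuity-corrected normal
approximation, which matches `wilcox.test(exact = FALSE)` and keeps the
genome x marker scan fast); only the most significant marker per
chromosome per gene is retained, and cis means the marker sits on the
target gene's chromosome. FDR comes from permutations: one global embryo
relabeling per round, applied within each marker's genotyped embryos so
missingness patterns (and cached ranks) are preserved, with
q(p) = [(1 + total permuted records ≤ p)/(B + 1)] / (observed records ≤ p),
monotonized in p. The add-one pseudocount keeps a finite permutation set
from reporting an unsupported q of exactly zero.

**Hotspots.** Per marker, the number of target genes with scan p < 0.005
is compared between the observed scan and the pooled permutation scans by
a two-sample Kolmogorov-Smirnov statistic. Because per-marker counts are
strongly dependent — one gene's chance association reaches every
correlated marker on a chromosome — the asymptotic KS p is
anticonservative; the reported p is therefore permutation-calibrated (the
observed KS statistic is ranked among each permutation scan's own KS
statistic against the pooled null), which is exact under the null and
bounded below by 1/(B + 1).

**ASE/eQTL concordance.** With mu_hom and mu_het the mean total expression
of B6/B6 and B6/Cast embryos, BAF_exp = mu_hom / (mu_hom + mu_het) and
BAF_pred = BAF_exp / (2 (1 − BAF_exp)) predicts the measured BAF from
total expression alone: 0.5 when the classes express equally, 1.0 in the
Cast-silent limit (mu_het = mu_hom / 2), and above 1 when sampling noise
pushes BAF_exp past 2/3. Spearman correlation against vote-measured BAF is
reported overall and for the 1,000 genes with the deepest allele-specific
coverage.

**Conservation.** A Spearman test between an externally supplied per-gene
conservation score and regulatory effect size (−log10 scan p or
|BAF − 0.5|), after removing genes under an expression floor (lowly
expressed genes are enriched for low scores). The package consumes scores;
it does not compute them.

# The synthetic backcross generator

`simulate_backcross()` emulates the study design so every stage can be
verified by parameter recovery: 8 + 8 F1 embryos from reciprocal crosses
and 65 + 89 N2 embryos (F1 x B6 and B6 x F1), 19 autosomes, somite counts
uniform on 42–57, and embryos multiplexed into sequencing pools of 12.
Recombinant gametes use a Poisson crossover count per chromosome (mean =
map length in Morgans), uniform crossover placement and no interference —
the simplest model that produces the observed block structure. The default
map length of 0.35 Morgans per autosome is a calibration: it makes 154 N2
embryos yield on the order of a thousand recombination-delimited marker
regions, the scale reported for real data of this design. Counts are
negative binomial (default dispersion 0.05, a typical inbred-cross
biological replicate value; 0 gives Poisson) around library size x
baseline RPM, with log-normal library sizes, multiplicative log-normal
per-(batch, gene) effects (sd 0.1), and multiplicative cis / imprinting /
maternal / developmental / trans-hotspot effects from the truth ledger.
Allele votes are binomial: SNP-covering reads are a binomial thinning of
the gene's count (default fraction 0.3 — 3'-biased protocols concentrate
reads on SNP-dense 3' UTRs; the per-gene depth distribution is exposed as
a knob because no canonical value exists), B6 votes are binomial in the
gene's allele-weight BAF, homozygous embryos vote B6 at 1 − 0.002, and a
1% "other" vote rate exercises the vote-mass accounting. Batch membership
is randomized within generation, as in a multiplexed design; assigning
pools in collection order would confound batch with cross direction and
manufacture spurious maternal effects.

What the generator does **not** emulate: reference-mapping bias (votes are
generated symmetrically; the real pipeline removes the bias by dual-genome
alignment), sex chromosomes and mitochondria (the analysis is
autosome-restricted), read-level errors beyond the flat vote error, linked
cis effects sharing a haplotype, and litter-level biological variance
beyond what maternal/batch effects induce. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every artifact of real libraries.

# Problem sizes and numerical choices in the verification suite

The test suite runs the trimmer against an exhaustive enumeration oracle
on 10,000 random reads, and the Viterbi decoder against brute-force path
enumeration on a 1,000-instance battery of chromosomes up to 20 genes
(comparing achieved log-likelihoods, so ties between equally likely paths
are not spurious failures). Null calibration uses 20 all-null replicates
at the full design size (about 2,000 genes, 154 N2 embryos, 20
permutations); recovery uses 50 cis effects of fold 2, 20 maternal effects
of fold 1.5 and 5 fully silenced imprinted genes in one dataset. The
hotspot check plants one controlling locus driving 30 trans targets at
fold 1.3; it uses a two-autosome genome (1,000 genes) with a 0.7-Morgan
map and 150 permutations, a geometry chosen by design analysis: the
hotspot chromosome must hold a large share of markers for the count-
distribution shift to dominate the KS statistic, while the longer map
decorrelates markers so the null KS spread stays small. Concordance uses
1,000 genes at roughly 100 allele votes per heterozygous embryo. Degenerate
inputs are defined away or reported as NA: BAF is undefined below one
informative vote, genes with fewer than three contributing embryos are
untested (and excluded from Bonferroni denominators), chromosomes without
a confident call decode to unknown, and a monomorphic marker is skipped.

# Known limitations

* Viterbi point estimates only; no posterior genotype probabilities.
* The imprinting test is a reconstruction around "binomial test": pooled
  per-direction maternal-allele counts against the cross-pooled allele
  fraction. Per-embryo alternatives would weight deep embryos less.
* The permutation FDR uses 20 global permutations by default — adequate
  for q thresholds down to about 1/(B+1) per stratum, not for very small
  q claims.
* The hotspot KS test has limited power for localized hotspots on
  many-chromosome genomes at desk scale; the calibrated p is honest but
  conservative there.
* `run_pipeline()` operates on synthetic datasets end to end; real-data
  ingestion goes through the exported per-stage functions on the
  documented TSV/VCF/BED formats.
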