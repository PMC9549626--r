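---
title: "Annotating a bacterial primary transcriptome with tssops: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a bacterial primary transcriptome with tssops: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssops)
```

This vignette is the package's own account of the science it implements: the
models and procedures, the parameters that matter and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the problem was genuinely
open.

## The measurement being modeled

Bacterial primary transcripts carry a 5′-triphosphate; processed RNAs carry a
5′-monophosphate. Enrichment protocols (Cappable-seq, dRNA-seq) exploit this
to capture transcript 5′ ends: in an enriched library, read starts pile up
sharply at transcription start sites (TSS), while an unenriched control
library distributes starts more evenly. The package's central contrast is
therefore between two per-base, per-strand read-start profiles of the same
replicon — one enriched, one control — each carrying its library's
total-mapped-read count for depth normalization.

Coordinates are 1-based inclusive throughout (the GFF3 convention, since the
genome annotation is the coordinate authority); bedGraph's 0-based half-open
frame is converted at the I/O boundary. The replicon is treated as circular
by default, so upstream windows wrap across the origin; a flag disables this
for linear sequences, in which case truncated windows are flagged and (for
motif work) dropped. A read's start is the coordinate of its 5′-most base on
its own strand, i.e. the alignment end for minus-strand reads.

## TSS calling

For a profile with total mapped reads $N$, the relative read score at a base
is $\mathrm{RRS} = c/N \times 10^6$ (reads per million). The calling statistic
is

$$\mathrm{score} = \log_2 \frac{\mathrm{RRS} + pc}{\mathrm{RRS}_{ctrl} + pc}$$

* **Threshold, default 2.5 on the log2 score.** The threshold is interpreted
  in log2 space because that is the space in which the score is defined. The
  phrase "enrichment factor" is sometimes used for the linear ratio, so the
  caller exposes `threshold_space = "linear"`, which cuts the score at
  `log2(threshold)` instead; both readings are runnable and the choice is
  recorded in the call.
* **Pseudocount, default 0.5 RPM.** Control libraries are sparse; a zero
  control count would make the ratio infinite. A symmetric pseudocount on
  both terms bounds the score, vanishes for strong signals, and keeps the
  antisymmetry property score(a,b) = −score(b,a).
* **RRS floor, default 1 RPM.** A single stray read at an uncovered position
  can carry an arbitrarily large score; requiring a minimal enriched RRS
  suppresses these one-read artifacts. At a typical library size of a few
  million reads this corresponds to a handful of reads.
* **Cluster window, default 5 bp.** Transcription initiation is locally
  fuzzy; candidates within 5 bp on the same strand are merged to the
  candidate with maximal RRS, ties resolved to the smaller coordinate so the
  result is deterministic. Merging is transitive (chains of candidates with
  gaps ≤ 5 bp form one cluster). A consequence worth knowing: the number of
  *clustered* calls is not strictly monotone in the threshold, because
  removing a mid-cluster candidate can split a cluster in two; the candidate
  set itself is monotone, and the test suite asserts exactly that.

Cross-condition comparison matches same-strand TSS greedily by distance
within a tolerance (default 3 bp, each TSS used at most once); TSS without a
partner are condition-exclusive.

## TSS classification

Classes are assigned with the precedence pTSS > iTSS > asTSS > oTSS:

* **pTSS**: same strand, 0–300 nt upstream of a gene's translation start
  (TLS). The window default of 300 nt is chosen to cover the long-5′-UTR
  regime (up to 300 nt, see below); shrinking it can only reduce the pTSS
  count. The closest TLS wins; ties go to the smaller gene start. A TSS lying
  *inside* the upstream gene of an operon is still a pTSS for the downstream
  gene — this is what lets internal promoters anchor sub-operons.
* **iTSS**: within a same-strand gene body.
* **asTSS**: within an opposite-strand gene body extended by a 100 nt margin
  on both sides. The margin is a design choice (antisense regulation
  plausibly extends past gene ends); it is configurable.
* **oTSS**: everything else.

Every TSS receives exactly one class, so class counts partition the call set.

## Promoter and RBS motif discovery

Windows of 70 bp upstream of each pTSS (reverse-complemented on the minus
strand so all windows read into the TSS) are searched for the two-box σ⁷⁰
architecture; 20 bp windows upstream of each TLS are searched for the
ribosome binding site.

The motif model is a ZOOPS (zero-or-one occurrence per sequence) finite
mixture: each window either contains one motif occurrence at a uniformly
distributed offset or none, against a 0-order background estimated from the
input windows. Fitting is by EM:

* The E-step computes the posterior over offsets and absence; the M-step
  re-estimates the position weight matrix with Dirichlet(0.25) pseudocounts
  and the occurrence probability.
* Because of the smoothing this is MAP-EM: the quantity that provably never
  decreases is the *penalized* log-likelihood (log posterior), and that is
  the objective the implementation tracks, asserts on every iteration, and
  reports. Convergence is declared when the objective gains less than `tol`
  (default 1e-6).
* EM on motif alignments is notorious for locking into a register shifted by
  one or two columns from the optimum. After the seeded restarts (default 5)
  the best fit undergoes phase-shift refinement: EM is restarted from the
  matrix shifted by ±1, ±2 columns (padded with background) for as long as
  the objective improves. This is deterministic given the seed.
* Motif width is fixed at 6 for both boxes and the RBS, matching the 6-mer
  consensi typical of σ⁷⁰ promoters and Shine–Dalgarno sites.
* The −10 box is discovered first, on the 3′-most 25 nt of each window —
  where it must lie given the 6–9 nt spacer between the −10 element and the
  TSS — and the −35 box is then discovered on the remainder of each window
  upstream of the matched −10. This mirrors the two-box structure without
  requiring a joint two-motif model.

The two-box scan then maximizes the summed log-odds of a −35 and a −10 site
subject to an 11–20 bp interspacer, reporting both spacer histograms; the
spacer to the TSS is the number of bases between the −10 match's 3′ end and
the TSS base. Windows below a combined score floor are reported unmatched.
The RBS report works the same way on TLS windows, with the spacer measured
from the match's 3′ end to the first base of the start codon.

On pure-noise corpora the ZOOPS maximization still aligns the best random
6-mers, which leaves a *selection-bias* information content of roughly
0.35–0.45 bits per column (measured over seeds at 200 windows of 40 nt);
planted motifs produce well over 1.2 bits. The null-calibration test uses
0.5 bits as the discrimination bound.

## 5′-UTR categories

The 5′-UTR length is the number of transcribed bases strictly before the
start codon — the TSS base is included, the TLS base excluded — so a pTSS at
the TLS gives length 0. This convention is chosen because it makes the
leaderless interval 0–9 nt attainable exactly. Categories are closed
intervals: leaderless 0–9 nt (too short to hold an RBS plus spacer), short
25–35 nt (exactly enough for an RBS plus spacer), long 150–300 nt (enough
for cis-regulatory structure), other for the gaps. A gene with several pTSS
contributes one UTR per pTSS by default; `primary_only` keeps the
highest-RRS pTSS per gene.

## Operons and sub-operons

Primary operons are maximal runs of adjacent same-strand genes in genome
order joined whenever at least 3 junction-spanning reads connect the pair
(the threshold is inclusive: exactly 3 joins). Adjacency is interrupted by
an opposite-strand gene, which always ends the walk. Genes never joined are
monocistronic; the result partitions the gene set.

A sub-operon is anchored at any pTSS or iTSS on the operon strand strictly
downstream of the first gene's TLS and upstream of the operon's 3′ end; the
operon's own primary TSS never anchors one. The sub-operon's genes are the
contiguous suffix starting at the first gene whose TLS is at or downstream
of the anchor — so an iTSS inside gene *g* starts the suffix at *g*'s
successor (the anchored transcript covers only part of *g*, so *g* itself is
not counted; this successor convention is a design choice where either
reading is defensible). Distinct anchors producing identical suffixes are
kept distinct, since they are distinct transcription units.

## Expression summaries

TPM is the within-sample normalization
($\mathrm{tpm}_g \propto c_g/\ell_g$, scaled to sum to $10^6$); replicate
concordance is checked as squared Pearson correlation of TPM with a warning
below 0.8. For cross-condition statistics, size factors are estimated by
median-of-ratios over genes with all-positive counts, the base mean averages
normalized counts over *all* samples (the convention of GLM-based DE tools;
the alternative per-condition mean is not used), A = log2 base mean, and M is
the log2 ratio of condition means (condition of interest over reference, so
upregulation under the condition of interest is positive). With the default
zero pseudocount, genes with a zero mean in either condition get M = NA
rather than an arbitrary finite value.

The DE test is a deliberately transparent negative-binomial Wald stand-in,
not a reimplementation of a shrinkage-based GLM framework. Per-gene
dispersion comes from method-of-moments on normalized counts; because the
per-gene estimate at three replicates is extremely noisy and underestimates
inflate the Wald statistic, each gene's dispersion is floored at the
genome-wide median estimate (a crude but effective form of information
sharing), and at 1e-8. The Wald statistic is the log2 fold change over its
delta-method standard error (a 0.5 normalized-count offset stabilizes both
near zero means), p-values are two-sided normal, and multiplicity is
controlled by Benjamini–Hochberg. The test's contract is *calibration* —
type-I error at the nominal level under a simulated null and high power for
strong planted effects — not numeric parity with any particular GLM
implementation. Regulation classes mirror an MA plot's color classes:
`highly_up` at M ≥ 4 and `highly_down` at M ≤ −3 (asymmetric thresholds
chosen qualitatively from the MA geometry, where upregulation under the
condition of interest is the stronger tail), `up`/`down` at |M| ≥ 1, all
requiring adjusted p < 0.01.

## The synthetic study generator

`simulate_genome()` lays out genes in operon runs (operon-size distribution
defaulting to 43% monocistronic and a 2-to-6-gene tail dominated by
two-gene operons, as observed in bacterial transcriptomes), plants a full
promoter upstream of each operon's lead gene — −35 box CTTGCC, 11–20 bp
interspacer, −10 box TATAAT, 6–9 bp spacer, TSS on an A — an RBS (AAGGAG,
spacer mode 8 nt within 2–19 nt) and an ATG at every TLS, and draws each
lead gene's 5′-UTR from a mixture over leaderless/short/long/other (weights
0.05/0.25/0.25/0.45). A configurable fraction of multi-gene operons
additionally receives one internal promoter assigned to one or both
conditions; these are the true sub-operon anchors. Motif instances are
degraded base-wise at a 10% mismatch rate by default.

`simulate_readstarts()` is a Poisson model: background starts at 0.05 per
base per strand in both libraries, Poisson(200) enriched starts at each
active TSS, and a control drawn at background level at the TSS (a perfectly
flat control by default). Per-base start counts are sparse, which is why a
Poisson rather than an NB model is used for them. The recorded library size
(2 × 10⁶ by default) deliberately exceeds the retained start counts, as in
real libraries where most mapped reads are not retained 5′ ends; this also
sets the RPM scale on which the RRS floor operates. `simulate_junctions()`
draws Poisson(30) spanning reads within operons and Poisson(0.05) across
operon boundaries. `simulate_counts()` draws NB counts for biological
triplicates per condition with log-uniform baseline means over 10–3000 and
NB size 20 (dispersion 0.05) — a typical bacterial biological-replicate
dispersion, chosen so that replicate TPM concordance reproduces the R² > 0.8
regime expected of consistent triplicates; 10% of genes receive a planted
log2 fold change of 1–5 with random sign. All stages derive their random
streams from one master seed, so a fixed seed reproduces the study
byte-for-byte.

What the generator does *not* emulate: sequencing error and mapping
ambiguity, RNA processing and degradation (no processed-5′-end background
structure in the control), rRNA contamination, transcript-level 3′ structure
(no termination sites), operon read-through gradients, and any correlation
between expression level and TSS signal strength. Passing recovery tests on
this generator therefore demonstrates the correctness of the *inference
machinery* under the stated noise model — thresholding, clustering,
classification, assembly, EM, calibration — not performance on real
libraries, where enrichment efficiency and processed-end background dominate
the error budget.

## Problem sizes and runtime choices

The default simulated study uses 150 genes (about 70 transcription units on
a ~140 kb replicon), which gives every stage enough events to score recovery
while keeping a full pipeline run under half a minute. The exhaustive
TSS-caller oracle runs on replicons under 10 kb, where an every-base scan is
feasible. Calibration runs that need tight sampling error use dedicated
sizes: 2000 monocistronic genes for the UTR-mixture recovery (multinomial
error below the 3-point band being checked) and 2000 genes for the DE null.

## Known limitations

* Single replicon; multi-replicon assemblies are out of scope.
* No TTS/terminator calling, so operon 3′ ends are annotation-derived.
* The two-stage −10/−35 discovery is not a joint model; a weak −35 signal
  does not influence the −10 alignment.
* The NB stand-in does not share dispersion information beyond a global
  floor, does not shrink fold changes, and has no outlier handling; very
  small counts rely on the delta-method approximation.
* The TSS caller pools replicates by design (enrichment protocols are
  typically run on pooled RNA); there is no replicate-aware error model for
  TSS calls.
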