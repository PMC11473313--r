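---
title: "Discovering hereditary and epigenetic fusion genes in case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering hereditary and epigenetic fusion genes in case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionrec)
```

## The procedure and its assumptions

`fusionrec` takes per-run fusion-junction calls (produced upstream by any
fusion-discovery tool), a gene annotation, and a run-to-patient cohort
design, and answers three questions:

1. Is each junction a *readthrough* product (epigenetic fusion gene, EFG)
   or does its geometry imply a genomic rearrangement (hereditary fusion
   gene, HFG, when recurrent in non-cancerous tissue)?
2. Which fusions are statistically associated with the case cohort?
3. Can the calls be validated directly from the sequencing reads?

The statistical model assumes that patient-level presence of a fusion is
an independent Bernoulli draw per patient within each cohort, that the
unit of recurrence is the *unique patient* (never the sequencing run —
cases often contribute several runs), and that cohorts are random samples
from their populations. The method makes no use of expression levels,
read counts, or isoform abundance: presence/absence per patient is the
entire sufficient statistic.

## Classification rules

A junction is EFG/readthrough iff its partners are on the same chromosome
and strand, the 5′ gene is transcriptionally upstream of the 3′ gene, and
the intergenic gap is at most `gap_threshold` (default 200,000 bp,
boundary inclusive). The remaining geometries map to genomic mechanisms:
different chromosomes → interchromosomal translocation; opposite strands →
inversion; reversed order → duplication/order-reversal; gap above
threshold → distal intrachromosomal event.

Three points were genuinely open and were fixed as package design
decisions:

* **Gap is measured between gene bodies** (outermost annotated bounds),
  not between breakpoints. The readthrough definition is a property of the
  two parental genes, and a per-isoform gap would let different isoforms
  of one fusion gene straddle the class boundary. This choice can flip
  borderline pairs whose breakpoints sit far inside long genes.
* **"Neighbouring" does not require adjacency.** Readthrough transcription
  can skip across an intervening gene, and known readthrough fusions span
  three-gene loci; only strand, order, and gap decide.
* **Order-reversed same-strand pairs are labelled
  `duplication_or_order_reversal`** without asserting the true mechanism —
  a duplication and a local inversion-plus-reinsertion are not
  distinguishable from junction geometry alone.

Overlapping same-strand genes in the correct order have gap 0 and are EFG.
Strand-discordant pairs are never EFG regardless of gap, because
readthrough requires a continuous same-strand pre-mRNA.

Coordinates are 0-based half-open internally; GTF (1-based inclusive) is
converted on read, BED passes through. A single internal convention keeps
the interval arithmetic free of off-by-one cases.

## The statistical model

With cohort sizes $n_1, n_2$ and positive-patient counts $x_1, x_2$, each
fusion passing the recurrence filter is scored with the pooled
two-proportion Z-test (no continuity correction), two-sided at
$\alpha = 0.01$, so significance means $|z| \ge 2.576$. Two-sided is the
right reading of a symmetric $Z_{\alpha/2}$ threshold, and it is what
allows *negatively* associated (protective) fusions to be reported at all.

The **$n p \ge 5$ filter** is applied as an integer patient count
$\ge$ `min_count` (default 5), and a fusion enters testing when it passes
in *either* cohort. The either-cohort rule is what admits fusions rare in
cases but common in controls — exactly the negatively associated class —
while still guarding the normal approximation (expected counts ≥ 5 is the
classical validity rule for the pooled Z / chi-square equivalence). At
$n_1 = 122$ the filter implies a minimum detectable case frequency of
$5/122 = 4.1\%$.

**Fold enrichment** is the frequency ratio; when the control count is
zero, a pseudocount of one positive control keeps the ratio finite. One
pseudocount (rather than 0.5 or a continuity-style correction) is the
convention that reproduces a finite ~37-fold for a fusion seen in 14.8% of
122 cases and zero of 252 controls.

**Somatic-origin model.** With a per-individual somatic fusion rate
$r = 3.6\times10^{-2}$, the probability that $k$ individuals share an
identical somatic fusion is $r^k$; at $k = 5$ this is
$6\times10^{-8}$, and the expected number of such coincidences is
$n r^k \approx 1.5\times10^{-5}$ in 252 controls ($7.4\times10^{-6}$ in
122 cases). This is why recurrent genomic-geometry fusions in
non-cancerous cohorts are interpreted as germline.

**Contribution split.** Let $R_H$ and $R_E$ be the case/control ratios of
*mean* recurrence frequency over positively associated HFG and EFG
transcripts. With $\rho = R_H / R_E$, the genetic share is
$100\rho/(\rho+1)$ and the environmental share its complement; the two
always sum to exactly 100. The split is computed exactly from the input
ratios — feeding the rounded ratios 8.1 and 3.3 gives 71.1%/28.9%, while
feeding the once-rounded intermediate ratio 2.48 gives 71.3%/28.7%; the
package computes, it does not chain rounded intermediates.

No multiple-testing correction gates the replicating mode (the procedure
is defined by its fixed $|z|$ cutoff); a Benjamini–Hochberg column is
emitted alongside for reference.

## The junction scanner

Validation is exact substring matching, deliberately alignment-free. Each
probe (default 30 bp per side of the breakpoint) contributes every window
of length `match_len` (default $2\times$`anchor` = 20) that spans the
breakpoint by at least `anchor` = 10 bases on each side; windows
containing `N` are dropped. Reads are streamed in chunks (memory is
independent of file size), scanned on both strands by default, and a
single junction-spanning read makes the run positive for that isoform.

The anchor is the specificity mechanism: a read from a *native* parental
gene can match one side of a probe perfectly but never a window that
crosses the breakpoint with 10 bases on each side. For uniform background
the per-window collision probability is $4^{-20} \approx 10^{-12}$, so
junction-free libraries of any realistic size produce zero hits; the
test suite checks this with 2,000 random reads at anchor 15 and the
acceptance run on a full synthetic study observes zero false positives at
the default anchor. Mismatch-tolerant matching, base-quality filtering,
and repeat screening are out of scope — exact junction evidence either
is or is not present in a read.

Reads shorter than `match_len` are not skipped: they fall back to a direct
substring comparison against each probe, still requiring both anchors.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
exercised: 122 case patients with three runs each versus 252 single-run
controls — the design the statistical constants (α = 0.01, filter ≥ 5)
were calibrated for. Its default fusion roster spans every mechanism
class, with prevalences patterned on the recurrence range the method must
resolve: a near-ubiquitous readthrough (0.99 case / 0.53 control), a
strong inversion-derived fusion (0.88/0.21), a moderate translocation
(0.40/0.08), a rarer order-reversal (0.22/0.01), a control-enriched
readthrough (0.23/0.41, the protective case), a case-only distal fusion
(0.15/0), and one null fusion (0.20/0.20).

Patient-level presence is the sampling primitive; for multi-run patients,
one run is forced positive and the rest are visible with probability 0.8,
so truth tables are exact at the patient level by construction. Annotation
geometry is drawn with uniform gaps (20–80 kb by default, comfortably
inside the readthrough window, with multi-gene spans providing the distal
class), and roster geometry is verified against the classifier *before*
sampling. Reads embed the exact junction probe at a random offset and
strand inside otherwise random sequence, plus gene-body background reads;
substitution errors are available but default to zero.

What the generator does **not** model: expression levels and RNA-seq
coverage biases (the pipeline never uses them), splice-isoform structure,
sequencing indels, repetitive genomic context (which the real validation
algorithm also excludes), or linkage between fusions within a patient
(presence draws are independent across fusions). Passing tests therefore
demonstrate the correctness of the bookkeeping, the statistics, and the
scanner — not robustness to repeat-mediated artefacts or to correlated
per-patient fusion burdens in real tissue.

## Numerical choices and problem sizes

Degenerate Z-test tables (pooled proportion 0 or 1) return $z = 0$,
$p = 1$ rather than NaN. Frequencies are kept exact and rounded only in
report columns (two decimals for percentages, one for folds). Ties in all
orderings are broken by fusion identifier, so every output table is
byte-reproducible.

The simulation-based checks use: 10,000 null fusions at prevalence 0.2
for the type-I error of the filter + Z-test procedure (the empirical
rejection rate must sit inside the binomial 99% band around 0.01); 1,000
replicates per direction at prevalences (0.4, 0.05) and (0.05, 0.4) for
power, where recovery with the correct sign exceeds 99%; 1,000 random gene
pairs against a brute-force rule enumeration; and one full synthetic study
(618 FASTQ files) for the scanner round trip, where scan-derived
association must equal truth-derived association exactly. These sizes are
the package's own choices, large enough that the binomial bands are tight
while the whole suite stays interactive.

## Known limitations

* Classification truth is geometric: a genuine readthrough across a >200 kb
  gap, or a germline rearrangement that happens to mimic readthrough
  geometry, is misclassified by construction. The threshold is a config
  parameter, not biology.
* The somatic-origin model treats the per-individual rate as a constant
  across fusions and individuals; it is an order-of-magnitude argument,
  not a calibrated posterior.
* The pooled Z-test ignores relatedness, ancestry structure, and batch
  differences between cohorts; with cohorts drawn from different studies,
  significant association includes any systematic cohort difference, not
  only disease biology.
* The scanner is exact-match only; a single sequencing error inside the
  matched window hides that read (at 20 bp windows and typical error
  rates this costs little sensitivity when several junction reads are
  present, but it is a real floor for single-read positives).
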