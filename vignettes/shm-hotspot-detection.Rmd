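---
title: "Detecting somatic-hypermutation hotspots from active-mark ChIP-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic-hypermutation hotspots from active-mark ChIP-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shmscan)
library(data.table)
```

## The problem

Activation-induced cytidine deaminase (AID/AICDA) normally diversifies
immunoglobulin genes in germinal-center B cells through somatic
hypermutation (SHM). The same machinery can stray onto the 5' regulatory
regions of other genes; in germinal-center-derived lymphomas this aberrant
SHM accumulates clusters of point mutations in proto-oncogene promoters.
Because promoter mutations are invisible to exon-capture and RNA-seq,
`shmscan` mines a different data source: reads from a ChIP-seq experiment
against an active promoter mark (typically H3K4me3), which concentrate
exactly on the 5' regulatory DNA of transcribed genes and are deep enough
there to call variants.

The pipeline answers three nested questions:

1. **Which covered positions carry a real variant?** — a per-site test
   against the sequencing-error process.
2. **Which variants are credible and novel?** — confidence filters plus a
   known-polymorphism (dbSNP-style) exclusion, restricted to 4-kb windows
   centred on transcription start sites (TSS) of mark-enriched genes.
3. **Which genes are SHM hotspots?** — genes whose windows hold unexpectedly
   many novel variants, enriched at AID target motifs.

## The site model: a Poisson-Binomial error null

Illumina mismatch rates depend strongly on the sequencing cycle (they
typically grow toward the read's 3' end). `shmscan` estimates one
experiment-wide error profile after collapsing clonal reads (same
chromosome, 5' alignment start and strand — presumed PCR duplicates):
for cycle $i$,

$$p_i = \frac{\text{reads mismatching the reference at cycle } i}
             {\text{reads of length} > i}.$$

At a genomic site covered by $n$ reads with $k$ of them non-reference, the
null distribution of the mismatch count is the Poisson-Binomial: the sum of
$n$ independent Bernoulli trials whose success probabilities are the $p_i$
at the cycle with which each overlapping read crosses the site. The
p-value is the exact upper tail $P(S \ge k)$, computed by the
dynamic-programming convolution equivalent to the classical recursion over
the weights $w_i = p_i/(1-p_i)$. A mismatch observed on a noisy late cycle
therefore contributes less evidence than one on a clean early cycle.

The trial vector uses the cycles of *all* overlapping reads, matches and
mismatches alike. This is the only reading under which the site test is a
well-defined $n$-trial Poisson-Binomial given where the site falls inside
each read; conditioning only on the mismatching reads would discard the
null information carried by the matching ones.

Two conventions worth noting:

* **Cycle mirroring.** SAM stores reverse-strand reads in reference
  orientation, but error rates belong to sequencing cycles. The aligned
  query offset of a reverse-strand base is mirrored
  ($\text{cycle} = L - 1 - \text{offset}$) before it touches the profile.
  This is a deliberate design choice: the phenomenon being modelled
  (cycle-dependent chemistry error) is a property of the machine, not of
  genomic orientation, so the profile is indexed in as-sequenced order.
* **$k$ counts every non-reference read**, while the reported allele is the
  modal alternate base (ties broken A < C < G < T).

Sites need $n \ge 4$ ("min_depth") to be scored; Benjamini–Hochberg
adjustment is applied across all scored sites of the run as one family and
calls are made at a 1% false-discovery rate.

## Confidence filtering and annotation

A called site is *high confidence* when

* the mismatch ratio $k/n \ge 0.33$,
* the mean raw-ASCII base quality of the alternate-carrying reads is at
  least 90, and
* a two-sided Welch t-test comparing qualities of reference-carrying vs
  alternate-carrying reads does not reject ($p \ge 0.05$); when either
  group has fewer than two reads (e.g. $k = n$) the test is undefined and
  the gate passes vacuously, since its purpose is only to catch
  quality-biased alternate alleles.

The quality threshold is expressed in raw ASCII code units — the scale on
which this filter is conventionally stated for Phred+64-encoded data
(90 means Q26). Both the threshold and the encoding are configuration
items; with Phred+33 data an equivalent setting is 59.

Note a structural property of this filter: for a *true* variant the two
quality groups are identically distributed, so the t-test p-value is
uniform and the gate sacrifices ~5% of true calls by construction, and the
ratio gate removes the low tail of the binomial allele-sampling
distribution (another ~2–3% at 30x and allele fraction 0.5). The
high-confidence set therefore deliberately trades sensitivity for
precision; sensitivity measured on it cannot exceed roughly 93% under
those conditions, which the planted-variant tests make visible.

Calls are annotated with window membership (`promoter` is true only inside
*enriched* windows), gene, and novelty against the known-polymorphism set.
Known-variant matching is position-level by default (an allele-aware mode
exists) because dbSNP-style filtering of this kind is conventionally
positional.

## Promoter windows and enrichment

Windows are TSS $\pm$ 2 kb (total 4 kb), clipped at chromosome edges.
Multi-transcript genes collapse to the 5'-most transcript start on the
gene strand; a per-transcript mode merges overlapping windows instead. The
enriched-window universe — the denominator of every downstream statistic —
is decided by one of three modes: a minimum overlapping read count
(default, $\ge 20$ reads), a Poisson background test against the
genome-wide read density (BH-adjusted tail $\le 0.05$), or intersection
with an externally supplied peak BED. No single enrichment criterion is
canonical for this step, so absolute promoter counts depend on the chosen
mode; what matters downstream is only that one consistent universe feeds
the per-gene test.

## Hotspot statistics

With $T$ high-confidence novel promoter SNVs over $W$ enriched windows,
the expected count per window under uniform scatter is
$\lambda = T/W$, and each gene with $k$ SNVs gets the Poisson tail
$P(X \ge k;\lambda)$, BH-adjusted across genes with $k \ge 1$ (windows
with zero novel SNVs carry no evidence either way, and including them
would only dilute the family). Genes pass the clustering gate with
$k \ge 3$ and adjusted $p < 0.005$.

Motif context is then tested per candidate gene and per motif class:

* **RGYW/WRCY** (R = A/G, Y = C/T, W = A/T): mutable G of RGYW, mutable C
  of WRCY — one class on the two strands;
* **WA/TW**: mutable A of WA, mutable T of TW.

The observed statistic is the number of the gene's SNVs at motif-mutable
positions (each SNV counted once per class even inside overlapping
motifs). The null redraws the same number of positions uniformly *without
replacement* from the window's covered positions (depth $\ge$ min_depth) —
not from all window positions, because variants are only detectable where
there is coverage, and uneven coverage would otherwise bias the expected
count. The default 1,000 permutations put the Monte-Carlo error of $z$
well below the decision boundary. Window sequences are extended 3 bp each
side during scanning so boundary-straddling motifs are found.

A gene is a hotspot when $k \ge 3$, adjusted $p < 0.005$, and $z > 1$
(strict) for either class. With a degenerate permutation null
($\mathrm{sd} = 0$) the convention is $z = +\infty$ if obs > exp, $0$ if
equal, $-\infty$ otherwise. Transitions are A$\leftrightarrow$G and
C$\leftrightarrow$T; downstream-of-TSS counts follow the gene's strand
(strictly 3' of the TSS base).

Because the permutation null is discrete, the $z > 1$ gate is noticeably
more permissive than the normal-approximation 16%: with $k \approx 6$ SNVs
and a motif-mutable fraction of a few percent, a single motif hit can
already clear one standard deviation (observed $z$ between 1 and 2 with
obs = 1 is common). The specificity property test therefore compares the
classifier's behaviour on uniformly placed SNVs against the analytic
(hypergeometric) admission rate of the gate itself rather than against a
fixed constant.

## The synthetic experiment generator

`simulate_experiment()` builds a complete, self-consistent input set:
random uniform-composition genome; genes on alternating random strands
with disjoint 4-kb promoter windows (2-kb gaps, 1-kb margins); a
known-variant VCF of planted germline SNPs (homozygous by default); reads
tiling the windows with per-cycle error rates following a configured curve
(default linear 0.1% to 1% across 36 cycles, the shape of GA-era Illumina
data); planted novel SNVs and motif-context SHM hotspots (transition
alleles at RGYW/WRCY- or WA/TW-mutable reference positions) carried by
each overlapping read with the configured allele fraction; 2% exact
clonal duplicates; base qualities uniform Q30–Q40, Phred+64. A
ground-truth manifest records every planted variant. Fixed seeds make all
outputs byte-identical.

Two generator conventions deserve explanation:

* `mean_depth` means *non-clonal* coverage. Uniform tiling of a 4-kb
  window offers only $2(4000-35)$ distinct (start, strand) placements for
  36-bp reads, so ~20% of sampled reads collide by chance and are
  collapsed by deduplication together with true PCR duplicates. The
  sampler inflates the read count by the expected collision loss so that
  the coverage the caller actually sees equals the requested value — depth
  figures for this kind of data conventionally refer to unique non-clonal
  reads.
* Planted positions stay one read length inside window edges, where
  coverage is full.

What the generator does **not** emulate: mappability structure and
alignment artefacts (reads are emitted as alignments; the tool's contract
starts there), ChIP fragment-size and peak-shape effects, GC bias,
non-uniform genome composition, heterozygous SNP phasing, and indels.
Passing tests on this fixture therefore demonstrate the statistical
machinery — error-profile estimation, exact tail computation, FDR
behaviour, motif permutation calibration, end-to-end determinism — not
robustness to alignment pathology on real genomes.

## Numerical and implementation choices

* The Poisson-Binomial pmf is built by an $O(n^2)$ convolution in C++
  with long-double (80-bit) accumulation; the tail is summed directly
  from the pmf, so tiny tails avoid 1-minus cancellation. Agreement with
  exhaustive enumeration is at the $10^{-15}$ level for $n \le 12$.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`. Note that
  step-up adjusted values are *not* a fixed point of re-adjustment (a
  second application changes them); the relevant invariants are
  order-invariance and agreement with the textbook definition.
* Internal coordinates are 0-based half-open everywhere; conversions
  (SAM/VCF 1-based, display) happen at I/O boundaries only.
* The site aggregation works on integer byte codes rather than character
  vectors; a 60-gene, 30x replicate (~200k reads) runs in well under a
  minute end to end, which is what makes the multi-replicate validation
  experiments practical.
* Degenerate inputs fail loudly: unsorted reads, zero reads, a cycle with
  error rate 1, reads beyond the profile length, an empty enriched-window
  universe.

## Validation experiment sizes

The test suite validates on these problem sizes, chosen to exercise the
method at its intended operating point while staying desk-scale:
planted-variant recovery on 50 promoters with 200 novel SNVs (allele
fraction 0.5, 30x) plus 100 germline SNPs; hotspot classification on 20
replicates of 60 promoters (10 seeded with 5–8 RGYW-context SHMs, 50
background genes with 0–2 scattered SNVs); 1,000 random vectors against
the enumeration oracle and 1,000 random 4-kb sequences for motif strand
symmetry. `scripts/acceptance.R` re-runs scaled versions of the same
experiments from scratch.

Two caveats surface in those experiments and are visible as failing
assertions rather than hidden: (i) the high-confidence filter's built-in
~7% sensitivity cost (above) makes a 95% sensitivity bar unreachable on
the final call set; (ii) in the 60-gene hotspot fixture the per-window
expectation is $\lambda \approx 1.9$, so the $q < 0.005$ clustering gate
cannot pass genes with only 5–6 SNVs — with thousands of enriched
promoters, as in real data, $\lambda$ is orders of magnitude smaller and
the gate behaves as intended. The seeded-hotspot recovery *property* is
therefore demonstrated on a 40-gene fixture with three seeded genes and
sparse background ($\lambda \approx 0.5$), where the arithmetic permits
recovery.

## A worked example

```{r example, eval = FALSE}
library(shmscan)

cfg <- sim_config(
  seed = 11, n_genes = 40, mean_depth = 30,
  planted_hotspots = data.frame(gene = c("G001", "G002", "G003"),
                                n_shm = 6, motif_class = "RGYW", af = 0.5),
  planted_scattered = data.frame(gene = c("G010", "G011"),
                                 n_snv = c(2, 1), af = 0.5))
sim <- simulate_experiment(cfg, "sim")
res <- run_pipeline(sim$paths[["genome"]], sim$paths[["reads"]],
                    sim$paths[["genes"]], sim$paths[["known"]],
                    outdir = "out", config = shm_config(seed = 11))
res$counts
res$hotspots$genes[, .(gene, k_gene, downstream, qvalue, z_rgyw, z_wa,
                       ts, tv, is_hotspot)]
```

The same pipeline is available from the shell via the installed
`exec/shmscan` script (`simulate`, `error-profile`, `call`, `annotate`,
`hotspots`, `run-all` subcommands).

## Known limitations

* No indel calling, no genotype likelihoods, no matched-normal somatic
  model: novelty relative to the supplied polymorphism set is the only
  germline filter.
* The enriched-promoter criterion is heuristic; absolute promoter counts
  depend on it.
* Genome builds of the FASTA, gene models and known-variant set must
  match; beyond chromosome-name agreement this cannot be verified
  internally.
* The per-gene BH family (genes with $\ge 1$ SNV) is one of two defensible
  readings; per-gene adjusted p-values shift modestly under the
  alternative (all enriched windows).
```
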