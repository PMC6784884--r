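---
title: "Methods: subgenome analysis of allopolyploid genomes with polysub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subgenome analysis of allopolyploid genomes with polysub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysub)
```

## The problem

Most cultivated bananas are interspecific triploids combining chromosome
sets from *Musa acuminata* (the A genome) and *M. balbisiana* (the B
genome) — constitutions such as AAB or ABB. Three things make these
genomes analytically interesting:

* **Homoeologous exchanges (HEs).** Segments of one subgenome can be
  replaced by the homoeologous segment of the other. When resequencing
  reads are mapped uniquely against a concatenated A+B reference, an HE
  shows up as paired evidence: depleted coverage on the losing subgenome
  and correspondingly elevated coverage on the gaining one. Accumulated
  whole-chromosome replacements change the effective genome constitution
  (an "ABB" accession can in fact carry, say, 8 A and 25 B chromosome
  equivalents).
* **Homoeologue expression dominance.** For a pair of homoeologous genes,
  one copy may be expressed far beyond what its copy number explains.
* **Dosage compensation.** Total expression of a triploid pair may be
  pulled back toward a diploid level, so the observed B:A expression
  ratio falls below the genomic copy ratio.

`polysub` implements the full desk-scale analysis chain for these
questions — homoeologue pair identification, HE calling, dominance and
dosage statistics, and Ka/Ks + 4dTv molecular-evolution contrasts —
together with a synthetic-data generator that produces every input with
known ground truth.

## Copy-state model for HE calling

Depth is summarised in non-overlapping 100 kb windows (the resolution at
which segmental exchanges are conventionally displayed and detected;
`window_size` is a parameter). For a total ploidy $P$ (3 for ABB) and a
per-copy depth $d_1$, each homoeologous window pair with observed depths
$(x_A, x_B)$ is assigned the copy state

$$(\hat n_A, \hat n_B) \;=\; \arg\max_{n_A + n_B = P}
\big[\log f(x_A \mid n_A d_1 + \varepsilon) +
     \log f(x_B \mid n_B d_1 + \varepsilon)\big],$$

where $f$ is Poisson, or negative binomial with variance
$\mu + \alpha\mu^2$ when over-dispersion $\alpha > 0$ is set. The usual verbal criterion —
coverage markedly elevated on one subgenome while depleted or absent on
the homoeologous region — is thereby operationalised as a likelihood
comparison that degenerates to simple ratio thresholds at high depth but
behaves sensibly near zero counts.
Design notes:

* The candidate states are **copy-conserving** ($n_A + n_B = P$) because
  an HE is a substitution: one subgenome's loss is the other's gain.
  Non-conservative duplications are outside the model.
* $\varepsilon = 0.01\,d_1$ (the `bg_frac` parameter) is a background
  term so that a zero-copy state tolerates an occasional stray read
  instead of taking a $-\infty$ log-likelihood.
* $d_1$ is estimated by `estimate_per_copy_depth()` as the **median** of
  window depth divided by the prior copy number from the accession's
  nominal constitution. The median keeps the estimate within a few
  percent of truth even when ~20 % of windows sit inside exchanges, which
  is verified by test.
* Depth is matched positionally between subgenomes, which the simulation
  guarantees. Real data would need a homoeologous coordinate map (e.g.
  from gene anchors); building one is out of scope and stated as such.

Runs of an identical non-nominal state spanning at least `min_windows`
(default 3, i.e. 300 kb) become HE segments. The default suppresses
single-window noise while keeping short real exchanges; there is no
field-standard minimum, so the value is exposed. A run covering at least
`chrom_fraction` (default 0.9) of a group's windows is promoted to a
whole-chromosome replacement. Direction labels are donor → recipient:
`A_to_B` means the A copy replaced B's slot ($n_A$ above nominal).
Unresolved windows break runs rather than bridging them. The segmentation
is provably equivalent to run-length encoding of the state sequence and
is tested against a brute-force oracle on random sequences.

`summarize_constitution()` takes the per-group modal state and renders
totals such as `"8A+25B"`; groups with fewer than half their windows
resolved are excluded with a warning.

## CIP/CALP homoeologue pairing

For each query gene the HSPs against a subject are reduced to

* CIP (cumulative identity percentage) =
  $100 \sum \text{identities} / \sum \text{HSP length}$,
* CALP (cumulative alignment length percentage) =
  $100\,|\bigcup \text{query intervals}|\,/\,\text{query length}$.

Pairs must meet both thresholds **inclusively** (defaults 60/60, the
standard filtering convention). Two conventions are not fixed by common
usage and are decided here: CALP is computed over the **query** length
with overlapping HSP intervals **unioned** (this bounds coverage at
100 %), and multi-hit genes are resolved by **reciprocal best** matching
(rank by CIP, then CALP, then partner identifier for determinism),
yielding a 1:1 partial matching. Note that with two thresholds,
reciprocal-best matching is not formally monotone in the thresholds: a
candidate admitted by a lowered CALP cut-off can displace a previous best
partner. On realistic tables where true pairs dominate their decoys this
does not occur, and the property is tested there. Synteny support is
consumed as an externally produced two-column table and only annotated,
never computed.

## Dominance and dosage statistics

Expression input is paired counts per homoeologue pair, sample and
replicate, with gene lengths and library sizes; RPKM is
$10^9 c / (L \cdot N)$.

Because published DE methodology for this design is not reproducible in
detail, the package uses an exact, dependency-free substitute that
respects the stated thresholds: replicates are summed per sample and the
two counts compared by the **exact conditional binomial test** — given
$n = c_A + c_B$, under the null $c_B \sim \mathrm{Bin}(n, p_0)$ with
$p_0 = \mathrm{off}_B / (\mathrm{off}_A + \mathrm{off}_B)$, with the
two-sided p-value summing all outcomes no more likely than the observed
one. The offsets fold in library size, gene length **and the genomic copy
numbers** of the accession: dominance is expression bias beyond what copy
number explains, so in an ABB accession a pair whose B output is simply
twice its A output is *not* dominant. The fold change is computed on the
per-copy RPKM scale for the same reason. This choice is what makes a null
ABB simulation come out clean (dominant-call fraction ≈ 0) while a
planted four-fold per-copy effect is recovered with ≥ 90 % recall — both
verified by test.

Q-values are Benjamini–Hochberg over the full pair × sample family (one
family; stated in output metadata). A sample supports B-dominance when
the per-copy fold change is ≥ `fc_threshold` (2) with q ≤ `fdr_threshold`
(0.001); a pair is classified when ≥ `min_supporting` samples (default 1)
support one direction and none support the other; conflicting pairs are
non-dominant and flagged `mixed`. The aggregation rule across samples is
a genuine open choice and is exposed as a parameter.

The dosage summary reports median and mean of
$\log_2\!\big((\mathrm{RPKM}_B + \epsilon)/(\mathrm{RPKM}_A +
\epsilon)\big)$ over pairs with summed RPKM above `min_expr` (1), with
$\epsilon = 0.01$ RPKM bounding the ratios without distorting expressed
pairs, and compares the median with the genomic expectation
$\log_2(n_B/n_A)$ as a compensation index (index < 1 = ratio compressed
toward the diploid state, as in an observed 1.2/1 against a genomic 2/1).

## NG86 Ka/Ks and 4dTv

Ka/Ks is computed with the Nei–Gojobori (1986) counting method rather
than an iterative codon-model estimator (yn00/GY94): downstream use is
class-level medians, which are insensitive to the estimator at this
divergence, and NG86 admits exact oracle verification — every
pathway-averaged difference count is tested against exhaustive
enumeration over all 61 × 61 sense codon pairs. Conventions:

* Site counts per codon position use the fraction of single-nucleotide
  changes that are synonymous, **excluding changes to stop codons from
  the denominator**; `ng86_sites("TTT")` is 1/3, `"TGG"` is 0. (Some
  implementations divide by 3 regardless of stop neighbours; the two
  conventions differ for codons with stop-codon neighbours, e.g. Tyr.)
* Differences per codon pair are averaged over all minimal substitution
  pathways with equal weights; pathways through stop codons are
  excluded. If every pathway is blocked, all pathways are used with the
  stop steps dropped, and the pair is flagged — never silently altered.
* Jukes–Cantor correction $-\tfrac34\ln(1 - \tfrac43 p)$; $p \ge 3/4$
  raises a saturation flag and the rate is `NA`, as is the ratio when
  Ks is 0 or unavailable.
* Standard genetic code only; gaps, ambiguity codes and stop codons are
  rejected at validation.

4dTv is the **raw** fraction of transversions among third positions where
both codons belong to a fourfold-degenerate family and the first two
positions agree between the sequences. An HKY-corrected variant is
deliberately not provided: the correction recipe varies between
pipelines, and the raw fraction is the well-defined contract.
Class contrasts (`compare_classes()`) report per-class medians (printed
to 3 decimals) and Welch's t-test p-values, excluding undefined or
saturated ratios with counts logged.

## What the simulator emulates — and what it does not

The generator's defaults describe the study conditions the package is
tested under: an ABB-like triploid with 11 homoeologous groups of 30 Mb,
100 kb windows at 20× per chromosome copy (Poisson by default, negative
binomial via `dispersion`), 5,000 homoeologue pairs at a per-copy mean of
200 counts with two biological replicates per sample, and codon
alignments of 300 codons diverged to Ks 0.2 / Ka 0.05 — values a
resequencing + RNA-Seq study of this kind would consider realistic.
Planted truth covers HEs (window-snapped, copy-conserving), replacements,
dominance labels, the compensation factor and every substitution event.

Simulated counts are drawn per window/gene, not per read. The simulation
therefore does **not** model mapping bias between subgenomes, GC or
repeat effects on coverage, sequencing error, or correlated biological
replicates. Consequently, passing recovery tests demonstrates
correctness of the inference given the count model — not robustness to
real-data artefacts, which would need a mapping-aware benchmark. The
depth noise model of real data is unknown; `dispersion` is a free
parameter, not an inference.

One deliberate deviation inside the generator: `target_ks`/`target_ka`
are interpreted as targets for the *corrected* rates, so the planted
proportion of hit sites is the inverse Jukes–Cantor transform
$p = \tfrac34(1 - e^{-4K/3})$ and substitutions land on distinct codons
(at most one per codon, never creating stops). This makes the NG86
estimates centre on the targets and keeps the planted synonymous /
non-synonymous counts exactly recoverable as Sd/Nd.

## Numerical and degenerate-input choices

* Exact binomial p-values use the minimum-likelihood two-sided rule with
  a $1 + 10^{-9}$ relative guard against floating-point ties; both
  counts zero gives p = 1 with an `unexpressed` flag.
* Copy-state ties in the likelihood (possible only at degenerate $d_1$)
  resolve to the smaller $n_A$ for determinism.
* Empty inputs error early and loudly (empty depth file, zero expressed
  pairs, zero-length queries); truncated terminal windows and coverage
  gaps are kept but flagged.
* A single global seed fans out to fixed per-stage child seeds, so every
  stage is individually reproducible and a rerun is byte-identical;
  output files carry tool version, seed and an FNV-1a config hash.

## Problem sizes used in the test-suite

The shipped tests run the full chain at deliberately desk-scale sizes:
constitution recovery on the full 11 × 30 Mb genome (6,600 windows), HE
recovery on 20 seeds of a 6 × 10 Mb genome with three planted exchanges
and one replacement each, dominance error control on 20 null seeds of
5,000 pairs and 10 planted seeds of 2,000 pairs, and Ka/Ks recovery on 50
seeds of 300-codon alignments. These sizes give stable statistics
(standard errors well inside the asserted bounds) while the whole suite
stays in the minutes range.

## Known limitations

* Real-data coordinate matching between subgenomes (liftover/anchors) is
  not implemented; the HE caller consumes positionally matched windows.
* The dominance test assumes independent counts; overdispersed real
  replicates would need the NB path or a shrinkage estimator.
* NG86 underestimates rates at high divergence relative to
  codon-model estimators; flags mark saturation rather than correcting
  beyond Jukes–Cantor.
* Headline counts from real accessions (numbers of exchanges or dominant
  pairs in particular cultivars) depend on deep resequencing and
  multi-tissue RNA-Seq and are not reproduced by the simulation; the
  package's claims are the property-level guarantees above.
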