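---
title: "Recovering ribosome A-site signals by deconvolving digestion blur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering ribosome A-site signals by deconvolving digestion blur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ribosome profiling reads are nuclease-protected mRNA fragments whose 5'
ends should sit a fixed distance upstream of the codon being decoded in the
ribosomal A site. In practice RNase digestion is imperfect: footprints of a
wide range of lengths are recovered, and even reads of one length have 5'
ends scattered over several nucleotides around the canonical boundary. The
observed 5'-end pileup of a transcript is therefore a *blurred* version of
the underlying ribosome position signal, and naive A-site assignment rules
(a fixed +15 offset, or one fixed offset per read length) mis-place a large
fraction of reads and destroy the 3-nt periodicity that codon-level analyses
depend on.

`riboclear` models this explicitly and inverts it.

## The model

For each transcript and read length $l$, let $P_{obs}(l)$ be the observed
5'-end pileup (normalized to sum 1) on the window $[-24, L)$ of positions
relative to the first base of the start codon. We posit a hidden,
length-independent consensus position signal $P_{true}$ (non-negative, sums
to 1), anchored on the length-28 5'-end coordinate frame, and model

$$ P_{obs}(l) \;=\; b(l) \ast \big( S_{s_l} P_{true} - \varepsilon(l) \big)
   \;+\; \text{noise}, $$

where $b(l)$ is a per-length *blur vector* of relocation probabilities on
offsets $[-15, 15]$, $S_{s_l}$ shifts by $s_l = -(l - 28)$ into the length-l
observation frame, and $\varepsilon(l)$ is a small per-length deviation
field. The shift follows from the empirical fact that the 3-nt periodicity
of length-$l$ reads starts at $-l + 16$: longer reads carry extra 5' bases,
so their 5' ends sit further upstream, and aligning a length-$l$ profile
onto the length-28 anchor means shifting it *right* by $k_l = l - 28$.

A note on this sign. Written with the opposite convention
($S_{+k_l}$ in the model), the same machinery still fits the data, because a
constant misalignment of $-2k_l$ is simply absorbed by the estimated blur
vector — until $|2k_l|$ exceeds the blur half-width of 15, at which point
short reads (e.g. length 18, where $-2k_l = +20$) become unexplainable. We
therefore lock the periodicity-consistent convention with a regression test:
a length-28 delta at position $-12$ must merge to A-site position $+3$, and
merged profiles on non-frameshifted synthetic data must be frame-0
concentrated.

## Fitting: an EM-like ridge-regularized total least squares

Given blur vectors, each transcript is deconvolved by minimizing

$$ \sum_l \alpha(l)\Big[ \lVert P_{obs}(l) - b(l) \ast (S_{s_l} P_{true} -
   \varepsilon(l)) \rVert_2^2 + \lVert \varepsilon(l) \rVert_2^2 \Big], $$

with $\alpha(l)$ the raw read count of length $l$ (abundant lengths weigh
more). Two alternating exact steps:

* **M-step** (per length): with $P_{true}$ fixed, $\varepsilon(l)$ solves a
  damped least-squares problem (damping parameter 1), i.e. the normal
  equations $(A^\top A + I)\,\varepsilon = A^\top r$ with $A$ the banded
  convolution matrix of $b(l)$ and $r = b(l) \ast S_{s_l} P_{true} -
  P_{obs}(l)$. Solved by a sparse banded Cholesky; an independent dense
  solve is the test oracle.
* **E-step**: with the per-length signals $P_{true}(l) = S_{s_l}P_{true} -
  \varepsilon(l)$ held fixed, the consensus moves to the $\alpha$-weighted
  average of the back-shifted $P_{true}(l)$. At window borders, zero-filled
  shifts mean some lengths do not cover a position; the exact minimizer
  averages only over covering lengths, so we use the per-position
  denominator $\sum_{l \ni i} \alpha(l)$ (identical to the plain weighted
  average everywhere in the interior). Deviations are then re-based
  ($\varepsilon \mathrel{+}= S_{s_l}\Delta P_{true}$) so that each
  $P_{true}(l)$ — and hence the data-misfit term — is untouched by the
  E-step. With both conventions the objective provably never increases
  across any M-step or pre-clipping E-step, which the test suite asserts on
  every synthetic transcript.

Negative consensus entries are then clipped to zero and the vector
renormalized to sum 1 (a small projection; it can tick the objective up and
is excluded from the monotonicity guarantee). Iteration stops when the
relative objective change drops below `tol = 0.01`, or when the objective
is below `1e-15` (exactly solvable inputs, where a relative test is
ill-defined). The consensus is initialized from the in-frame (positions
$\equiv 0 \bmod 3$) values of the length-28 pileup — 28-mers match the
yeast footprint, so their boundaries are the most likely to be
digestion-exact. If filtering removed length 28, the most abundant length,
aligned back to the anchor frame, seeds the consensus instead (logged).

## Estimating blur vectors from meta-profiles

Blur vectors are estimated once per data set from meta-profiles: per-length
sums of 5'-end counts over all transcripts longer than 350 nt, on the
window $[-24, 350)$. The same EM loop runs on the meta vectors with one
extra move at the top of each round: each $b(l)$ is refit as the
non-negative least-squares solution (Lawson–Hanson) of
$\lVert X b - M_{obs}(l) \rVert^2$, where column $j$ of $X$ is the shifted
meta-consensus displaced by offset $j$. NNLS fixes no scale, so weights are
renormalized to sum 1 (they are relocation probabilities).

Two kinds of positions are excluded from all meta fitting:

* the top 1.65% of positions by count — outliers, derived from treating the
  top 5% of in-frame reads (one third of positions) as artifacts; applied
  per read length;
* the last 15 positions (one blur half-width) of the truncated window —
  reads there are convolved in from consensus positions beyond position
  350, which a zero-padded model cannot represent. This is the same
  convolution boundary effect that motivates restricting to transcripts
  longer than the window in the first place.

A practical identifiability note: on a start-codon-anchored meta-profile,
within-frame blur offsets ($j$ vs $j \pm 3$) are distinguished only by
positional variation of the meta-consensus. A hypothetical data set whose
in-frame meta values were constant would leave them nearly collinear. Real
libraries are far from this degenerate case because meta-profiles carry
reproducible structure — most prominently the 5' translational ramp — and
the synthetic generator includes that ramp for the same reason.

## A-site merging and downstream statistics

The A-site offset of a length-$l$ read is $l - 13$ (equivalently: align to
the length-28 frame by $k_l$, then shift right by the canonical 15). The
merged A-site profile is
$C[i] = \sum_l \alpha(l)\, P_{true}(l)[\,i - k_l - 15\,]$, with negatives of
$P_{true}(l)$ clipped at reporting time. $C$ retains sub-codon resolution:
frame fractions, and frame skewness on either side of a planted frameshift
point, are computed directly from it.

Codon decoding times (CDT) are estimated per codon type from the frame-0
A-site values at each codon position: raw values below 1 are excluded,
survivors are divided by the transcript mean over included positions, the
first and last 20 codon positions are dropped, and the pooled per-codon
distributions are fit by a lognormal. The CDT estimate is the lognormal
skewness $(e^{\sigma^2} + 2)\sqrt{e^{\sigma^2} - 1}$, with $\mu, \sigma$
the maximum-likelihood ($1/n$) moments of the log counts. The raw-count
filter precedes normalization and the mean is taken over included
positions; this ordering is recorded here because the two cited
normalization conventions do not fully pin it down. Wobble comparisons use
$\Delta t = (t_{wb} - t_{wc}) / t_{wc}$ within shipped same-tRNA yeast
codon pairs (three anticodon classes: U:A vs U:G, G:C vs G:U, I:C vs I:U);
the pair table is an approximate default and can be overridden by a TSV.

## The synthetic world

The generator states one world and the tests live in it:

* 50 transcripts (200 for the blur round-trip), CDSs of 150–300 codons, so
  every transcript exceeds the 350-nt meta window;
* read lengths 26–30 with length 28 carrying 42% of 10,000 reads per
  transcript — matching a deep yeast library where under 60% of reads are
  28-mers;
* a sparse consensus with mass only at frame-0 positions ($3c - 15$ on the
  anchor frame), values drawn from a heavy-tailed lognormal
  (baseline $\sigma_0 = 0.6$) scaled by the shared 5' ramp
  $1 + 1.5\,e^{-c/20}$;
* unimodal discretized-Gaussian blur kernels, spread $0.5 + 0.35\,|l - 28|$
  (the 28-mer is cleanest), mode 0;
* per-length multiplicative perturbations (lognormal, $\sigma = 0.05$)
  mirroring the deviation freedom of the model;
* multinomial read sampling from the convolved expectations; optional SAM
  emission for end-to-end reader tests;
* optional planted +1 frameshifts (uniform frame-0 in-CDS points) and
  per-codon dwell multipliers.

Dwell is modeled as *stochastic pausing*: codon values are drawn
$\mathrm{LN}(0, s_k)$ with $s_k^2 = \sigma_0^2 + 2\log m_k$, so the mean
dwell equals $e^{\sigma_0^2/2} m_k$ and both the mean and the lognormal
skewness increase with the planted multiplier $m_k$. This is deliberate: a
purely multiplicative dwell would shift only $\mu$, to which the skewness
statistic is blind by construction; slow-because-of-pauses is also the
mechanistic reading of wobble-induced slowdown (tRNA rejection and
re-sampling).

What the generator does **not** emulate: ligation/sequence bias,
multi-mapping, rRNA contamination, position- or transcript-dependent
digestion, elongation ramps beyond the shared 5' ramp, and real biological
dwell heterogeneity. Green tests therefore establish that the estimator
inverts its own generative model at realistic depth and scale — not that it
reproduces every real-data figure. One real-data claim demonstrably does
not transfer: on real profiles most per-codon distributions get *narrower*
after deblurring, whereas in this world the blur is a variance-reducing
low-pass filter on exchangeable codon values, so deblurring (correctly)
restores the wider true dispersion. The package reports this fraction as a
diagnostic instead of asserting it.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `length_range` | 18–33 nt | retained read lengths; 18 is the shortest length with a visible periodicity start, 33 the longest common yeast footprint |
| `l_up` | 24 nt | upstream window extent; periodicity starts at $-l+16$, so 24 covers lengths up to 40 |
| `min_coverage` | 0.5 | a length profile is kept iff *strictly more* than this fraction of in-frame CDS loci are nonzero |
| blur width | 31 offsets | $\pm 15$ nt, about half a footprint either way |
| `tol` | 0.01 | relative objective-change stop for both EM loops |
| `max_iter` | 100 | EM round cap; non-convergence returns the current state flagged |
| `mask_rate` | 0.0165 | outlier fraction masked in meta-profiles (top 5% of in-frame reads) |
| damping | 1 | ridge weight on deviations; with profiles normalized to sum 1 this makes deviation cost commensurate with data misfit |
| `n_min` | 20 | minimum observations per codon for a lognormal fit |
| `trim` | 20 codons | CDS head/tail excluded from CDT |
| `min_raw` | 1 | raw A-site count below which a codon position is excluded |

## Degenerate inputs and tie-breaks

Frame ties break toward the smallest frame index. All-zero profiles, zero
in-frame initialization mass, and a consensus annihilated by clipping raise
errors rather than returning silently wrong output. The >50% coverage rule
uses the full CDS (not the 350-nt meta window) — the more conservative
reading. Frameshift points strictly *after* a read start move it; the shift
position itself belongs to the "before" segment. Coverage filtering counts
loci of the transcript-level in-frame (highest-count frame over all
lengths).

## Known limitations

Blur vectors are global per length: position- or transcript-specific
digestion is out of scope (and was found unnecessary upstream). Only +1
insertions are simulated for frameshifts. tAI and codon-frequency tables
are consumed, never computed. Genome-coordinate (spliced) alignments are
not handled; inputs must be transcriptome alignments.
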