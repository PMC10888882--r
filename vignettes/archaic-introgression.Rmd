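---
title: "Detecting archaic introgression and founder events with archscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting archaic introgression and founder events with archscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archscan)
```

## The problem

Most people outside Africa carry roughly 1–2% of their genome from
archaic hominins — Neanderthals and, in parts of Asia and Oceania,
Denisovans. `archscan` implements a *reference-free* scan for these
introgressed segments in phased diploid genomes. Rather than comparing
test haplotypes directly to an archaic genome, it exploits a density
signal: a haplotype segment inherited from an archaic population carries
far more derived variants that are *absent from a large outgroup panel*
(e.g. sub-Saharan Africans, who carry negligible archaic ancestry) than a
modern-human segment does, because the archaic lineage separated from the
outgroup hundreds of thousands of years earlier. Archaic reference
genomes enter only *after* detection, to assign each called segment to a
source.

The package covers the full analysis chain around that idea: windowed
observation tracks, a two-state hidden Markov model (HMM), source
assignment by derived-archaic-variant (DAV) match rates, interval algebra
over called segments (assembled introgressed genomes, sharing partitions,
rarefaction), landscape scans (enriched regions, deserts, population
branch statistic, uniquely shared derived alleles, incomplete lineage
sorting tests), a coalescence-time clock based on the human-state
emission rate, and identity-by-descent (IBD/HBD) founder-event
statistics. A synthetic-data generator with machine-readable truth
replaces the access-controlled cohorts such analyses are usually run on,
so every stage is validated end to end.

## Observation model

For each haplotype the genome is tiled into half-open windows of
`window_size` bp (default 1 kb, 0-based coordinates). Window $w$ records

* `obs` — the number of derived alleles carried by the haplotype, absent
  from the outgroup set, inside the callable mask;
* `callable` — callable bp overlapping the window;
* `weight` — a local mutation-rate proxy.

Outgroup membership is keyed by (chromosome, position, derived allele),
not position alone, so triallelic artifacts do not leak through. The
default outgroup frequency threshold is 0: any single outgroup carrier
removes a site from the "private" set, the strictest reading of
"not found in the outgroup". Indels and multi-allelic records are
excluded on reading.

**Mutation-rate weights.** Local SNP density in the outgroup panel is the
proxy for local mutation rate. Density cannot be estimated per 1-kb
window (most windows contain no panel SNP at realistic densities), so it
is measured in coarse bins (default 1 Mb) and broadcast to windows. Raw
bin ratios are shrunk toward 1 by the ratio of their Poisson sampling
variance to the observed between-bin variance — ordinary empirical-Bayes
shrinkage — so a sparse panel contributes no spurious rate variation
while genuinely variable rates survive in large panels. Weights are
normalised to mean 1 over callable windows. Whether the density should
come from the outgroup or the test cohort is genuinely open; the default
is the outgroup (the test cohort's private-variant density is exactly the
signal being scanned for, so using it would be circular), and the
function accepts any site table.

## The two-state HMM

States are *modern human* and *archaic*. Emissions are Poisson:

$$\mathrm{obs}_w \mid s \sim \mathrm{Poisson}\!\left(\lambda_s \cdot
\mathrm{weight}_w \cdot \mathrm{callable}_w / \mathrm{window\_size}\right)$$

with $\lambda_a > \lambda_h$ reflecting the deeper coalescence of archaic
segments with the outgroup. Training is Baum–Welch (EM) in scaled
forward–backward arithmetic (C++ backend); the log-likelihood is
asserted non-decreasing at every iteration and training stops at
improvement `tol = 1e-4` or `max_iter = 1000`. Chromosomes — and separate
haplotypes, when a list of tracks is supplied — are independent chains
re-initialised from the start distribution. For cohort-scale runs the
package trains one shared parameter set on all haplotype tracks pooled;
per-track training is available through the same function, but pooled
estimates are far more stable for the transition rates, which are driven
by a few thousand archaic tracts cohort-wide.

Numerical choices: initialisation puts $\lambda_h$ at 96% of the
genome-wide mean rate and $\lambda_a$ at ten times that, with dwell-heavy
transitions (stay-human 0.999, stay-archaic 0.98) and the stationary
start distribution — far from the symmetric saddle where EM could not
separate the states, and near the density ratios seen in human–archaic
data. Windows with less than 10% of their span callable are masked from
emission entirely (exposure 0), which prevents spurious short segments at
mask edges; masked windows still pass transition information. A rate
floor of `1e-8` guards degenerate fits, and an all-zero observation track
is rejected with advice to fit a single-state model.

**Segment calling.** Posterior decoding gives the archaic-state
probability per window. Segments are maximal runs of consecutive windows
with posterior above 0.5 (a tie at exactly 0.5 counts as human —
conservative), retained when their *mean* posterior reaches the cutoff:
0.8 standard, 0.9 stringent. Coordinates snap to window bounds. No
minimum-length or minimum-observation filter is applied: whether such a
filter should exist is unstated in the sources this design follows, so
the default applies none and downstream code may filter. Note the
inherent resolution limit: with ~68-kb tracts and 1-kb windows, posterior
decoding extends a detected tract by a window or two on each side before
the evidence for the human state accumulates, so a few percent of called
bases fall just outside true tract boundaries even with exactly correct
parameters. The per-individual archaic fraction defaults to
*per-haplotype* accounting (summed segment bp over both haplotypes
divided by twice the callable genome); a `union` convention (merged
haplotypes over the callable genome) is available and documented.

## Source assignment

DAVs are the private derived variants inside a called segment. For each
archaic reference genome the *match rate* is the share of DAVs carried at
sites where that genome has an observed genotype; sites missing in a
genome are uninformative for it. Classification compares the best
Neanderthal-clade rate with the best Denisovan-clade rate: a clade wins
when its rate reaches `min_rate` and exceeds the other by `margin`; both
high within the margin is *Ambiguous*; everything else (including too few
informative sites) is *Unknown*. The thresholds
(`min_informative = 5`, `min_rate = 0.3`, `margin = 0.1`) are explicit
stand-ins — the partition thresholds used in comparable published
analyses are not printed — and are exposed and logged. A stringent mode
uses only clade-diagnostic sites (derived in exactly one clade, the other
clade observed ancestral in all its genomes) with majority vote.

One- versus two-pulse structure is read from the distribution of
per-segment match rates to a single reference: Gaussian mixtures with 1
and 2 components are fitted (via `mclust`) and chosen by BIC, with a
variance floor of `1e-4` short-circuiting degenerate rate sets to one
cluster. Two well-separated clusters — e.g. segments sharing ~84% of
DAVs with the sequenced Denisovan next to segments sharing ~47% —
indicate two source populations at different divergence from the
sequenced reference.

## Interval algebra and landscape scans

Assembled introgressed genomes, sharing partitions across populations,
rarefaction curves and downsampled comparisons are interval operations,
implemented on `GenomicRanges`. Per-individual contributions merge the
two haplotypes first, so a homozygous archaic tract counts once.
Rarefaction subsamples individuals *without* replacement (it asks how
much sequence $n$ individuals recover); downsampled cohort comparisons
bootstrap *with* replacement to get a confidence interval on the
difference at equal $n$. Both are seeded.

The frequency track records, per window, the fraction of haplotypes whose
called segments overlap it. Scans on it:

* **Enriched regions** — windows above the genome-wide mean + 2 standard
  deviations, adjacent windows merged (no gap tolerance). The sd is
  computed over windows with data; including masked windows would
  deflate it.
* **Deserts** — maximal runs of windows each below 0.1% frequency,
  retained at ≥ 10 Mb. Run semantics (every window below the limit)
  rather than a run-mean criterion: a mean criterion would let a single
  high-frequency island be diluted into a surrounding "desert", which is
  exactly what the scan must not do. Missing windows do not break a run
  and count toward its genomic length (deserts are genomic regions); a
  flag switches to callable-length accounting.
* **PBS** — the population branch statistic on archaic carrier
  frequencies, $\mathrm{PBS}_A = (T_{AB} + T_{AC} - T_{BC})/2$ with
  $T = -\ln(1-F_{ST})$. $F_{ST}$ uses the Hudson estimator with
  sample-size correction (the source analyses name no estimator; Hudson
  is the standard choice for unbalanced panel sizes), clamped to
  $[0, 1-10^{-9}]$.
* **Uniquely shared derived alleles** — sites carried by a test
  haplotype and one archaic clade, absent from the other clade and the
  outgroup; counted per region with percentile ranks.
* **Regional haplotype statistics** — per-group carrier frequencies and
  segment lengths, with a pooled-variance two-proportion z-score of each
  group against the others combined (the z construction is unstated in
  the sources; pooled variance is the textbook default).
* **ILS test** — the probability that a shared haplotype of length $m$
  survives from ancestral polymorphism rather than introgression. The
  expected ILS tract length is $L = 1/(r\,t_{\mathrm{split}})$ and the
  length law is Gamma(shape 2, mean $2L$), the standard construction for
  this test; an Exponential alternative is a flag. Parameters default to
  unset because the published p-values do not print the $r$ and
  $t_{\mathrm{split}}$ behind them.

## The coalescence clock

The human-state emission rate measures the density of variants private
with respect to the outgroup, which accumulate at $\mu T$ per bp over a
coalescence time $T$, so

$$T_{\min} = \frac{\lambda_{\mathrm{corrected}}}{\mu \cdot w},$$

with $\mu = 0.45 \times 10^{-9}$ per bp per year and $w$ the effective bp
per unit window. This is exactly the inverse of the generator's
private-variant law and is a *lower bound* on the coalescence time. Three
corrections mirror the biases of real pipelines: (i) archaic
contamination — the rate is re-estimated over windows not overlapped by
stringent (posterior > 0.9) archaic segments; (ii) phasing drop-out and
(iii) multi-allelic-site removal — both delete true private variants, and
the rate is divided by the joint survival
$(1-d_{\mathrm{phase}})(1-d_{\mathrm{multi}})$, treating the losses as
independent (their functional form is not published; independent
multiplicative loss is the natural model and is exact for the
generator). Loss fractions are configuration inputs on real data and are
measured from truth in the validation suite. Individuals with more than
1% outgroup-continent ancestry (strict inequality) are excluded first.
Cohort summaries use a seeded percentile bootstrap over individuals
(1,000 replicates) since the published interval construction is
unstated.

An earlier out-of-Africa wave contributing fraction $\alpha$ at depth
$T_{\mathrm{old}}$ shifts the expected rate to
$\mu w\,[(1-\alpha) T_{\mathrm{main}} + \alpha T_{\mathrm{old}}]$; the
admissible $\alpha$ interval is the part of a grid whose expected rate
falls inside the cohort bootstrap interval.

## Founder-event statistics

IBD/HBD tables (hap-IBD dialect: id1, hap1, id2, hap2, chrom, start, end,
cM) are filtered at 2 cM and against centromere overlap (any overlap
drops a segment). HBD rows are encoded as `id1 == id2`. HBD profiles
stratify at 8 cM (long segments: recent consanguinity; short: historical
founder events), with 20 cM as the alternative threshold. Closest-relative
curves report, per individual, the maximum total IBD shared with any
partner — all segments, all four haplotype pairs, no cap at the genome
length (matching the conventions of segment-detection output; a capped
variant is a flag) — optionally restricted to cross-sampling-unit pairs,
with a seeded subsample bootstrap (n = 500 by default) for cohort-size
comparability.

The closed-form expectation for kth-degree cousins is
$2G(1/2)^{2(k+1)}$ with $G = 6{,}782$ cM the diploid autosomal genome
size: siblings (k = 0) expect half the diploid genome, and each degree
divides the expectation by four. `classify_degree()` inverts it —
smallest $k$ whose expectation the observed total reaches, ties to the
closer degree — and always logs that the formula assumes random mating:
founder events inflate sharing, so inferred degrees are upper bounds on
relatedness distance.

## The synthetic cohort generator

`simulate_cohort()` produces the full input universe with truth:

* **Tracts** by a two-state Markov renewal process: exponential tract
  lengths with mean $1/(r\,t_a\,(1-p))$ bp and stationary archaic
  fraction $p$. This is deliberately not a coalescent simulation — the
  renewal model is the closed-form contract all validation targets refer
  to. Defaults: $p = 0.02$, $t_a = 1{,}500$ generations,
  $r = 10^{-8}$ (mean tract ≈ 68 kb).
* **Variants**: private derived variants at rate $\mu T_h$ per bp outside
  tracts ($T_h = 54{,}000$ yr) and $\mu T_{\mathrm{arch}}$ inside
  ($T_{\mathrm{arch}} = 648{,}000$ yr, a ~12-fold density contrast);
  outgroup-shared polymorphism at a configurable background rate
  (default $10^{-4}$ per bp), always carried by at least one outgroup
  haplotype and never reusing a private position. The REF allele is
  ancestral by convention (declared via the `AA` tag on output).
* **Archaic references** carry each tract variant with per-source,
  per-genome probabilities (`dav_share`); defaults emulate a
  Neanderthal-like source against four reference genomes, or a
  Denisovan-close (0.84) plus Denisovan-distant (0.47) pair with two
  sources. Reference genotypes go missing at 5% by default.
* **Nuisance processes**, all off by default and recorded in the cohort
  metadata for the clock corrections: multi-allelic thinning, phasing
  drop-out, phase-switch errors, and an earlier-wave mixture
  (`early_wave_prop` at 74,000 yr) for the two-wave bound.
* **Pedigrees**: gene-dropping through the pedigree connecting kth-degree
  cousins, Poisson crossovers at uniform map positions (Haldane model,
  no interference — the closed-form cousin expectation assumes exactly
  this), on a 22-chromosome human-like map scaled to
  $G = 6{,}782$ cM diploid.

What it does *not* emulate: realistic allele-frequency spectra (shared
sites draw frequencies uniformly), background selection, gene conversion,
recombination-rate variation, sex chromosomes, or genotype error. Passing
tests therefore demonstrate correctness of the inference machinery under
the stated generative model, not robustness to every artifact of real
cohort data. The default validation genome is 4 × 50 Mb with a 1 Mb
centromere gap per chromosome — chosen so a full cohort simulation,
training and decoding complete in a few minutes — with a flag-free path
to larger maps simply by passing 22 realistic chromosome lengths.

## Determinism

Every stochastic entry point takes a seed and derives all randomness from
it; rerunning any stage with the same seed and configuration reproduces
outputs byte for byte. Scans on fixed segment tables have no hidden
randomness.

## Known limitations

* Segment boundaries are window-quantised; sub-window precision is out of
  scope, and posterior-run calling overshoots true tract edges by a
  window or two at realistic emission contrasts (see above).
* The HMM has exactly two states; a second archaic source is separated
  downstream by match-rate clustering, not by extra latent states.
* The clock's corrections assume independent multiplicative variant loss.
* Cousin-degree classification inherits the random-mating assumption of
  the closed form; in founder-event populations it overstates closeness.
* `pulse_clustering` fits one-dimensional Gaussian mixtures; heavily
  skewed rate distributions at low DAV counts can favour two components
  without a real second pulse — inspect `n_informative` before reading
  cluster structure.
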