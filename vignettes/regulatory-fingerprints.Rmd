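---
title: "Regulatory fingerprints: models, parameters and design choices"
author: "creFingerprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory fingerprints: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creFingerprint)
```

# The problem

A cis-acting regulatory element (CRE) is a short DNA word near a gene that
modulates its transcription. Given (i) a genome with gene annotation and
(ii) a gene-by-array meta-matrix of M-values (log2 expression ratios from
many independent microarray comparisons), the package asks: *do the genes
that carry a given CRE in a given region behave differently from the rest
of the genome, and under which conditions?* The vector of per-array answers
is the CRE's **regulatory fingerprint**; it is diagnostic of the element's
biological role and of the trans-acting factors that read it.

Two complementary workflows are supported. The **reverse search** starts
from a catalog of known or suspected IUPAC patterns, scans gene-flanking
regions for them, and tests each carrier set for enrichment of induced or
suppressed genes in every array. The **forward search** starts from
co-expressed gene clusters, discovers candidate motifs de novo with a Gibbs
sampler, and feeds each discovery straight back into the reverse search.
Candidate transcription factors for a CRE are then ranked by correlating
the carrier set's per-array z-score profile with each TF's own expression.

# Regulation calls

Each array's genes are split into three states by a fold-change cutoff
$c$ (default 2):

* induced: $M \ge \log_2 c$,
* suppressed: $M \le -\log_2 c$,
* neutral: otherwise; missing M-values stay missing.

Both boundaries are inclusive: "two-fold induced" is read as *at least*
two-fold. Arrays whose M-value range is compressed can be given a lower
per-array cutoff (typically 1.5) through `per_array_cutoffs`; deciding
*which* arrays deserve it is a property of the data set, so it is left to
the caller rather than guessed from the data.

# The enrichment test and the fingerprint

For a carrier set of effective size $n$ on one array (genes with missing
calls are excluded), let $O_t$ be the observed number of genes in a target
state and $E_t = n\,\hat p_t$ its expectation under the genome-wide
proportion $\hat p_t$ of that state among all called genes. The test is a
1-df goodness-of-fit chi-squared on the binary split target-vs-rest,

$$\chi^2 = \frac{(O_t - E_t)^2}{E_t} + \frac{((n - O_t)-(n - E_t))^2}{n - E_t},$$

computed separately for induced-only, suppressed-only and combined
(induced+suppressed vs neutral) targets, yielding the three p-values
reported per cell of a fingerprint. Design decisions worth knowing:

* **No continuity correction and no multiple-testing correction by
  default.** Raw $p < 0.05$ defines significance; Benjamini-Hochberg
  across arrays is available behind a flag but is off by default.
  Expected cells below 5 are *flagged* (`low_expected`), not switched to
  an exact test.
* **The background population is the called genes of that array**, not
  all annotated genes: only measured genes can be induced or suppressed.
* **Direction is reported separately** (`enriched`/`depleted`), since
  chi-squared is sign-blind.
* The combined test is binary (1 df) by default; a 3-category, 2-df
  variant is available via `combined_classes = "three"` because the
  published wording admits both readings.

Two statistical properties of this construction matter when interpreting
calibration results. First, the carrier set is *part of* the background it
is compared against, which couples observed and expected counts and
deflates the test's variance by roughly $(1 - n/N)$ for a set of $n$ genes
in a genome of $N$; the test is therefore mildly conservative when the set
is a large fraction of the genome. Second, at small expected counts the
binomial discreteness makes the $\chi^2_1$ approximation conservative as
well — exactly the regime the `low_expected` flag marks. The null
calibration reported by the test-suite therefore uses 5,000 genes and a
300-gene set (expected induced count about 6.8), where the empirical
type-I rate sits close to the nominal 0.05; with a 200-gene set in a
2,000-gene genome it drifts to about 0.03, which is the method's honest
behaviour under those conditions, not an implementation artifact.

# Regions and scanning

Five strand-aware analysis regions are extracted per gene from FASTA +
GFF3: 1 kb and 3 kb upstream of the transcription start site, the 5'-UTR,
the concatenated introns, and 1 kb downstream of the translational stop
codon (which therefore includes the 3'-UTR). Regions are written 5' to 3'
in the gene's own reading orientation; internal arithmetic is 0-based
half-open while all I/O honours GFF3's 1-based inclusive convention. When
a gene has several mRNAs the longest genomic span is used, giving one
region per gene. Neighbouring genes are *not* masked out of upstream
regions, matching how pattern matching on fixed flanks is usually run.
Introns are joined with a run of 30 N's — longer than the maximum pattern
width of 25 — so no match can bridge two introns. The downstream region
starts at the base *after* the stop codon (the stop codon itself is
excluded; the convention is stated here because the literature leaves it
open).

Scanning follows PATMATCH semantics: a pattern over the 15-letter IUPAC
alphabet matches the exact set product of its positions; **all**
occurrences are reported, including overlapping ones (this is what "copy
number" counts); an N in the genome never matches any pattern position
(conservative). Both strands are scanned, except for patterns that equal
their own reverse complement (palindromes), which are scanned forward
only so occurrences are never double-counted. For upstream regions,
positions are reported as *upstream distance*: the 1-based distance from
the TSS to the occurrence base nearest the TSS, for both orientations.

Fingerprints can be stratified by position (200-bp bins of upstream
distance), orientation (genes with at least one forward hit vs at least
one reverse hit; meaningful only for non-palindromic patterns) and copy
number (exact counts 1, 2, 3, pooled ">=4"). Each stratum is tested
against the same genome background; strata below `min_stratum_n` (default
20) are flagged underpowered but still reported.

# Motif discovery

The forward search re-implements MotifSampler-style discovery as a seeded
**ZOOPS Gibbs sampler** (zero-or-one occurrence per sequence) over an
order-$k$ Markov background:

* **Background.** Conditional base probabilities per $k$-mer context,
  maximum likelihood with +1 pseudocount per cell; order 0-3, order 1 by
  default; training demands at least $100 \times 4^k$ bp. A valid base
  whose context contains an N falls back to the marginal composition.
  Separate models per region kind are recommended since their
  compositions differ.
* **Sampler.** Site prior 0.5 per sequence; every sweep resamples each
  sequence's site from the posterior over all windows on both strands
  (weights proportional to the PWM/background likelihood ratio) plus the
  no-site option. PWM pseudocounts are background-proportional. Defaults:
  width 8 (configurable 4-25, a range is searched), 200 sweeps, 10
  restarts; the best restart by total log-likelihood-ratio score wins.
  Windows containing N are strictly unsamplable — their background term
  carries a large positive sentinel so masked positions can never attract
  the chain.
* **Ranking and masking.** Additional motifs are found by masking the
  previous motif's sites to N and re-running, so successive motifs never
  share sites. Motifs are returned ranked by score; discoveries are named
  `OS_<REGION>_<NNN>` (`1K`, `3K`, `5U`, `UT`, `1D`) in discovery order.
* **Consensus.** Per PWM column, the smallest IUPAC code covering all
  bases with frequency at least 0.25 — this threshold reproduces the
  degenerate 8-mer style of published CRE catalogs.
* **Co-existing motifs.** The search is restricted to the sequences
  carrying an anchor CRE, with the anchor's occurrences masked to N by
  default (flag to disable, since unmasked co-occurrence discovery is
  also informative) and the background trained on *all* sequences of the
  region kind, not just the anchor-bearing subset.

The sampler makes no claim of reproducing any particular external
binary's scores; its priors and iteration counts are explicit package
choices, configurable in one place.

# TF association

For a carrier set and each array, the z-score is

$$Z = \frac{(X - \mu)\,\sqrt{n}}{\delta},$$

with $X$ the mean M-value of the set's genes present on the array, $\mu$
and $\delta$ the mean and standard deviation of **all** genes' M-values
there, and $n$ the effective set size. $\delta$ is the population
(n-denominator) standard deviation by default (configurable to sample).
The full-genome set has $Z \equiv 0$ by construction. $Z$ is undefined
(missing, flagged) only when no set gene is measured on the array or the
genome variance is zero; a singleton set is legitimate ($n = 1$).

Each TF's expression row is then correlated with the Z profile over
pairwise-complete arrays ($n_{\text{pairs}}$), requiring
$n_{\text{pairs}} \ge \lceil 0.8\,A \rceil$ of the $A$ arrays — the
published fixed threshold generalised to its stated 80% rationale. The
statistic is

$$T = r\sqrt{\frac{n_{\text{pairs}} - 2}{1 - r^2}},$$

tested two-sided against $t_{n_{\text{pairs}}-2}$ (sidedness is a package
choice; the literature does not state it). Strength classes: strong when
$|r| \ge 0.5$, moderate when $0.3 < |r| < 0.5$, weak when $|r| \le 0.3$
(the weak band is applied symmetrically in $r$, a deliberate smoothing of
an asymmetrically-worded source). A TF is flagged *autoregulated* when
its own 1-kb upstream region carries the CRE. The exported network keeps
edges with $|r| \ge 0.45$ (inclusive), sorted by $|r|$ then p-value.
"Fold-change values" of a TF are its M-values in the meta-matrix — the
only fold-change the data model defines.

# The synthetic-data generator

Every stage is testable without downloads because the generator emits
standard files with complete ground truth:

* **Genomes** (`make_genome`): contigs of order-1 Markov sequence with
  configurable GC (default 0.43, rice-like — a modelling choice, not a
  measured value), carrying gene models on alternating strands, each with
  a 5'-UTR, two exons, one intron and a 3'-UTR, spaced so every gene has
  full upstream and downstream regions.
* **Planting** (`plant_motifs`): exact carrier fractions, copy-number and
  position-bin distributions, orientation policies; each site
  instantiates one concrete word drawn uniformly from the degenerate
  expansion; planted sites never overlap. By default the target region is
  first *scrubbed* of chance occurrences of the pattern, and junction
  artifacts (matches spanning a planted word and its flank) are repaired
  afterwards — so the truth table and the scanner agree occurrence for
  occurrence, which is what makes exact-recovery tests meaningful.
* **Expression** (`simulate_expression`): baseline
  $M \sim \mathcal N(0, 0.5)$ everywhere; a responder fraction (default
  0.5) of carriers is shifted by $\pm\Delta$ (default 1.5) with noise sd
  0.5 in designated arrays; missingness injectable completely at random.
* **TF rows** (`simulate_tf_profiles`): $c\,Z + \varepsilon$ with the
  scale chosen so the population correlation equals the target exactly.

What the generator deliberately does **not** emulate: correlation
structure between arrays (real meta-matrices have plenty; no model for it
is defined here), probe-level microarray noise, repeat content, nested or
overlapping genes, and alternative transcripts. Passing tests on this
synthetic data therefore demonstrate the *algorithmic* correctness and
calibration of the pipeline, not robustness to every pathology of real
expression compendia.

# Numerical and reproducibility choices

* All randomness flows through explicit integer seeds; internal RNG use
  saves and restores the caller's RNG state, and the compiled hot loops
  (Markov sequence simulation, Gibbs window scoring) draw from R's own
  RNG so results are reproducible across the R/C++ boundary.
* K-means clustering (used only to seed forward searches) is Lloyd's
  algorithm with $k$ distinct seeded rows as initial centres, a 100
  iteration cap; genes with more than 50% missing cells are dropped and
  the rest mean-imputed per array for the distance computation only.
* p-values of 0 are reported as the smallest positive double rather than
  0, and $|r| = 1$ correlations carry an infinite-T sentinel.
* Reports are written with fixed numeric formatting, so identical inputs
  produce byte-identical files.

The test-suite and the acceptance script run the pipeline at desk scale:
genomes of 100-2,000 genes, 8-24 arrays, 1,000 null array-tests, 200
power replicates, 5-10 discovery seeds, 231-array TF panels with 220
TFs. These sizes are the package's own benchmark design; the demo
scenario (2,000 genes, 24 arrays, two planted CREs, 20 planted strong TFs
among 200 decoys) exercises both workflows end to end.

# Known limitations

* The chi-squared enrichment inherits the conservativeness discussed
  above for carrier sets that are large relative to the genome, and the
  approximation degrades below five expected counts (flagged, not
  corrected).
* The Gibbs sampler assumes at most one site per sequence (ZOOPS); genes
  with tandem motif arrays contribute only one site to discovery, though
  scanning and copy-number stratification see all copies.
* Orientation stratification is undefined for palindromic patterns and
  the package refuses to over-interpret it.
* With ~200 arrays, a TF-CRE correlation of 0.45 is highly significant
  but still explains only ~20% of variance; the strength bands are
  conventions for triage, not effect-size guarantees.
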