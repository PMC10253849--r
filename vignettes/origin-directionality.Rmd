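---
title: "Classifying unidirectional and bidirectional replication origins from strand-specific nascent-strand data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying unidirectional and bidirectional replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriSSDS)
```

## The model

Classical origins of replication fire two divergent forks. In
strand-specific short-nascent-strand sequencing (ori-SSDS) this produces a
distinctive two-sided signature: the leftward fork synthesizes its nascent
leading strand on the Crick (−) strand, the rightward fork on the Watson
(+) strand, so a bidirectional origin peak shows Crick reads in its left
half and Watson reads in its right half. A peak whose reads sit on a
single strand on *both* halves instead suggests replication proceeding in
only one direction — a unidirectional origin, plausibly caused by a
replication fork barrier such as a G4 quadruplex on the blocked leading
strand.

`oriSSDS` operationalizes this as follows. Each peak is split at its
middle, the 0-based position $m = \lfloor (start + end)/2 \rfloor$, and
reads are assigned to the left or right half by their own midpoints (a
read midpoint exactly at $m$ counts right — the same half-open tie rule
used everywhere in the package). With $f_L$ and $f_R$ the Crick-read
fractions of the two halves,

* **CO** (Crick-only): $f_L > 0.5$ and $f_R > 0.5$;
* **WO** (Watson-only): $f_L < 0.5$ and $f_R < 0.5$;
* **ORI** (bidirectional): Crick left, Watson right, i.e. $f_L > 0.5$,
  $f_R < 0.5$;
* **OTHER**: the remaining quadrant;
* **UNASSIGNED**: a half with zero reads, or a fraction exactly 0.5 —
  strict inequalities leave such peaks in no quadrant, and they are
  excluded from all downstream per-class analyses.

The source material is internally inconsistent about which mixed quadrant
is the bidirectional one: the written classification rule places origins
at $f_R > 0.5, f_L < 0.5$, while the accompanying schematic and the fork
biology (nascent leading strands point away from the origin) put Crick
reads on the left. We implement both readings; the default
`orientation = "figure1b"` follows the schematic/biology, and
`orientation = "methods_literal"` swaps ORI and OTHER. Nothing else in the
pipeline depends on the choice, and CO/WO calls are identical under both.

Fork direction is validated independently with Okazaki-fragment (OK-seq)
reads: fragment strand encodes fork direction, so with $F$ and $R$ the
Watson- and Crick-strand read counts per 1 kb bin,

$$\mathrm{RFD} = \frac{R - F}{F + R} \in [-1, 1],$$

undefined where $F + R = 0$. Meta-profiles average RFD in 40 windows of
50 kb anchored at peak midpoints: a genuine origin shows RFD < 0
immediately left of the midpoint and > 0 immediately right, with a single
zero crossing. Window RFD is computed from *summed* counts rather than by
averaging per-bin RFD values — robust to empty bins, and identical to the
count-weighted mean of bin RFDs (an algebraic identity the test suite
asserts). Windows are snapped to the bin grid at the anchor bin; windows
extending past a chromosome end are skipped for that peak rather than
truncated, which maximizes usable peaks on small genomes.

## Feature association

Feature enrichment compares each peak class with length-matched random
control regions: the control set has the identical multiset of interval
lengths, each placed uniformly over allowed genome-wide positions (not
per-chromosome), overlaps permitted, optionally avoiding a mask. Overlap
is strand-blind and requires one shared base; annotation precedence is
promoter > gene > intergenic with promoters defined as TSS ± 1 kb. Counts
are compared by chi-squared without continuity correction (matching the
large-count regime of genome-scale peak sets) or Fisher's exact test. By
default one matched control set is drawn per peak set; this is
configurable, and the RFD random control deliberately pools many sets (see
below).

The discriminating analysis is G4 strand asymmetry. Per peak, overlap is
evaluated separately against Watson- and Crick-strand G4 intervals; peaks
touching G4s on both strands are excluded and the remaining exclusive
calls are tested per class against a 50:50 split. Flank counting tallies
every G4 in the 2 kb window around the peak center once (no proration —
the unit of observation is a quadruplex, not a base), with a side
breakdown by G4 midpoint. At bidirectional origins each flanking G4 is
also folded into leading/lagging coordinates: left of the center the
nascent leading strand is Crick, right of it Watson, so a G4 whose strand
matches its side's leading-strand label is "leading". Both the raw
per-strand and the folded tables are emitted, since either convention is
defensible for flank counting.

Expression uses $\mathrm{RPKM} = \mathrm{CPM} / (\mathrm{length}/1000)$
with a strict RPKM > 5 cut. ATAC accessibility is a per-peak midpoint read
count compared with Welch's two-tailed t-test (R's default t-test
variant). Replication timing is read at the peak midpoint; the genome
background is the track's segment values weighted by segment length, and
distributions are compared with two-sample KS tests. The
transcription-direction analysis records, for each unidirectional peak
overlapping exactly one expressed gene, that gene's strand, and tests the
CO/WO × strand table; peaks with zero or multiple overlapping expressed
genes are excluded and counted. No multiple-testing correction is applied
anywhere — the reported p-values are raw, per test.

## The synthetic study

Real ori-SSDS, OK-seq, RNA-seq, ATAC-seq and G4-seq inputs are external
accessions; the generator replaces them with a fully specified study whose
truth is known, so every stage is testable end to end. The defaults are
the study conditions; they are set once and the tests are written against
them.

| parameter | default | meaning |
|---|---|---|
| `nChrom` × `chromLength` | 2 × 10 Mb | genome size |
| `nORI`/`nCO`/`nWO` | 200/50/50 | planted class counts (2:1 bidirectional:unidirectional, the regime reported for strand-specific origin data) |
| `efficiency` | 50 | Poisson mean SNS reads per firing side |
| `snsHalfwidth` | 1000 bp | nascent-strand extent per side |
| `snsReadLength` | 150 bp | fixed read length, uniform start in the flank |
| `barrierStrength` | 1 | P(blocked side yields no reads); all-or-none |
| `strandSwapNoise` | 0.05 | per-read strand flip probability |
| `backgroundRate` | 1e-7 | background reads per bp per strand |
| `minSpacing` | 4 × halfwidth | minimum origin separation |
| `okDensity` | 0.01 /bp | OK-seq read density |
| `g4PerOrigin`, `g4Beta` | 2, 0.75 | G4s per origin in the firing flank(s); P(Watson) at CO, mirrored at WO, 0.5 at ORI |
| `promoterPlacement`, `expressedPlacement` | 0.45, 0.25 | origin placement mixture |
| `rtAmplitude`, `rtBumpHalfwidth` | 2, 20 kb | early-RT bump at origins |
| `atacFold` | 3 | ATAC density ratio inside origin peaks |

Design choices worth recording:

* **Peaks are emitted by the generator, not called from reads** — peak
  calling is out of scope (published peaks are the real-world input), so
  the peak interval is the nominal span of the flank(s) that fired.
* **OK-seq forks propagate on both sides of every origin**, including CO
  and WO. This encodes the central observation the pipeline is built to
  reproduce: blocked forks resume, so fork direction switches in the
  middle of unidirectional peaks too. How long blocked forks pause is not
  modelled; OK-seq reflects fully resumed replication.
* **Placement mixture**: 45% of origins are planted in promoter windows
  and 25% inside expressed gene bodies. Under the default gene density
  (one ~5 kb gene per 10 kb slot at 80% occupancy, half expressed) this
  yields observed/control overlap ratios close to 2× for both features —
  the planted preference the enrichment stage must detect.
* **RT bump halfwidth is 20 kb**, not larger: at 300 origins on 20 Mb,
  ±50 kb bumps would tile the genome and make the genome-background RT
  distribution identical to the peak distribution, leaving the KS
  comparison nothing to detect. 20 kb covers ~60% of the genome, which
  still separates cleanly (D ≈ 0.5).
* **The RFD random control pools 25 matched sets** in the acceptance-grade
  profile. With noise-free OK-seq each anchor's window RFD is ±1, so a
  control profile over $N$ anchors has per-window SD ≈ $1/\sqrt{N}$; with
  80 peaks and 25 sets ($N = 2000$, SD ≈ 0.022) the flatness band of 0.1
  sits at ≈ 4.5 SD, making the check stable by construction rather than by
  seed luck.
* **Determinism**: one seed in the spec governs every stage (each stage
  derives a fixed offset seed), and two runs of the same config are
  byte-identical — asserted on file checksums.

What the generator does *not* emulate: sequence-level G4 motifs (G4s are
labelled intervals), SNS size selection, mappability masks, partial
barriers (the all-or-none barrier has a configurable escape probability
but no read-attenuation mode), replication-timing stochasticity, and any
cross-tissue structure. Passing tests therefore demonstrate that the
analysis recovers planted structure of the stated kind and strength — not
that real data contain such structure.

## Problem sizes and tolerances

The test suite runs the generator at its default scale (300 origins,
20 Mb) for classification and feature checks, a 300 Mb / 80-origin genome
with ≥ 2.2 Mb spacing for the isolated-origin RFD signature, and reduced
3–6 Mb configurations for pipeline determinism — sizes chosen so the whole
suite completes in about a minute on one core while keeping every
statistical margin wide (the weakest planted effect in the suite exceeds
its detection threshold by several standard deviations). Classification
robustness is asserted at ≥ 95% label accuracy under 5% strand-swap noise
with ~50 reads per side; in practice recovery at these settings is
complete, since a side's majority strand flips only if half of ~25
Bernoulli(0.95) draws fail.

## Limitations

The classifier conditions on published peak intervals and inherits their
boundaries; fractions near 0.5 with few reads are noise-sensitive (the
UNASSIGNED rule removes only exact ties and empty sides); the
leading/lagging fold assumes the two-fork geometry and is therefore
restricted to ORI-class peaks; and the transcription-direction contract
(single-overlapping-gene) is one of several defensible readings and is
labelled as such in the output tables.
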