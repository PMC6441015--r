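---
title: "poredose: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poredose: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poredose` reproduces, as tested code, the quality-control analysis used to
assess how ionizing radiation degrades nanopore sequencing: event-level read
quality (skips and stays per base), alignment quality and genome coverage,
platform-QC pore counting, time-resolved throughput, and per-dose comparison
against unirradiated controls. Because the raw data of such experiments live
on proprietary instruments, the package is built around a synthetic run
generator whose statistical structure matches what the analysis consumes.
This vignette explains the models, the defaults, and the choices made where
the design was genuinely open.

## The event model and read metrics

The detector reports one *event* per k-mer residency (k = 5 by default: the
pore senses five bases at a time). Each event carries a `move`: how many
bases the *called sequence* advanced since the previous event. The package
fixes the move grammar of simulated reads to {0, 1, 2}:

* **stay** (`move = 0`): an extra event on the same k-mer. An N-event dwell
  counts as N − 1 stays; the first event of a read always has `move = 0`
  because it merely establishes the initial k-mer and no translocation
  decision precedes it — it is excluded from stay counting.
* **step** (`move = 1`): ordinary single-base advance.
* **skip** (`move = 2`): a k-mer that produced no event. In the generator a
  skip advances *three* template bases while calling two of them, so exactly
  one template base is deleted from the basecall per skip. This keeps two
  identities exactly true at once: the called length equals
  `k + sum(move)` for every read (the fast5-style move convention, asserted
  over every simulated bundle), and each skip contributes one deletion to the
  read/reference alignment.
* **insertion**: realized as an extra event (`move = 1`, no template
  advance) calling a random base, again preserving the length identity.

Per-read metrics follow directly: `read_length = k + sum(move)`,
`n_stays = #{move = 0 after the first event}`,
`n_skips = sum(pmax(move - 1, 0))`, each divided by read length for the
per-base rates. `read_metrics()` accepts any event table with this schema,
not only simulated ones; a first move other than 0 is rejected as malformed.

**Pooling.** Condition-level rates are base-weighted by default
(`sum(n_skips) / sum(read_length)`), which is robust to short reads; the
unweighted per-read mean is available via
`pool_metrics(..., method = "per_read_mean")` because published analyses do
not always state which convention they use. Empty conditions report a read
count of 0 and *absent* (NA) rates — a dead flow cell has no rates, not
zero rates.

## The degradation model

Radiation-tolerance experiments measure degradation but do not provide a
generative model, so the generator uses the fewest parameters that reproduce
the qualitative pattern seen in such data (healthy at low dose, elevated
skips/stays and falling identity at mid dose, outright failure at high dose):

| parameter | meaning | unit | default |
|---|---|---|---|
| `d50_pore` | dose at 50% pore survival | Gy | 400 |
| `hill` | survival steepness | — | 4 |
| `p_stay0`, `c_stay` | stay probability per event, baseline + per-gray slope | —, Gy⁻¹ | 0.10, 1e-4 |
| `p_skip0`, `c_skip` | skip probability per event | —, Gy⁻¹ | 0.04, 5e-5 |
| `p_sub0`, `p_ins0`, `c_err` | basecall substitution/insertion rates, shared slope | —, Gy⁻¹ | 0.06, 0.02, 2e-4 |
| `drift_pA_per_gray` | in-sequencing current shift | pA/Gy | 0.02 |
| `d_fail` | dose at/above which a run yields zero reads | Gy | 500 |

Survival is Hill-type, `1 / (1 + (dose/d50)^hill)`; every rate is
`clamp(r0 + c·dose, 0, 0.95)`; the run is alive only below `d_fail`. The
baselines give a zero-dose base identity in the mid-to-high 80s percent,
typical of this read chemistry, and `d_fail = 500` reflects that flow cells
at 500 and 750 gray in the motivating experiments produced no reads at all.
Whether such failures are protein damage or electronics damage is unknown;
the model deliberately conflates both into survival plus `d_fail` and
attributes no mechanism.

The per-gray slopes are a deliberate simplification: they are linear from
dose zero, so a 50-gray run is *slightly* degraded in expectation rather
than exactly unchanged. The package's dose-ladder tests therefore assert the
qualitative, ordered pattern (throughput and coverage preserved at 50 gray;
strict skip/stay elevation and identity drop at 300 gray; zero reads at and
beyond `d_fail`) rather than "no change at 50 gray" literally.

## The run generator

A run uses the full flow-cell geometry: 2048 wells in 4 rotation groups of
512; MUX period *p* monitors group *p mod 4*; reads are drawn only from
alive wells of the monitored group, with Poisson counts at
`mean_reads_per_active_channel_per_hour` (default 30, sized so a healthy
24-hour run produces a few hundred thousand reads) and uniform start times
within each period. Wells die independently with probability
`1 − survival(dose)` at simulation start.

Fragment lengths are log-normal (default meanlog `log(3000)`, sdlog 0.5);
strands are equiprobable; fragment *ends may truncate at the molecule
boundaries* with at least 200 bases retained. The truncation matters: a
linear genome that is physically fragmented produces terminal fragments, and
without them the first and last positions of the reference would almost
never be covered, making "complete coverage" unattainable by construction.
The 200-base floor keeps every read above the aligner's default 100-base
span gate.

The per-read event walk draws i.i.d. stay/skip/insert/step decisions until
the fragment is consumed. A trailing skip may overshoot the nominal fragment
end by up to two bases; the realized fragment simply extends (shifting left
only at the reference edge) rather than demoting the skip, so event-type
fractions remain exactly binomial — this is what lets the recovery tests
check pooled stay/skip fractions against the generator probabilities with
plain binomial standard errors. Event currents come from a synthetic pore
model (every k-mer assigned a mean level uniform in 60–130 pA, sd 1.5–3 pA)
plus Gaussian noise, the dose drift, and exponential dwell times (rate
400 s⁻¹). Barcoded runs prepend the barcode to the template *before* the
walk, so barcodes suffer the same error process as the insert.

All randomness is seeded; identical inputs and seed reproduce bit-identical
bundles, and the pipeline expands one master seed per condition.

## Alignment

The built-in aligner is semi-global — query fully aligned, reference ends
free — with unit scores (match +1, mismatch −1, linear gap −1), evaluated on
both strands. Two numerical choices matter:

* **Determinism of ties.** The DP maximizes (score, matches)
  lexicographically. For a fixed optimal score S the number of alignment
  columns is `2·matches − S`, so identity `matches / (2·matches − S)` is
  strictly increasing in matches: the lexicographic optimum *is* the
  highest-identity optimal alignment, with remaining ties broken toward the
  smaller reference start and the plus strand. The test-suite oracle (an
  independent full-matrix DP) uses the same rule, which is why oracle
  comparisons can demand exact equality instead of closeness.
* **Banding.** On references longer than 2000 bases the DP is restricted to
  a diagonal band of half-width `max(32, 0.2 × query length)` centered on
  the median diagonal of exact 11-mer seed matches (repetitive seeds with
  more than 16 hits are ignored). A strand needs at least 4 co-diagonal
  seed votes to be attempted; foreign sequences and the wrong strand
  typically produce none and are reported unaligned. The expected diagonal
  drift of a read, `(p_skip − p_ins) × length`, is an order of magnitude
  smaller than the band. At or below 2000 reference bases the band covers
  the whole matrix, so small-scale results are exhaustive optima.

Reads are flagged `aligned` when identity ≥ `min_identity` (default 0.55 —
permissive for high-error reads, far above what a random placement achieves
on a long reference) and the query is at least `min_span` (default 100)
bases. Identity counts all alignment columns in its denominator
(`matches + mismatches + insertions + deletions`); the alternative
denominator without deletions is exposed as
`align_read(..., identity_denom = "query")`. Coordinates are 0-based
half-open throughout; coverage depth over the reference satisfies
`sum(depth) = sum(aligned span lengths)` exactly, and coverage is *complete*
when every position has depth ≥ 1.

**Demultiplexing** scans the first 100 bases for the barcode with minimum
infix edit distance (barcode fully consumed, window ends free); a read is
assigned only when that distance is ≤ `max_edit` (default 3) *and* strictly
beats the runner-up — equidistant queries are `unclassified`, mirroring how
low-quality reads fail barcode assignment. The default 12-barcode set uses
24-base sequences with pairwise edit distance ≥ 10.

## Platform QC

The vendor's pore-counting classifier is proprietary; the package uses the
simplest testable stand-in with the right interface: a well is active iff
its open-pore current lies in a closed window (default 180–280 pA) and its
current noise is at most 15 pA. Boundary values count as active — a
deterministic, documented convention. Counts are per *well* (whether the
vendor counts wells or channels is unstated; this package says what it
counts). Simulated well observations are class-separable by construction
(alive wells draw currents strictly inside the window, dead wells strictly
outside), so QC recovery tests isolate the binomial sampling of pore
survival; the dose current drift applies to in-sequencing event levels, not
to open-pore QC currents, which are a separate measurement.

## Dose tables and the worst-control rule

Per-condition summaries are compared metric-by-metric against the *worst
performing control*: higher-is-better for reads, % aligned, base identity
and mean read length; lower-is-better for skips and stays per base. A metric
is flagged only when *strictly* worse — equality is not a drop. Zero-read
conditions appear as rows with absent quality fields and are excluded from
both the control envelope and flagging, the way failed high-dose runs are
reported. No holistic per-condition verdict is synthesized; whether
"performance" is per-metric or holistic is left to the reader, so the flags
are reported per metric. Time-chunked series additionally report
`stopped_at_mux_boundary`: true when a run with at least one read has an
empty trailing chunk and its last read start lies within one chunk width of
a positive multiple of the MUX interval (default chunks of 10 minutes
resolve the 8-hour boundary into 48 points).

Dosimetry helpers are exact arithmetic: exposure (roentgen) × 0.008656
gray(Si)/R — the photon-energy-dependent equivalence for ~1.25 MeV gammas in
silicon — dose-rate × time, and daily-dose × days transit accumulation.

## Problem sizes and what the tests show

The test-suite and acceptance script run at desk scale, chosen as the
package's own working sizes: references of 1–48.5 kb (the largest matching
the lambda-phage genome scale), runs of a few hundred reads for end-to-end
checks, ~2000 reads for rate-recovery checks (≈10⁶ translocation decisions,
giving 3-SE binomial bands of about ±0.001), 200 random pairs (length ≤ 50)
for oracle equality, and 6 doses × 20 seeds for QC survival tracking.

Passing tests demonstrate internal consistency — conservation laws, seeded
reproducibility, oracle-exact alignment, unbiased rate recovery, and the
qualitative dose-response shape. They do *not* validate the generator
against real instrument data: real pores have correlated failures, k-mer-
and homopolymer-dependent error, time-varying translocation speed, and
basecaller-specific artifacts that the i.i.d. decision model deliberately
omits. Headline numbers from physical experiments (read counts in the
hundreds of thousands, specific alignment percentages, pore-count tables)
are measurements of irradiated devices and are not reproduced — only their
qualitative structure is.

## Known limitations

* No raw-signal ("squiggle") simulation below event level, and no
  basecaller model: reads are emitted already called.
* Moves are restricted to {0, 1, 2}; real event tables occasionally contain
  larger moves (the metrics code handles them; the generator never emits
  them).
* The aligner reports one interval per read — no split or chimeric
  alignments, and no SAM/BAM emission.
* Reagent chemistry is not modeled separately from its effect on read
  quality; dose-rate effects and non-photon radiation are out of scope.
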