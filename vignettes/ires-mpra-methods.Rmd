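---
title: "Quantifying IRES and cap-dependent translation from pooled reporter assays"
author: "iresMPRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying IRES and cap-dependent translation from pooled reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and its statistical model

A pooled reporter library places each candidate 5' UTR on two co-transfected
mRNA reporters: a G-cap version (standard m7G cap, measuring cap-dependent
initiation, CDI) and an A-cap version (non-functional adenosine cap followed
by a stable stemloop, so that only internal ribosome entry produces
translation). Nascently translating mRNAs are affinity-purified; sequencing
of the immunoprecipitated (IP) and input pools, demultiplexed by a short
cap-class barcode carried in the A-cap 5' UTRs, yields unique-molecule
counts per (construct, cap class, sample). Translation efficiency is

$$\mathrm{TE} = \log_2 \frac{\mathrm{RPM}_{IP}}{\mathrm{RPM}_{input}},$$

computed independently for the A-cap (IRES TE) and G-cap (CDI TE) reporters
of each construct. RPM normalization runs over the *whole* sequencing
sample, both cap classes together: the two classes come from one pool split
in silico, and per-class normalization would erase the genuine global
difference between IRES and CDI recruitment that the IRES-as-percent-of-CDI
statistic depends on.

Because RPM is a composition, TE values are *relative*: the model predicts
every estimate is shifted by the constant $\log_2(T_{in}/T_{IP})$, where
$T$ are the pool totals of abundance and abundance x TE respectively.
Comparisons within an experiment (ranking, fold changes, percentages,
activity calls) are unaffected; parameter-recovery statistics in the test
suite remove this constant analytically from the simulation truth.

## Read architecture and processing dialect

The simulator emits read pairs over a fixed fragment layout (mate-1
orientation):

```
[stagger 0-6 nt] [5' anchor CTTAATCACAGATCT] [cap adapter (17 nt)]
[UTR insert] [common adapter AGATCTGTGATTAAG] [rc(RT anchor)] [rc(UMI 9-11)]
```

Mate 1 is the first 150 nt of the fragment, mate 2 the first 150 nt of its
reverse complement, so mate 2 begins with the UMI followed by the fixed
15-nt reporter-side RT anchor. The 5' anchor is the reverse complement of
the common adapter, mirroring the cloning-site origin of both. The exact
primer geometry of the wet assay is not published; this layout is the
package's abstraction and is self-consistent between simulator and
processor. One consequence: in paired (unmerged) mode the cap adapter is
searched on mate 1, adjacent to the 5' anchor, because for exactly the long
fragments that fail to merge the far end of the fragment - where mate 2
would see it - is out of reach.

Processing follows a two-dialect adapter policy. Merged single reads use
exact matching (zero mismatches) for the common adapter and both cap
adapters; unmerged pairs allow `floor(0.07 x adapter length)` mismatches
(one for 15-17-nt adapters). Reads matching neither or both cap adapters
are `unassigned` - a value, not an error - and reads whose UMI anchor
cannot be located are dropped from counting. Merging itself is a best
ungapped overlap of mate 1 against the reverse complement of mate 2, with
consensus disagreements resolved toward mate 1 (which covers the UTR 5'
end, where the cap-class adapter lives).

Alignment is replaced by exact/near-exact ungapped Hamming matching against
the known construct set (default budget: 2 substitutions), with an explicit
`ambiguous` class for tied best hits that is discarded, never broken at
random. References are short and fully known, and a handful of mis-mapped
reads is enough to fake weak IRES activity, so a conservative matcher is
preferable to a heuristic aligner. Unmerged pairs are matched against
same-length reference *prefixes*; scanning-mutant siblings whose
distinguishing window lies beyond the observed prefix become ambiguous and
are excluded, which is the conservative direction.

Duplicate removal is two-staged, as in the assay: a first collapse of
identical (insert, UMI, stagger, cap class) tuples - stagger differences
survive this stage by design - and a final unique-UMI count per (construct,
cap class, sample). UMI matching is exact; no near-duplicate clustering.
At very high per-construct depth, unique-UMI counts saturate slightly
(birthday collisions in a 4^9-4^11 UMI space), a property shared with any
unique-UMI protocol; at the depths used here the effect is at the
percent level.

## Quantification parameters

| parameter | default | role |
|---|---|---|
| `minInput` | 10 counts | a (construct, cap class) with fewer than 10 unique UMIs in *any* input library is removed; exactly 10 is retained |
| `pseudocount` | 0.000001 | replaces zero IP counts before RPM scaling; such rows are flagged `ip_pseudocounted` and treated as display floors, not estimates |
| `maxMismatches` | 2 | Hamming budget for construct assignment |
| `minOverlap`, `maxMismatchRate` | 20 nt, 0.1 | pair merging |
| `thresholdConstruct` | `"CrPV"` | activity boundary: a construct is `active` iff its A-cap TE is at least (inclusive) the CrPV IRES A-cap TE from the same experiment |

Technical replicates are summed first, then biological replicates, with
Pearson correlation QC available between the two steps; correlations
exclude constructs with zero IP counts in either member of a pair.

## Spike-in anchored stress comparisons

Three G-cap spike-in reporters, serially diluted 1:10:100 and added from a
single unstressed lysate to 1% of every sample, anchor cross-condition
comparisons. Their ribosome loading is fixed before mixing, so any apparent
TE change of the spikes between conditions measures a global technical or
physiological shift rather than construct-specific biology. The package
defines the per-condition factor as the geometric mean over the three
spikes of $TE_{spike}(\mathrm{ref}) / TE_{spike}(\mathrm{cond})$ - robust
on a three-point log scale - and multiplies the condition's TEs by it; the
reference condition has factor 1 by construction. The reciprocal of the
factor is the measured global shift (a uniform halving of IP efficiency in
the treated lysate gives a factor of 0.5, i.e. a measured 2x shift). The
spikes are G-capped; applying their factor to both cap classes assumes the
global shift is shared, which is the design's working assumption. A
per-condition linearity $R^2$ (observed log spike input RPM against the
designed log dilution) reports whether the dilution series behaved.

Two caveats follow from the arithmetic. First, the factor measures the
shift of the spikes *relative to the whole pool*: constructs exempt from a
"global" effect dilute it, so validation scenarios keep exempt constructs
to a small slice of the pool. Second, spike-in 1 is ~1e-4 of all molecules
(1% x 1/111), so factor precision is limited by its counts; the validation
suite therefore simulates these scenarios at the count level (below) at
1e7-4e7 molecules.

## The synthetic-data generator

`buildTruth()` fixes the study conditions: UMI lengths 9-11 (uniform),
stagger 0-6 nt (uniform), substitution errors i.i.d. at 0.001 per base
(typical short-read error), PCR duplicates per molecule geometric with mean
1.5, spike dilution 1:10:100 at 1% of the pool, input abundances log-normal
(sdlog 1) and true log2 TE uniform on [-5, 5] unless fixed. `simulateReads()`
draws molecule counts multinomially - weights are abundance for input
samples and abundance x TE for IP samples - assigns each molecule a random
UMI, and emits geometric PCR-duplicate read pairs differing only in
stagger, with a per-read truth sidecar. Output is bit-identical for
identical (truth, seed).

`simulateCounts()` / `simulateCountMatrix()` draw the exact count-level
marginal of the same generative model (multinomial molecule counts; UMI
collisions are negligible in a >= 4^9 UMI space). They exist for
deep-coverage designs - spike-in factor precision, group-level stress
shifts - where per-read FASTQ realism adds nothing and read-level
simulation would take orders of magnitude longer. Everything that tests
the read *processing* itself runs read-level.

What the generator does not emulate: indel sequencing errors, quality-score
structure (the pipeline ignores qualities), optical duplicates,
adapter-dimer artifacts, UMI-specific amplification bias, and
cross-contamination between constructs. Passing tests therefore demonstrate
correctness of the pipeline's logic and its statistical behavior under the
stated noise model, not robustness to every artifact of real libraries.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
unique-UMI counts against a brute-force tally of distinct (construct, cap
class, UMI) triples in the simulator sidecar (10^3-10^5 reads, exact
equality); error-free simulations against per-read sidecar labels (zero
tolerance); TE recovery on 500 constructs x 2 cap classes at 10^6 read
pairs per sample; spike dilution recovery on a spike-only pool at 10^5
reads; stress scenarios at 10^7-4x10^7 count-level molecules; design
algebra and the exact rank-sum null against closed forms (the 2-vs-2
complete separation gives p = 1/6 by enumeration).

One quantitative note on TE recovery. With true log2 TE uniform on
[-5, 5], rank recovery is excellent (Spearman ~0.99), but the plain ratio
estimator's RMSE against truth is bounded below by counting noise: from
the realized counts of the standard run the Poisson floor is ~0.28 log2
units, and the observed RMSE is ~0.31-0.33, about half of which comes from
the ~4% of rows whose true TE near 2^-5 leaves single-digit IP counts even
when the input side is deeply covered. An RMSE materially below 0.3 at
this depth is achievable only without PCR duplication and sequencing
errors. The corresponding check in the acceptance suite asserts the 0.3
bound and is expected to fail by that margin; it is kept as an honest
record of the estimator's noise floor rather than relaxed. Zero-IP
(pseudocounted) rows are excluded from recovery statistics - their TE is a
reporting floor, not an estimate, which is why the flag exists.

## Structure-function analyses

Scanning mutagenesis designs (all-adenosine 3-nt windows in 1-nt steps;
base-pair-ablating A<->C / G<->T transversions in 4-nt windows, 3-nt steps
- both widths and steps are parameters, since published descriptions of
such designs vary) map variant-versus-wildtype A-cap fold changes to each
window's center nucleotide, `floor((start+end)/2)`. Helix validation uses
L/R/C mutants (left strand, right strand, or both complemented in place,
without reversal); the compensatory variant restores pairing with altered
sequence. `helixRescue()` reports `rescue_index = te_C / sqrt(te_L te_R)`
and a restoration fraction that places log2 te_C on the scale from the
mean disrupted level (0) to wildtype (1), clipped to [0, 1.5] - the paper
equivalent offers no formula, so the geometric-mean baseline is this
package's choice, symmetric in L and R and exact in the two boundary
cases.

Strong-pair analysis counts G-C pairs (either order) as a percentage of
all base pairs, pseudoknot pairs included; G-U wobbles count only in the
denominator. Structures are inputs (three-line dot-bracket with
bracket-class pseudoknot notation, or CT tables); structure prediction is
out of scope. Group comparisons between active and inactive IRESes use a
one-sided exact rank-sum test (active > inactive), chosen for validity at
the small group sizes typical of IRES subtype comparisons; ties fall back
to the normal approximation, and the output records the test used.

## Known limitations

- TE values are relative to the pool composition; absolute enrichment
  requires external anchoring (the spike-in machinery provides it across
  conditions, not within one).
- The assignment matcher is substitution-only; indel-containing reads are
  lost rather than rescued (the conservative direction for IRES calls).
- The spike-in factor transfers G-cap-derived normalization to A-cap
  reporters by assumption.
- Unmerged pairs are assigned on the observed 5' prefix only; variants
  distinguishable only near the UTR 3' end are excluded as ambiguous
  rather than resolved.
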