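---
title: "Detecting single position polymorphisms on short-probe tiling arrays"
author: "tilespp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting single position polymorphisms on short-probe tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilespp)
```

## The problem

Genotyping arrays that tile transcript (unigene) sequences with
overlapping short oligos — 25 nt probes stepped every 2 bp, up to 13
probes interrogating each base — detect sequence polymorphisms as
coherent hybridization differences: a mismatch under a probe reduces that
probe's signal in the lines carrying the variant allele. Because many
probes overlap every base, evidence can be integrated per base position,
and a polymorphism appears as a short run of positions at which the panel
of lines splits into a high-hybridization and a low-hybridization mode.
Such a call is a *single position polymorphism* (SPP): the array analog
of a SNP or small indel, localized to a few bases rather than a
nucleotide. `tilespp` implements the whole chain from raw probe
intensities to a filtered marker-by-line call matrix, the validation of
that matrix against sequence-derived truth variants, and the germplasm
diversity statistics and population-analysis exports computed from it.

## Normalization model

Hybridization levels are adjusted per chip before any comparison across
chips:

1. **Background correction.** Each array carries anti-genomic (AG)
   control probes matching no known sequence. The chip's median AG
   intensity is subtracted from every probe and the result floored at 1.0
   (linear scale). The floor keeps downstream ratios defined; the median
   is robust to the AG tail.
2. **Quantile normalization across all chips** (via
   `limma::normalizeQuantiles`, ties averaged), forcing every chip onto
   the common mean-of-order-statistics distribution. AG probes take part:
   they must remain comparable after normalization because thresholds are
   derived from them.
3. **Background thresholds.** A probe is *informative* on a chip when it
   exceeds the 90th percentile (linearly interpolated order statistic) of
   that chip's AG probes. The percentile is a parameter of
   `background_threshold()`.

Replicate quality is checked before calling: chips are clustered
(Euclidean distance, average linkage) on a probe subset covering known
polymorphisms, and a line passes only when its replicate chips form an
exclusive clade (`replicate_concordance()`, tree returned as Newick).

All intensities stay on the linear scale internally; log transforms are
for display only.

## The caller

**Position signals.** For each unigene base position and chip, the signal
is the weighted mean of the informative probes overlapping the position,
with the weight of a probe determined by the distance `d` of the position
from the probe center: `w(d) = 1 - (|d| / ((L+1)/2))^2`, a symmetric
quadratic falloff that is 1 at the center and near 0 at the probe ends
(bases near the center of a 25-mer are the most sensitive to
polymorphisms). Users holding an empirically calibrated sensitivity curve
can substitute any function of the same signature (`weight_fun`).

A position/chip signal is only defined when enough overlapping probes are
informative. By construction, a pure-background probe exceeds a
90th-percentile threshold 10% of the time, so accepting a single
informative probe would make a background-level chip look informative at
most positions (with 13 overlapping probes, 75% of the time). The default
minimum is therefore derived from the array itself: the smallest count
that keeps that chance under 5%, `qbinom(0.95, redundancy,
1 - percentile) + 1`, which is 4 at 13-fold redundancy. This is a
statistical floor, not a tuning constant, and it is a visible parameter
(`min_informative` in `position_signals()`).

**Mode fitting.** At each position the across-chip signals are split into
two modes by the exact optimal one-dimensional two-cluster partition:
signals are sorted and every contiguous cut is scored by total
within-cluster sum of squares. The optimum of the unrestricted two-cluster
problem is always a contiguous cut of the sorted values, so this is exact
and, unlike iterative k-means, deterministic and seedless. Ties in the
criterion break toward the larger gap between adjacent sorted values,
then toward the more balanced partition. The **SPPdev ratio** — the
separation statistic thresholded at 1.2/1.5/2.0 in the standard parameter
profiles — is the high-mode mean divided by the low-mode mean, i.e. a
linear-scale fold change. Positions with fewer than four defined signals
are not evaluable.

**Chip calls and replicate summarization.** Chips in the high mode are
called `A` (A is *always* the high-hybridization allele), low-mode chips
`B`, and chips whose signal falls within 10% of the inter-mode gap of the
midpoint are left uncalled (`-`; the margin is `nocall_margin`). The
three replicate chips of a line then collapse to one symbol: unanimous
A/A/A is `A`, B/B/B is `B`; B/B/- is `C` ("not A") and A/A/- is `D`
("not B"); -/-/- stays `-`; any A-vs-B conflict, or a single call with
two missing, is inconsistent, `I`. Other replicate counts generalize by
the same logic (unanimous, majority-with-missing, conflict-or-short).

**Run assembly.** Adjacent evaluable positions merge into one SPP marker
while their chip partitions agree. Agreement is checked against the
*run's established partition* — each chip's first non-missing call within
the run — not merely the previous position: with only pairwise-adjacent
comparison, a run can drift across the transition between two different
underlying polymorphisms through a band of no-calls, blending their
partitions. A marker's range is the run's extremes (1-based, inclusive);
its SPPdev ratio the maximum over member positions; its informative-probe
count the number of distinct probes overlapping the range that are above
background on at least half the chips; its per-line calls the replicate
summarization of each chip's majority call across the run. Markers must
meet `min_ratio`, `min_informative` and `min_span` to be emitted.

## Filtering

`apply_filters()` reproduces the standard dataset-shaping chain, in the
order used for diversity work: detection stringency (ratio, informative
probes, span), removal of markers in multi-copy sequence, C/D conversion
to B/A, then allele-count, missing-call and inconsistent-call limits.
Each step's removals are logged (`write_filter_log()`). Three presets are
shipped (`preset_params()`): the diversity profile (ratio 1.2, 2
informative probes, 4 bases, both alleles present, zero `I`, zero `-`,
multi-copy dropped), a low-FDR profile (the same at ratio 1.5) and a
line-specific discovery profile (ratio 1.5, span 2, missing tolerated).

**Multi-copy flagging.** Calls inside sequence that is duplicated
elsewhere in the transcriptome can reflect paralog cross-hybridization
rather than allelic variation. For each marker, the unigene subsequence
from 8 bases before its start to 8 after its end is searched, ungapped
and on both strands, against all unigene (and optionally external)
sequences; a hit qualifies at ≥95% query coverage with ≤2 substitutions,
and a marker is flagged when any qualifying hit exists besides the
perfect self-match at its own coordinates. The 95% is interpreted as
*query* coverage (for short flank queries this is the direction that
makes biological sense); the search is substitution-only, matching the
two-mismatch criterion — indel-tolerant alignment is out of scope. Note a
structural property of the rule: it can only fire when the duplicated
sequence extends at least the flank width beyond the marker's range, so
markers produced by a duplication whose hybridization footprint and
sequence identity end together are not flaggable. This is visible in the
deletion/paralog scenario below.

## Validation

Against a table of sequence-derived truth variants (SNPs, heterozygous
positions, indels, deletion ranges), a marker is a true positive when any
variant lies within 8 bases of its range (inclusive; the window absorbs
the positional blur of overlapping 25-mers). Markers whose windowed range
has no truth-sequence coverage are excluded as unverifiable; the false
discovery rate is FP/(TP+FP) over the rest. Heterozygous truth positions
count as variants — they perturb hybridization even if the caller is
biallelic. Coverage can be given per base (interval mask) or per unigene.

Concordance with an independent genotyping assay maps each marker's assay
alleles onto the A/B orientation by majority agreement; markers whose two
orientations tie are reported as ambiguous and excluded rather than
silently absorbed. Overall concordance uses every pair where both assays
called (C/D converted); the unambiguous rate restricts to strict A/B
calls on the array side.

## Diversity layer

All statistics are computed on the filtered call matrix, counting `A`/`D`
as the A-like allele and `B`/`C` as B-like, over non-missing,
non-inconsistent calls in the requested line subset:

- allele frequencies and minor-allele frequency (ties at 0.5 reported
  with A arbitrarily minor);
- per-line unique (line-specific) allele counts;
- polymorphism-within-group Venn counts over named groups, after an
  overall minor-allele-count threshold;
- two-group MAF contingency matrices;
- informative markers (MAF strictly above 0.25 in every group);
- gene diversity `H_e = 1 - sum(p_i^2)` per marker, with the panel value
  an unweighted mean over the supplied marker set — monomorphic markers
  contribute 0, which is what makes `H_e` comparable between groups over
  a common marker set;
- unigene haplotypes: the distinct ordered tuples of a line's alleles
  across a unigene's markers, with frequency = carriers / lines with
  complete profiles (so frequencies sum to 1 per unigene even when some
  lines are excluded for missing calls), and the line-by-unigene
  haplotype-frequency matrix used as input for principal component
  analysis;
- monomorphic region scans along a genetic map: maximal runs of
  consecutive mapped markers monomorphic within a line subset, reported
  with their cM extent (max − min of member positions; runs need at
  least 2 markers by default).

Two writers feed external population-genetics software. The Structure
writer keeps mapped markers, thins each genetic bin to one representative
per distinct allele profile (completely linked markers add nothing to the
linkage model), and writes a marker row, an inter-marker cM distance row
(−1 opens each linkage group) and one haploid row per line (A-like 1,
B-like 0, missing −9); the panel is inbred lines, so haploid rows are the
default and diploid duplication is a flag. The PHYLIP writer recodes
polymorphic markers among the included lines as restriction-site
characters (A→1, B→0, other→?), thins per-unigene duplicate profiles,
pads taxon names to the 10-character field and errors on truncation
collisions. Running Structure/PHYLIP themselves is out of scope; only
their inputs are produced.

## The simulator

`simulate_panel()` generates the full study design: a panel of inbred
lines (default 20) hybridized in triplicate to an array tiling 100
unigenes (about 400 bases each) at 2 bp with 25 nt probes, plus
anti-genomic controls. The expected intensity of a tiling probe on a
line's chip is

```
affinity(probe) * attenuation(planted SNPs) * deletion factor
  + cross-hybridization from duplicated segments + background,
```

all times multiplicative lognormal chip noise. The components and the
reasoning behind their defaults:

- **Probe affinity** is a G/C-content curve (best performance at
  intermediate G/C) times a lognormal field that is *spatially smoothed*
  along each unigene — probes stepped 2 bp share 23 of their 25 bases, so
  neighboring probes must have correlated affinities — times a
  "poor hybridizer" factor applied in runs around splice-junction points
  (transcript-derived probes that mismatch genomic DNA). The spread and
  junction density are calibrated so that about 76% of tiling probes sit
  above background, the fraction reported for real genomic hybridizations
  of this array class; this choice was fixed against that single marginal
  statistic, not against any acceptance outcome.
- **Mismatch attenuation** shares the positional family of
  `probe_weight()`: a variant at the probe center leaves
  `attenuation_center` (default 0.3) of the signal, one at the edge
  leaves almost all of it. Detection and generation use the same family
  by default but are independently configurable, so model misspecification
  can be tested.
- **SNP sites** are Poisson per unigene (mean 1.5); each line carries the
  alternate allele with probability 0.3. Within a unigene, successive
  SNPs reuse one primary line bipartition with probability 0.8 — inbred
  germplasm has strong within-gene linkage, so polymorphisms in one
  transcript mostly sort the panel the same way.
- **Deletions** (5% of unigenes, 120 bases) silence the self term for
  probes inside the range, scaled `(1 - overlap/L)^2` for straddlers.
- **Paralog pairs** (5% of unigenes) copy a 120-base segment into another
  unigene with 0–2 substitutions; cross-hybridization onto either copy's
  probes tracks the *donor* copy's genotype, attenuated by the planted
  mismatches and by out-of-segment bases treated as mismatches.
- **Background** is lognormal (median 100, sdlog 0.3); anti-genomic
  probes draw from it directly. Chip noise is lognormal with sdlog 0.1.
  Replicates draw independent noise; batch effects are not modelled.

`write_fixture()` emits the probe TSV, manifest TSV, intensity TSV,
unigene FASTA and truth TSV, byte-stable for a fixed seed, with the
configuration (seed included) as YAML alongside.

**What passing tests do and do not show.** The simulator reproduces the
features the caller relies on — positional attenuation, replicate
structure, G/C-dependent and spatially correlated probe behavior, a
realistic below-background fraction, paralog cross-hybridization — but
not batch effects, spatial chip artifacts, heterozygous intermediate
signals (the panel is modelled fully inbred; real residual
heterozygosity around 3.5% lands in no-calls via the margin), or
thermodynamic duplex chemistry. Recovery and FDR measured on it
characterize the implementation under its own assumptions, not the error
rates to expect on real chips.

**High-contrast sites.** Recovery guarantees are stated for planted SNPs
that are (a) free of overlapping structural confounders — no planted
deletion or duplicated segment within probe reach (24 bases), no
neighboring SNP with a different carrier set within probe reach — and
(b) adequately probed: at four consecutive positions containing the SNP,
at least four overlapping probes are expected above background for
carriers and non-carriers alike, judged from the generator's realized
probe affinities. (b) matters because roughly a quarter of probes sit
below background by design: a SNP falling where the array cannot see
produces no hybridization contrast at any attenuation, and no caller
could recover it. `planted_snp_recovery()` labels every planted site so
the caller's behavior on confounded and unprobed sites remains
observable.

**The deletion/paralog scenario.** `simulate_deletion_paralog()` builds
the classic confounded locus: a gene with a 200-base 5' deletion
segregating in half the panel, and a paralog sharing the deleted region
at about 96% identity. Cross-hybridization is deliberately marginal
(2% of a perfect self-match for a mismatch-free probe): deletion carriers
then rise above background only at locally strong, locally mismatch-free
patches, which is what produces short, discrete markers *inside* the
deletion — separating carriers from non-carriers yet reading as local
polymorphisms — whose flank queries stay inside the duplicated sequence
and are therefore flaggable by the multi-copy rule. With uniformly strong
cross-hybridization the whole deletion merges into one long marker whose
flanks leave the duplicated region, and the 95%-coverage rule can never
fire; the marginal-patchy regime is also what real paralog-confounded
loci look like (discrete calls at pockets of high identity). The long
deletion-spanning marker, when it forms, is a *true* detection of the
deletion (the deletion is in the truth set) and is intentionally not
removed by the flank rule.

## Numerical and scale choices

Problem sizes were chosen so the full default pipeline (quantile
normalization of ~19,000 probes × 60 chips, ~40,000 position fits, run
assembly, flank search) runs in about a minute: 100 unigenes × 20 lines
in triplicate for end-to-end checks, 12 unigenes × 8 lines for unit
fixtures. The exhaustive mode-fit oracle is checked up to n = 12 chips
per position, where all 2^n − 2 binary splits remain enumerable. Degenerate
inputs are handled explicitly: positions with all signals equal report
ratio 1 (non-polymorphic); fewer than four defined signals make a
position non-evaluable; markers with no called line report NA
frequencies; an FDR over zero verifiable markers is reported as
undefined rather than 0.

## Known limitations

- Multi-allelic sites and copy-number estimation are out of scope; the
  caller is strictly biallelic with heterozygotes landing in `-`/`I`.
- The flank-based multi-copy rule cannot flag markers whose duplication
  ends with their hybridization footprint (see above); combining it with
  a unigene-level multiple-hit screen is advisable on real data.
- The exact statistic of the original SPPdev software is defined in prior
  literature that prints no equation; the fold-change reading used here
  is consistent with its published thresholds (1.2/1.5/2.0), and both the
  separation statistic's inputs and the probe weighting are configuration
  points for users holding the original curves.
- The Structure/PHYLIP writers produce inputs only; parameter choices for
  those programs (burn-in lengths, K selection, bootstrap counts) are the
  user's.
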