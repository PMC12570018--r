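---
title: "Models and methods behind icemethylome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icemethylome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`icemethylome` analyses bacterial and viral DNA methylation in
environmental metagenomes from per-nucleotide modified-base pileups. This
vignette documents the models, the statistical and numerical choices, the
synthetic-data generator that backs the test suite, and what the passing
tests do and do not establish about real data.

## Data model and coordinate conventions

Every parser converts to a single internal convention — 0-based,
half-open intervals, strand-specific positions — and every writer converts
back at the boundary. GFF3 (1-based inclusive) is converted on read and
write; BED and bedMethyl are already 0-based. A methylation record is one
strand-specific pileup row: contig, position of the modified base, strand,
modification type (5mC, 6mA or 4mC), valid coverage, modified-read count,
and their ratio. Records with zero coverage carry an undefined fraction
and never reach any aggregate. The read-level confidence filter applied by
upstream basecalling/pileup software is deliberately *not* re-applied: it
acts before bedMethyl exists, and re-filtering would double-count it.

Two bedMethyl dialects are accepted and detected by column count: the
18-column layout (9 BED fields plus the pileup extension; valid coverage
in column 10, modified count in column 12) and a minimal 11-column layout
(9 BED fields plus those two counts). Unknown modification codes are
skipped with a warning rather than failing, for forward compatibility
with new code tables; structurally malformed rows (bad column counts,
non-integer counts, modified > valid) are hard errors naming the line.

A motif is an IUPAC string plus the offset of the methylated base and its
modification type, printed as `G[6mA]NTC` — the bracketed modification
code stands on the methylated base. Scanning is strand-aware: the forward
strand is scanned with the motif and with its reverse complement, and
every match is a distinct instance because each strand has its own
methylated base and its own pileup row. Palindromes therefore yield
paired instances over one window, all overlapping occurrences are
reported, and an `N` in the *sequence* matches only the pattern code `N`
(ambiguous sequence never supports a concrete motif call). One subtlety
follows from these rules: GANTC is its own reverse complement under `N`,
so a single GACTC window yields both a `+` and a `-` instance — the
minus-strand methylated adenine sits in the GAGTC reading of the
complementary strand.

## Profiling and categorisation

Sites below 5× valid coverage are removed (boundary inclusive); the
threshold is the `min_cov` argument throughout. Per instance and sample
group, "normalised by coverage" is implemented as coverage-weighted
pooling: the group mean is Σ modified / Σ valid over the group's samples,
i.e. the maximum-likelihood estimate for a shared underlying fraction,
invariant to how reads are split across samples. The unweighted mean of
per-sample fractions was rejected because it up-weights shallow samples.
The group standard error is the SE of per-sample fractions (defined from
two samples up); it feeds the population-heterogeneity variant of the
differential test. Methylation categories are low < 0.33,
medium [0.33, 0.66] (both boundaries inclusive, configurable), high
> 0.66; the headline category of an instance comes from the pool of all
samples unless a reference group is named. An instance with no surviving
record in a group is reported as `no_data`, never dropped, and "has data"
for summary purposes is exactly "survived the coverage filter" — no
further sufficiency notion is introduced.

## De novo motif discovery

Discovery is enumeration-and-generalise, parameterised so its defaults
mirror the categorisation above (seed sites are "high": pooled fraction
at the `min_fraction = 0.66` default with pooled coverage ≥ 5):

1. ±5 bp contexts around every seed site, minus-strand contexts
   reverse-complemented so the methylated base sits at the fixed centre;
   contexts containing `N` are discarded.
2. Every sub-window of length k ≤ 6 containing the centre contributes
   concrete k-mer candidates, counted among contexts and against the
   contig's own empirical k-mer background on both strands (robust to
   GC/composition skew, unlike an i.i.d. model).
3. Each candidate is tested with an uncorrected 2×2 chi-squared
   (seed-context vs background, motif vs not) and BH-adjusted at
   α = 0.01. Only enrichment (not depletion) is reported.
4. Significant candidates are generalised: a Hamming-distance-1 sibling
   is merged when its support rate (seed count over background count)
   reaches `support_frac = 0.5` of the parent's, and the position is
   rewritten as the minimal covering IUPAC code. Ties are broken by seed
   count, then lexicographic order, making discovery deterministic and
   invariant under reverse-complementing the input.
5. Flanking positions that become `N` are trimmed; interior `N`s remain
   (GANTC). Bipartite Type I sites are supported only as explicit N-runs.
6. Generalised motifs are re-tested on pooled counts, BH-filtered,
   ranked by chi-squared, and accepted greedily; a motif whose seed-site
   set is contained in an already accepted motif's seed set is redundant.

The redundancy rule operates on *seed* sites, not genome-wide instances.
Over genome-wide instances a short sub-motif (GA) always matches a
superset of the true motif's instances and would displace it; ranking by
enrichment first and then testing seed-set containment keeps the most
specific motif that explains the methylated sites — GATC defeats GA
because its background is 16-fold smaller at equal seed support.

## Differential methylation

The contig-level comparison is a two-sample, two-sided Kolmogorov–Smirnov
test between the per-instance group means (or group SEs) of the two
sample groups, per contig × motif, with BH correction across all rows of
a run. The exact p-value is used when n·m ≤ 10 000 and no ties are
present, the asymptotic form otherwise. A contig × motif below
`min_instances = 10` paired instances is reported as
`insufficient_data`. Two significance flags are always reported: the
configured α (default 0.01) and the 0.05 level conventionally used for
contig-level significance calls — the two levels coexist in the source
conventions, so the discrepancy is surfaced rather than hidden.
Applying the KS test to per-instance group means (rather than
concatenated per-sample values) was an explicit choice: it tests the
biologically meaningful per-site distribution and avoids pseudo-replication
from correlated within-instance samples.

The instance-level test pools counts per group and compares the two
proportions (chi-squared without continuity correction; Fisher's exact
test whenever any expected cell is below 5). The effect is
`delta = fraction(bottom) − fraction(top)`: positive means more methylated
in the bottom group. Promoters are `[start − w, start)` upstream of
plus-strand start codons and `[end, end + w)` for minus-strand genes,
with `w = 60` bp by default and 70 bp supported for isolate-style
analyses.

### Operating characteristics

The acceptance suite calibrates the contig-level test on synthetic
profiles with ~100 instances, three samples per group and Poisson-30
coverage. Type-I error at α = 0.01 is controlled (0–1.5% across seeded
runs of 200 simulations). Power for a shift of 0.3 on 20% of instances
sits at the boundary of 90% at the 0.05 flag (87–94% across independent
200-simulation seed sets) and near 38% at α = 0.01: a 20% shifted subset
caps the KS statistic near d = 0.2, while the critical values at
n = m = 100 are 0.192 (5%) and 0.230 (1%). Detecting such a shift
reliably at α = 0.01 needs more instances, a larger shifted subset, or
the instance-level test, whose per-site power at these coverages is high
(end-to-end recovery of planted differential instances is 92–98% at
FDR 0.05 across seeded bundles).

## RM balance and the surplus statistic

Gene counts per system type treat combined restriction-and-modification
fusions as both an MTase and an REase; specificity subunits count as
"other"; Type IV systems cannot contribute MTases. An MTase is orphan
within its genome group (MAG/bin id when provided, else contig) iff no
same-type REase pairs with it, where pairing is a known, IUPAC-compatible
recognition motif in either orientation, or — when either motif is
unknown — co-location within `linkage_kb = 5` kb on the same contig (an
operon-scale distance). Combined fusions are never orphans. The surplus
statistic needed a declared null because none is standard: each of the
N = n_MTase + n_REase role-assignable genes is independently MTase or
REase with probability ½, giving z = (n_MTase − n_REase)/√N, two-sided
normal p, with a seeded permutation alternative exposed for small N. The
null calibration (|z| > 1.96 in ~5% of balanced assignments at N = 400)
is checked by the suite.

## Phage–host comparisons

Motif "frequency" is reported in both framings — occurrences per bp and
bp per occurrence — because both appear in practice; the displayed
spacing truncates toward zero (24 047/23 = 1045.5 prints as 1045) while
the exact value is kept in machine output. The host remainder is the
contig minus all prophage intervals, pooled. The density comparison
treats positions as trials in a 2×2 table; the exact conditional (Fisher)
test is the default because it is cheap at any region size and a plain or
Yates-corrected chi-squared deviates from the exact p by up to 0.04–0.11
precisely in the count regimes prophages produce. A
mononucleotide-composition-normalised observed/expected ratio
(`motif_obs_exp`) is available because raw density ratios between
regions of different base composition can mislead. Host matching scores
a phage's methylated-motif set against each host's RM recognition set by
weighted Jaccard; motifs match when one pattern aligns compatibly within
the other on either strand, which lets a short recognition core (ACAY)
match a bipartite site written with an explicit N-run (ACAYNNNNNRTT).
Information weighting (2 − log2 |degeneracy set| bits per position)
down-weights promiscuous motifs; ties rank by host id for determinism.

## GC skew and methylation trends

Skew is (G − C)/(G + C) in 10 kb windows stepped by 1 kb (windows without
G or C score 0); under the leading-strand G-excess convention the
replication origin sits at the cumulative minimum and the terminus at the
maximum, reported at window centres. The convention is stated explicitly
because only a tool name, not an orientation, is usually given. Note that
reverse-complementing a genome maps each extremum to its own reflected
coordinate — it does not exchange ori and ter, because the complement
flips strand and direction together. An AT-only (degenerate) input warns
and returns NA extrema. The methylation trend is an ordinary
least-squares polynomial (quartic by default) of fraction against
position, fitted per group on pooled instances; positions are rescaled to
[0, 1] internally because raw bp positions to the fourth power overflow
double precision conditioning, and coefficients are reported in both
parameterisations via exact binomial expansion. Degree-4 fits through
five points interpolate; noiseless planted quartics are recovered to
1e-8. Contig order within a MAG is taken as given.

## The synthetic-data generator

`sim_config()` defaults describe the emulated study conditions: two
groups ("top"/"bottom") of three replicate samples; Poisson coverage with
λ = 30; one planted Dam-like G[6mA]TC motif, methylated at Beta-mean 0.9
(concentration 50) at motif sites and 0.02 elsewhere; 20% of instances
truly differential with |δ| = 0.3; a prophage whose planted-motif density
is thinned to ρ = 0.5 of the host's by single-base substitutions at
non-methylated motif positions; uniformly placed non-overlapping genes;
a planted GC-skew origin (amplitude 0.03); and an RM table with a
controlled MTase surplus. True fractions are drawn independently per
instance and group (so null groups share a distribution, not values);
observed counts are Binomial given Poisson coverage — a Beta–Binomial
observation model whose concentration-50 overdispersion is comparable to
real pileups without extra parameters. The differential shift is applied
*downward* in the bottom group: from a 0.9 baseline, a +0.3 shift would
clip at 1.0 to an effective 0.1 and no longer be the stated effect size;
the negative sign realises the full magnitude, and the sign itself is
immaterial to every statistic tested. One master seed drives independent
per-purpose substreams (sequence, fractions, coverage, genes, RM table),
so changing one parameter perturbs only its own stream, and a
configuration is always either rejected up front or produces a
byte-identical bundle on re-run.

Problem sizes in the test suite are chosen to give each check its stated
statistical resolution at interactive runtimes: 50 kb contigs (~400
planted instances) for discovery replicates, 12.8 kb (~100 instances) for
KS calibration, 60 kb for depletion replicates, 1 Mb for origin
localisation, 100 kb for the end-to-end bundle.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: sequencing error and reference bias in
the modified-base calls themselves (records are generated, not
basecalled), strand-asymmetric or hemimethylation states, within-genome
composition heterogeneity beyond the planted skew, partial genome bins,
multi-species mixtures on one contig, and motif families beyond
fixed-length IUPAC patterns (variable-gap bipartite sites in
particular). Results on real pileups additionally inherit whatever
read-level confidence filtering produced them.

## Known limitations

* Discovery reports fixed-length IUPAC motifs up to k = 6 with N-runs
  only as explicit spacers; variable-gap bipartite motifs are out of
  scope.
* The KS comparison has limited power against small shifted
  subpopulations at α = 0.01 (see operating characteristics); the
  instance-level test is the sensitive tool at that scale.
* Orphan detection is conservative when gene coordinates are absent:
  unknown-motif pairs cannot be linked and the MTase is reported orphan
  with reason `no_linked_rease`.
* The surplus null treats genes as independent Bernoulli role
  assignments; operon structure violates independence, which the
  permutation variant does not repair (it shuffles the same labels).
* Printed spacing values use truncation to match display conventions;
  downstream arithmetic should use the exact `spacing_bp`.
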