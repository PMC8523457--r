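---
title: "Methods: sequence-based STR genotyping, QC and databasing statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based STR genotyping, QC and databasing statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strmps)
```

# Scope and data model

`strmps` analyses per-sample, per-locus *sequence-level* read counts from a
forensic STR sequencing panel (22 autosomal STRs plus amelogenin) together
with paired length-based (CE) genotypes. The central objects are:

- `StrCatalog` — locus definitions (repeat period 3–5 bases, canonical
  motif, the ordered counted/uncounted block template of the repeat region)
  and a catalogue of flanking/repeat variants with their net length
  changes. Amelogenin is carried as a non-STR panel member; the period and
  motif invariants apply to repeat loci only.
- `ReadProfileSet` — read counts keyed by (sample, locus, sequence),
  with a sequence annotation table (repeat units, partial bases, carried
  variants).
- `GenotypeCallSet` — thresholded calls; a homozygote is one allele record
  plus a marker, never a duplicated row, so allele counting is unambiguous
  (homozygotes count twice only in frequency math).

Raw read processing (FASTQ extraction, alignment, repeat-structure
parsing) is upstream of this package and out of scope; the read-count
table is the entry format.

# Allele calling

Thresholds are integer read counts, so all comparisons are exact:

- **Analytical threshold** (`at`, default 50): sequences with `reads >= at`
  are retained. The boundary is inclusive by design and documented, since
  "a threshold of 50 reads" does not by itself fix strictness.
- **Stutter separation**: a sequence one full repeat unit below a stronger
  same-locus sequence with a read ratio ≤ 0.35 is treated as a stutter
  artifact, not an allele candidate. The 0.35 ceiling is a standard
  forensic filter level: simulated stutter means stay below ~0.21 while
  heterozygote balance rarely drops that low, so the two populations are
  well separated. Adjacent-allele heterozygotes are protected because a
  true allele's ratio to its neighbour is governed by heterozygote
  balance, not stutter.
- **Interpretation thresholds** (`itHom` 500, `itHet` 100): two candidates
  ≥ `itHet` give a heterozygous call; one candidate ≥ `itHom` a homozygous
  call; one candidate in `[itHet, itHom)` is deliberately *not* forced
  homozygous but left uncalled with a `possible_dropout` flag — forcing a
  homozygote would silently convert allelic drop-out into a wrong genotype.
  More than two strong candidates raise a `triallelic` flag and no call.

Run-level QC classifies cluster density as under (< 1000 K/mm²), optimal
(1000–1200) or over (> 1200) and passes Q30 above 75%. Q30 summaries are
reported as mean and n−1 SD, rounded to one decimal; other percentages to
two decimals; printed-table style rounding is half-up (R's default
half-to-even would change printed values such as a 3.25-fold increase).

# Designation arithmetic

The repeat-count designation of a sequenced allele sums the unit counts of
its counted blocks; leftover counted bases (0 to period−1) form the partial
part, rendered `n.b` in the CE micro-variant convention (`9.3` is 9 units
plus 3 bases, never 9.3 units; designations are strings on disk, never
floats).

The CE-equivalent (pseudo-CE) designation converts the counted length
`L = units × period + partial` under the summed net length changes of
carried indels: `L' = L + Σ net`, designated `L' div period . L' mod
period`. SNPs (net 0) are the identity; a deletion exceeding the allele
length is an error. Two locus-specific conventions cannot be derived from
uniform arithmetic and are handled explicitly:

- **Penta D rs536566765** ([A/−], 3′ flank): the observed CE mapping of a
  14-repeat carrier is 13.3 although uniform arithmetic gives 13.4
  (14×5−1 = 69). The catalogue therefore supports a
  `ce_designation_override`, and the shipped entry records the observed
  mapping rather than guessing the sizing convention.
- **D19S433 rs147936416** ([TC/−] spanning a counted-unit/uncounted-block
  border): repeat counting yields `X.3` while CE sizing yields `X.2`, and
  published catalogues differ in how these micro-variants are aligned.
  The package reports the repeat-count and arithmetic CE designations side
  by side instead of imposing one convention; the carrier *rate* (the
  quantity the scenario checks) is unaffected.

Designation equality everywhere (concordance, isoallele detection) is
exact string equality after normalisation — CE sizing noise is out of
scope, and "longer/shorter" orders by (units, partial), not amplicon bases.

# Quality-control statistics

- **Relative marker performance**: per profile, each marker's share of
  total reads (amelogenin included); the equal-performance expectation for
  23 markers is 100/23 ≈ 4.35%. Markers are flagged when their mean share
  leaves the band grand mean ± one SD of the marker means.
- **Heterozygote balance** HB = minor/major reads ∈ (0, 1], symmetric and
  scale-free; calls with HB ≤ 0.30 are flagged imbalanced. Zero reads on
  either allele is drop-out territory and an explicit error, not HB 0.
- **Stutter** is analysed length-defined and univariate (n−1 full repeat,
  same partial), the deliberate reduction appropriate for single-source
  samples; sequence-defined multivariate stutter and n+1/n−2 artifacts are
  out of scope. Parents whose n−1 position coincides with the genotype's
  other allele are skipped — the "stutter" reads there are mostly allele
  reads and would inflate ratios. Ratios are summarised per locus and
  read-depth category (I: total ≤ 63,500 reads; II: ≥ 199,000; inclusive
  boundaries as printed in the defining table, whose caption is taken as
  normative over the running text). Single-observation groups report SD as
  missing; "stutter > 20%" counts strictly greater than 0.20.

# Concordance classification

CE designation multisets are compared with pseudo-CE multisets recalculated
from the calls (homozygous calls expanded to two copies). A locus is a
drop-out when exactly one CE allele is missing and nothing extra appears
(direction from the designation order), a drop-in when extra alleles appear
over a matching CE genotype, otherwise discordant; an empty MPS locus
against a typed CE locus counts as one discordant locus and two unmatched
alleles. Allele concordance is Σ matched alleles / (2 × loci compared);
locus concordance the fraction of fully concordant loci; both to two
decimals. The naive repeat-count designation is carried alongside, so
designation-method mismatches (e.g. a D2S441 deletion carrier: pseudo-CE
9.3 vs naive 10) are reported as would-be false exclusions against a
length-based database.

# Population genetics

Frequencies count complete genotypes only (incomplete ones are excluded
per locus with a warning), homozygotes as two copies. The expected
heterozygosity is the unbiased Nei estimator `(2N/(2N−1))(1 − Σ p²)`; the
matching probability sums squared *observed* genotype-class frequencies;
`PD = 1 − MP`; with `h = h_obs`, `H = 1 − h`: `PE = h²(1 − 2hH²)` and
`TPI = 1/(2H)` (infinite, flagged, when no homozygote was observed). These
are the standard forensic definitions; each is validated in the tests
against a brute-force oracle (pairwise chromosome draws for heterozygosity,
direct genotype-class counting for MP). Where a laboratory's in-house
formula variants differ, per-locus values would differ accordingly.

The exact Hardy-Weinberg test conditions on the allele counts: the p-value
is the total probability of genotype-count tables whose conditional
(Levene) probability does not exceed the observed table's. Full
enumeration is used while the (crudely bounded) table space stays below
`maxTables` (default 10⁷); above that a seeded Monte-Carlo permutation of
the allele vector is used (`nPerm` default 100,000 for a single locus;
cohort-scale wrappers default to 5,000 per locus, a size at which the
Monte-Carlo standard error ≈ 0.007 is negligible against the 0.05 decision
level). Monomorphic loci return p = 1 by convention. The permutation
p-value uses the (hits+1)/(n+1) convention so it is never exactly zero.

# The simulator: what it emulates, and what it does not

`generatePopulation` draws diploid genotypes independently per locus under
Hardy-Weinberg proportions from per-locus spectra; `simulateReads` turns
them into read tables: log-normal per-sample totals, fixed marker-weight
shares, Beta-distributed heterozygote balance applied as minor share
HB/(1+HB) with a fair (seeded) coin choosing the minor allele — HB is a
ratio, not a direction — and n−1 stutter whose mean ratio grows linearly
with repeat count, with Gaussian noise truncated at zero. Read counts are
rounded to integers (nearest, ties to even) so thresholding is exact; a
configured mean stutter ratio ≥ 1 is rejected as a misconfiguration.
Injected drop-outs zero an allele's reads (and its stutter); drop-ins add
spurious sequences. All randomness flows from the single mandatory config
seed via fixed per-stage sub-seeds.

Defaults are declared assumptions, not inferences from data: unit ranges
per locus span the commonly observed allele ranges with triangular
frequency profiles; 13 loci split their modal length class into an
isometric pair; low-frequency carriers of the D2S441 flanking deletion and
the D19S433 intermediate-allele deletion are included; totals are
log-normal around 120k reads (sdlog 0.5, placing roughly 10% of samples in
category I and 16% in category II); HB is Beta(24, 4) (mean ≈ 0.86);
per-locus stutter means lie between 3% and 15% with slope 0.009 per repeat
unit, and intermediate-allele parents stutter at 0.7× the integer-allele
mean, encoding the qualitative integer-vs-intermediate ordering.
Consequences the tests verify: cohort mean stutter in the 10–15% band for
most loci, heterozygote balance means well above 0.70, full concordance in
the absence of injected events, and recovery of configured stutter means
within ±0.01 from ≥ 5,000 parent alleles.

The simulator does **not** model per-base sequencing error, PCR inhibition,
degradation, mixtures, primer-binding-site drop-out (the catalogued D5S818
primer SNP is carried as annotation, not simulated as CE imbalance), or
amplicon-length effects on marker shares. Passing tests therefore show the
*analysis* behaves correctly on data with the assumed structure; they are
not evidence about artefacts absent from that structure.

## Deterministic scenarios

Scenario builders freeze their own internal seeds so their aggregate counts
are exact and independent of the caller's seed:

- `concordance_247`: 247 samples × 22 loci with a tight read model (totals
  around 150k, sdlog 0.2; HB Beta(90, 10)) so every locus call clears the
  interpretation thresholds, and exactly two injected single-allele
  drop-outs (the longer D2S1338 allele of an 18/28 genotype, the shorter
  Penta E allele of an 8/11). 10,866/10,868 alleles and 5,432/5,434 loci
  concordant.
- `isoallele_1075`: 1,075 length-homozygous genotypes of which 181 are
  isometric heterozygotes, distributed over 13 loci.
- `hb_flags_5434`: 5,434 heterozygous calls with exactly seven HB ≤ 0.30
  (five at D2S1338, one each at D19S433 and D21S11).
- `d19_intermediate_494`: 494 D19S433 alleles, 55 carrying rs147936416.

# Problem sizes and determinism in the test suite

The suite uses cohorts of 8–250 samples for pipeline round-trips, 2,500
parent genotypes for stutter-ordering checks, 150 samples (≈ 6,600 parent
alleles) for stutter-mean recovery, 5,000–10,000 samples for single-locus
frequency/HWE convergence, and 20,000 permutations when comparing the
Monte-Carlo HWE route against full enumeration on 3–4 allele cases —
sizes at which the binomial/Monte-Carlo error bounds used in the
assertions are meaningful. All stochastic tests fix their seeds.

# Known limitations

- The counted-block templates shipped for the 22 loci are the simple
  canonical structures needed by the designation examples, not a full
  repeat-structure guide; compound-repeat subtleties beyond the shipped
  blocks are not modelled.
- No genome-coordinate liftover, no reverse-complement handling: catalogue
  coordinates are 0-based half-open on the catalogue's stated strand.
- SE33 (absent from the sequencing panel) and Y-STRs are out of scope, as
  are error-tolerant database search algorithms and population
  substructure (θ) corrections.
- The interface is the exported function set plus this document; file
  interchange is TSV (CSV accepted on read), UTF-8, Unix newlines, "."
  decimal separator regardless of locale.
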