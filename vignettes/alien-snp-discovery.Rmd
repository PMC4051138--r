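---
title: "Discovering alien chromosome-specific SNPs and mapping introgressions"
author: "aliensnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering alien chromosome-specific SNPs and mapping introgressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aliensnp)
```

## The problem

Bread wheat is an allohexaploid (AABBDD): every chromosome exists as a trio
of homoeologues that are similar but not identical in sequence. Breeding
programs move chromatin from wild relatives in the tertiary gene pool —
species such as *Aegilops geniculata* — into wheat as whole-chromosome
additions, substitutions or small translocated segments. Tracking that alien
chromatin in segregating material needs markers with a very specific
property: at the marker site, **all three wheat homoeologues must carry one
identical allele while the alien chromosome carries another**. A single
allele-specific assay (KASP-style: two allele-specific forward primers, one
common reverse primer) then distinguishes alien chromatin on any wheat
background, because the wheat allele is present three times regardless of
which homoeologue the primer lands on.

`aliensnp` implements the discovery pipeline for such markers from
short-read sequence of a flow-sorted alien chromosome arm, plus the
downstream interpretation of marker genotypes across panels of derived
lines. Because real inputs of this kind (a sorted-arm read set and three
homoeologous survey assemblies) are large and external, the package also
ships a first-class simulator that generates data with exactly the
structure the method assumes, together with a truth table, so every stage
is testable end to end.

## Pipeline model

The discovery chain is deliberately simple and transparent; every stage is
a pure function of its inputs and thresholds.

1. **Read QC.** Bases with phred ≤ 15 are trimmed from both read ends,
   working inwards until a base above the floor is met (interior
   low-quality bases are retained; base calls are never altered). Reads are
   then kept only if strictly longer than 30 bp with at least 80% of bases
   at phred ≥ 15. `N` bases count against the 80% rule regardless of their
   declared score — a conservative choice, since an `N` carries no allele
   information. The two thresholds are deliberately asymmetric at the
   boundary (trim at ≤ 15, count ≥ 15 as passing); both are exposed as
   parameters with these defaults.

2. **Mapping.** Reads are placed **ungapped, end to end**, on both strands
   of each homoeologous assembly independently, with at most 3 mismatches.
   A read is reported only when a *single* placement achieves the minimum
   mismatch count: ties are dropped as ambiguous rather than assigned
   arbitrarily, because a tied placement in a polyploid context usually
   means the read sits on paralogous or homoeologous repeat structure and
   any assignment would manufacture false variant support. (A
   `drop_ties = FALSE` mode reproduces classic report-one-best behaviour
   for comparison.) The built-in mapper seeds candidate placements by the
   pigeonhole principle — a read within a budget of *k* mismatches must
   contain one of *k*+1 exactly matching chunks — and verifies every
   candidate by full comparison, so its output is provably identical to
   exhaustive scanning; the test suite enforces this against an
   independent brute-force oracle. `N` counts as a mismatch against
   everything, including another `N`. Gapped or spliced alignment is out
   of scope; externally produced SAM can be imported instead, subject to
   the same mismatch budget.

3. **Variant calling.** Pileups pool both strands. At each column whose
   majority non-reference base has support, a haploid candidate call is
   emitted with a phred-scaled quality

   $$Q = -10\,\log_{10} P\!\left(X \ge k \;\middle|\; X \sim
   \mathrm{Binom}(n, \varepsilon)\right),$$

   where $n$ is the column depth, $k$ the alt-supporting read count and
   $\varepsilon = 10^{-\bar q_{alt}/10}$ the error rate implied by the mean
   phred score of the alt bases. This is an explicit, testable stand-in
   for the opaque quality score of a general-purpose caller: the
   conventional thresholds (depth ≥ 4, quality ≥ 50, both inclusive)
   retain their intent — a site is kept when seeing its alt support by
   chance under the error model is at most $10^{-5}$ — while the number
   itself is reproducible to machine precision from the stated formula.
   The tail is computed in log space and capped at phred 1000 to avoid
   taking the logarithm of an underflowed probability. Ties between alt
   bases are broken by higher quality sum, then lexicographically with an
   `ambiguous` flag. The sample is one sorted chromosome arm, hence
   haploid: a second allele above 20% of depth raises a `het` flag (e.g.
   residual heterozygosity in the donor accession or sorting
   contamination) but is never genotyped.

4. **Trio intersection and flank identity.** For every filtered call on
   the anchor homoeologue (the A-genome copy by convention), the 201-base
   window centered on the SNP is searched in the other two assemblies on
   both strands, requiring the 2×100 flanking bases to match **exactly**
   and the hit to be **unique** in each assembly. The center base is
   excluded from the identity requirement — it is the allele under test.
   Exact search is used rather than a seeded local aligner because the
   method's own criterion is 100% flank similarity: wherever a fuzzy
   aligner would matter, the site is rejected anyway, and exact search is
   fully deterministic. A site is emitted as alien-specific when the three
   homoeologues agree at the center, the alien allele differs, and — under
   the default, strictest reading — a concordant filtered call also exists
   at the corresponding position of the other two homoeologues
   (`require_calls_on_all = FALSE` relaxes this to reference bases only).
   Rejections carry per-step reason codes (`edge`, `flank_mismatch_B/D`,
   `multi_hit_B/D`, `trio_discordant`, `no_call_B/D`) so the relative
   stringency of each filter stays observable.

5. **Marker candidacy.** A specific site is promoted to an assay-ready
   candidate when no *other* filtered anchor variant lies within 100 bp on
   either side (nearby variation under a primer footprint destabilises
   allele-specific PCR), and, when a de-novo alien assembly is supplied,
   when the anchor window with the alien allele substituted at the center
   has a unique exact match in the alien contigs — evidence that primers
   designed on wheat flanks will also bind the alien template. Without
   contigs this second check is recorded as untested rather than silently
   passed. Markers are named `gsnp_<arm><serial>` in anchor-coordinate
   order.

6. **Introgression mapping.** Genotypes of the resulting markers across a
   line panel are interpreted with the heterozygous-pattern logic: in a
   line carrying both wheat chromosomes and alien chromatin, an
   alien-specific marker co-detects both alleles. `HET` and `ALIEN_HOM`
   are therefore both treated as alien-positive for segment calling —
   substitution lines lack one wheat homoeologue, so allele dosage (and
   hence the called state) varies while the biology is the same. Per line,
   the alien fraction over non-missing markers classifies the line:
   `NO_ALIEN` at 0, `WHOLE_ARM` at ≥ 0.9, `PARTIAL` in between,
   `UNCALLED` when nothing was called. The 0.9 default separates the
   empirically observed regimes — whole-arm addition/substitution lines
   genotype heterozygous at ~94–97% of validated markers (assay dropout
   keeps this below 100%), while terminal translocations sit at ~8–25% —
   with a wide margin on both sides. Segments are maximal runs of
   alien-positive calls in marker order; `noise_tolerance` interior
   non-alien calls may be absorbed per run (default 0). Missing calls
   neither break nor extend runs. Segment intervals are reported half-open
   from the first marker of the run to the next marker after it, because
   the physical breakpoint between two markers is unobservable; this makes
   breakpoint error naturally countable in marker intervals.

## The simulator

`sim_config()` / `evolve_trio()` / `generate_reads()` emulate the study
design the pipeline targets: a common ancestral sequence evolves by
substitutions into three wheat homoeologues (default branch divergence
0.01/site each) and a more diverged alien arm (0.02/site), and the alien
arm is sequenced single-end (100 bp, 30×, per-base error 0.001). Three
classes of sites are planted with protected 100-bp neighbourhoods:
`alien_specific` (the marker pattern, clean flanks),
`homoeologue_discordant` (the trio disagrees — must never be emitted) and
`flank_contaminated` (marker pattern plus a second alien variant within
100 bp — must never be promoted). Planted sites sit at least one flank
width from sequence ends and more than two flank widths apart. The truth
table records *every* position at which the four sequences differ, with
background substitutions labelled `background`; a direct per-site rescan
of the emitted sequences reproduces it exactly, which is the simulator's
own round-trip test.

Defaults are the package's reference study conditions (200-kb arm,
150/50/30 planted sites) and are used unchanged by the acceptance checks.

Choices worth knowing:

* **Substitution-only evolution.** No indels in this version, so all four
  sequences stay colinear and truth positions are exact on every
  reference. The detection code never relies on this — flank
  correspondence is established by search, not by shared coordinates — but
  it makes oracles exact. Real survey assemblies of course contain indels
  and fragmented contigs; the flank-identity step handles those by
  construction (a flank interrupted by an indel simply fails the 100%
  rule).
* **Coverage bias.** Sorted-arm DNA is whole-genome amplified before
  sequencing, which biases coverage. This is modelled as a per-1-kb
  lognormal multiplier on expected read counts, log-sd 0.3 by default — a
  moderate, heavy-tailed choice; the exact shape of amplification bias is
  not critical here, only that coverage is non-uniform. Window counts are
  `floor(lambda) + Bernoulli(frac(lambda))`, so expectations are exact and
  the bias-free integer-coverage limit is deterministic.
* **Quality strings.** Two-tier: ordinary bases get the phred score
  consistent with the configured error rate (30 at error rate 0.001,
  capped at 40), and a configurable fraction of reads receives an
  appended low-quality (phred 2) tail, plus optionally a fraction of
  entirely low-quality reads, to exercise the trimming and filtering
  rules.
* **Seeds.** The genome uses `seed`, the read generator `seed + 1`; every
  output is a deterministic function of the one configured seed.

What the simulator does **not** model — and hence what passing tests do
not demonstrate about real data: repeat families and paralogy (real wheat
arms are repeat-rich, so real mapping rates are far lower and the
unique-placement filter works much harder), indels and assembly
fragmentation, chromosome-sorting contamination by wheat fragments, and
within-accession heterozygosity of the alien donor. The package's
validation shows the *logic* is sound and complete under its stated model;
real-data funnels will be dominated by effects the simulator excludes.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally, converted only
  at the VCF (1-based POS), marker-sheet (1-based assay coordinates) and
  BED (0-based half-open) boundaries.
* Flank windows truncated by a contig end are rejected with reason
  `edge`; windows containing non-ACGT bases with `ambiguous_base`.
* SNP density is reported per kb of **covered** bases (positions with
  depth ≥ 1) — the closest well-defined analogue of "analyzed sequence" —
  with a switch to full reference length.
* An empty candidate set exports a header-only marker sheet; duplicate
  marker ids are a hard error.
* The 201-base alien-contig query has odd length, so it can never be its
  own reverse complement and the two strand searches cannot double-count
  a single occurrence.

## Validation scale

The shipped tests validate the full pipeline at the reference conditions
(200-kb trio, ~60,000 reads, three references) plus a matched error-free
run, mapper-vs-oracle panels of 20 × 1,000 reads on ≤ 5-kb references,
10,000-read QC oracle comparisons and 100-column quality-score checks;
these sizes keep the whole suite under a minute on one core while every
rate they estimate (recall, precision, agreement) is computed from
hundreds to tens of thousands of independent decisions.
`scripts/acceptance.R` re-runs the same measurements from scratch at a
caller-chosen seed.

## Limitations

Ungapped mapping and substitution-only calling mean indel-proximal sites
are invisible; the mapper treats each reference independently (no joint
homoeologue-aware placement); KASP chemistry, primer thermodynamics and
fluorescence cluster calling are out of scope (genotype calls are input);
and the classifier's `whole_arm_min` presumes reasonably complete marker
panels — very sparse panels shift the alien fraction's granularity and
deserve a tuned threshold.
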