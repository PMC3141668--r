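---
title: "Cross-platform SNP validation with snpXval: models and methods"
author: "snpXval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform SNP validation with snpXval: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpXval)
```

# The problem

Low-coverage resequencing of a handful of individuals is a cheap way to
discover single-nucleotide polymorphisms genome-wide, but any single
dataset at 3-8X coverage produces potential-SNP lists dominated by
caller-specific artifacts, chemistry-specific error modes and
assembly problems. snpXval implements a validation methodology built on
one idea: *an identical heterozygous allele pair observed at the
identical position in two independent datasets is very unlikely to be an
artifact*, because independent chemistries (and independent animals) do
not share error modes. "Independent" means a different sequencing
chemistry on the same individual, or a different individual with any
chemistry.

Two complementary engines implement the idea:

* **Positional-allele comparison** intersects per-dataset heterozygote
  call lists by chromosome, basepair and unordered allele pair. It
  inherits the (deliberately permissive) stringency of the upstream
  caller, handles clustered SNPs, but is limited to positions both
  callers dared to call.
* **E-genotyping** starts from an *a priori* list of potential SNPs and
  interrogates the raw reads of another dataset directly: for each SNP,
  one 31 bp probe per allele (15 bp reference flanks around the variant
  base) is matched *exactly* against every read; a result is positive
  when every allele of the pair collects at least one exact-match read.
  Exact matching confers high specificity at the price of effective
  coverage and blindness to clustered variants.

# Calling model

The internal heterozygote caller is a deliberately minimal pileup
thresholder. It stands in for the chemistry-specific callers a real
study would use upstream; reproducing any particular caller's scoring
model is out of scope. Simulated reads carry their true placements, so
no aligner is involved anywhere — alignment is orthogonal to the
validation logic this package is about.

A position is called heterozygous when at least two alleles each carry
at least `minVariantReads` reads whose base quality is at least
`minPhred`. Tunables, with defaults chosen to favour sensitivity
(validation, not calling, provides specificity):

| parameter             | default | meaning |
|-----------------------|---------|---------|
| `minPhred`            | 20      | per-base Phred floor (~1% error) applied at the pileup |
| `minVariantReads`     | 2       | reads required per variant allele |
| `maxAlleleReads`      | 200     | any allele above this suppresses the site (presumed collapsed repeat / mis-mapping) |
| `positiveMinReads`    | 1       | exact-match reads per allele for an e-genotyping positive |

The same `StringencyProfile` object parameterises validation: a pair
validates a SNP only if both datasets show every allele of the pair
with at least one read at `minPhred` or better, and no allele above
`maxAlleleReads`. `highStringency()` (Phred 30, 4 reads) exists for the
low- versus high-stringency contrast; the quality floor is applied
per-base at the SNP position, not per-read average (the base actually
supporting the call is what matters).

Quality thresholds act per base, which is why the `Pileup` class stores
raw (position, base, Phred) observations and materialises columns at
any cutoff on demand: one pileup supports a whole stringency sweep.

# E-genotyping details

Several design points are genuinely open in a probe-matching engine;
the choices here, and why:

* **Strand.** Reads come from both strands, so base-space matching also
  accepts the reverse complement of a probe. In colour space the colour
  string of a reverse-complemented read is the reversed colour string
  (complementation preserves every di-base transition class), so the
  reversed colour probe is matched instead.
* **Colour space.** SOLiD reads encode di-base transitions (identical
  pair to 0; A/C and G/T to 1; A/G and C/T to 2; A/T and C/G to 3 —
  equivalently, XOR of 2-bit base codes). Colour reads are matched as
  colours against the probe's 30 internal transition colours rather
  than decoded first: a single colour read error corrupts all
  downstream bases of a naive decode but only one transition of a
  colour match. The primer-transition colour (first colour of every
  read) encodes the adapter junction, not genome, and is excluded.
* **Probe-site uniqueness.** Probes are screened by exact k-mer
  counting of the probe window — the two flanks with *any* centre base —
  against both strands of the reference; a site is usable only if that
  window occurs exactly once. Uniqueness is a property of where the
  window maps, not of the substituted centre base (an alternate-allele
  probe never occurs verbatim in the reference). Counting, not
  alignment, matches the engine's own exact-match semantics.
* **Counting unit.** A read counts at most once per probe even if the
  probe occurs twice within it: the evidence unit is a read, not an
  occurrence.
* **Known blind spots**, asserted as tests rather than patched: reads
  shorter than the probe (25 bp mate-pair reads vs 31 bp probes) can
  never match, and a second variant within 15 bp of the target breaks
  exact matching on the haplotypes carrying it, so clustered-SNP
  detection power drops. SNPs within 15 bp of contig ends or assembly
  gaps get no probe at all.

# Validation bookkeeping

All unordered dataset pairs are compared positionally
(`buildValidationMatrix`); potential SNPs left unvalidated are turned
into uniquely-mapping probes and scanned against every readset of a
different chemistry or animal (`runCrossValidation`); a dataset never
validates against its own reads. All per-pair validated sets are then
appended and deduplicated by chromosome/basepair (`mergeValidated`).
Allele conflicts between pairs are unioned and flagged `multiAllelic`
rather than discarded — a site may genuinely carry three alleles, or
one chemistry's reference call may be wrong; the VCF writer surfaces
sites whose validated alleles exclude the reference base with a
`REF_MISMATCH` filter flag instead of resolving the conflict silently.
A homozygous-alternate call never validates a heterozygote elsewhere:
the rule requires the *identical heterozygote* in both members of the
pair. Unvalidated calls are retained per dataset and exportable as BED.

# The simulator and what it does (not) emulate

`simulateStudy()` builds the conditions the package is evaluated under:
a 2 Mb single-contig genome at GC 0.42, three diploid individuals,
and per-individual read sets at the study coverages — Sanger 700 bp at
5.2X, SOLiD fragment 50 bp at 5X (colour space), SOLiD mate-pair
25 x 25 bp at 8X (colour space); a 454 preset (250 bp, 0.5X) exists but
is not part of the default study. Error rates (Sanger 1e-3, SOLiD 5e-3,
454 2e-3) are simulator defaults chosen as representative orders of
magnitude; no published per-chemistry error rates back them, and they
are configurable. Per-base Phred scores are drawn around the quality
equivalent of the error rate (SD 4, clamped to [2, 40]) and each base
errs with the probability its own quality implies, so qualities are
consistent with errors by construction and quality thresholds have
real work to do.

Two deliberate departures from a literal reading of the discovery
study:

* **Shared polymorphism.** Drawing each individual's heterozygous sites
  independently leaves essentially no position heterozygous in two
  animals at desk scale, which would make cross-animal validation and
  the "heterozygous in two of three animals" control group empty.
  `simulatePopulation()` therefore draws segregating sites once (site
  density calibrated so per-individual heterozygosity is 1.5e-3, the
  rate implied by ~4.3 million heterozygous positions in a ~2.9 Gb
  genome), assigns each a minor allele frequency uniform on
  [0.05, 0.5], and genotypes individuals under Hardy-Weinberg
  proportions. `simulateIndividual()` keeps the simple independent
  model for single-individual work.
* **Every animal gets every chemistry.** In the original design two of
  the three animals carried a single chemistry, so a heterozygote
  private to one of them is unconfirmable by construction. The
  simulated study applies the reference animal's multi-chemistry design
  to all three animals so that within-animal validation is available
  genome-wide; cross-animal routes remain active through the shared
  polymorphism.

The collapsed-duplication model generates reads from both the original
interval and a divergent copy (fixed divergence alleles shared by all
individuals), all placed on the single reference copy: local coverage
doubles and every individual appears heterozygous at every divergent
position — exactly the artifact signature the screens target. The copy
carries no individual polymorphism of its own, and reads from the copy
never extend past the interval (so coverage tapers within one read
length of its ends; the read-count is scaled so the interior sits at
the target coverage). No indels, no CNV dosage beyond this mechanism,
and no quality recalibration drift are modelled. Mate pairs are emitted
as two independent 25 bp reads at a fixed 1 kb insert; the pairing
itself is never used downstream, matching the role of mate-pair data
as extra coverage.

What passing the simulation-based checks shows, and what it does not:
the pipeline recovers hets that its own rules make recoverable, at the
modelled error rates, with false validation at the predicted
coincidence level — on reads with i.i.d. substitution errors, perfect
placements and no mapping ambiguity. Real data adds mis-mapping,
context-dependent errors and reference bias that only the
`maxAlleleReads` guard and the duplication screens partially address.

# Duplication screens

`coverageScreen()` compares read coverage of validated SNPs
heterozygous in *all* animals (the duplication-artifact risk group)
against an equal-size seeded random sample of SNPs heterozygous in
exactly two. It reports group means, histograms, and the fraction of
each group at or above `ceiling(2 * mean coverage)` — twice the
genome-wide average, the rounding that turns a 5.2X mean into a
threshold of 11 reads. A two-proportion test (`prop.test`) is attached
as a formal decision rule on top of the descriptive comparison;
enrichment is flagged at p < 0.01. The control sample is seeded for
reproducibility; with a single-contig simulated genome no
chromosome-stratification of the control draw is needed.

`scanUnplaced()` covers the other failure mode — duplicate copies
excluded from chromosome scaffolds into the unplaced bin: the unplaced
sequence is chunked into consecutive 150 bp pseudo-reads (short tail
kept; the concatenation reproduces the input) and scanned with probes
from all validated SNPs. Any hit marks a validated SNP with an
unrecognised near-identical copy. A probe occurrence straddling a chunk
boundary is invisible; the boundary-placement test asserts this
inherited property rather than hiding it.

# Annotation

Gene models (GFF3 via `rtracklayer`, or built directly with
`geneModel()`) classify each SNP per overlapping transcript as splice
site, non-synonymous, synonymous, 5'/3' UTR, intronic or intergenic.
Codons are derived from the CDS in transcription order with
strand-aware complementation; translation uses the standard genetic
code. Choices where the category scheme is underdetermined:

* Splice sites are the 2 intronic bases at each intron end (canonical
  donor/acceptor); the window is configurable since published
  splice-site counts cannot pin it down.
* A consolidated per-SNP category is taken by priority (splice_site >
  nonsynonymous > synonymous > utr5 > utr3 > intronic > intergenic),
  with a `placementVaries` flag whenever transcripts disagree — jointly
  these reproduce both a per-transcript view and an
  "additional transcripts" tally.
* Transcripts whose CDS length is not a multiple of 3 are incomplete
  models: coding placements there become `coding_unresolved` and stay
  out of the synonymous/non-synonymous tallies rather than guessing a
  frame.

# Evaluation statistics

`classifyConcordance()` buckets genotype calls against simulated truth
into good homozygote / good heterozygote / het-called-as-hom /
wrong-hom / erroneous-het; the miscall rate is the fraction in the
three error buckets, optionally recomputed inside coverage bounds
(default [3, 2 x mean]: very low coverage drops alleles, very high
coverage marks repeats). `validationEfficiency()` reports the validated
fraction of each dataset's calls, counting positions (consistent with
the position-keyed dedup rule). `densityByChromosome()` flags
chromosomes more than one standard deviation from the mean SNPs/Mb,
with an exclusion list for chromosomes with known ascertainment
problems (e.g. X with a male animal). `positionOverlap()` /
`overlapReport()` compute exact positional overlap between two SNP
sets, the overlap expected under uncorrelated placement
(|A| x |B-universe| / genome length) and the observed/expected
enrichment.

# Numerical and scale choices

Problem sizes are chosen so the whole suite exercises every path at
full fidelity while staying desk-sized: the standard simulated study is
a 2 Mb genome, three animals, nine read sets (~36 Mb of sequence), one
50 kb duplication at 1e-3 divergence and a 100 kb unplaced contig;
oracle-equivalence checks run at 200 reads x 50 probes and <= 50
pileup columns where brute force is exact and fast. Exact integer
counting is used throughout the engines; the only stochastic
quantities are simulation-derived rates, which are checked against
binomial/Poisson expectations at 3-5 SD tolerances. Ties in the caller
(equal read support) resolve in base order A < C < G < T,
deterministically. All generators are seed-parameterised; derived
sub-seeds are drawn once from the master seed so stages are
independently reproducible.

# Known limitations

* No aligner: placement-true simulation isolates validation logic but
  cannot exhibit mapping-error artifacts; `maxAlleleReads` and the
  duplication screens are the only mis-mapping proxies.
* The internal caller is a thresholder; caller-specific error modes
  (homopolymer indels, colour-space miscalls surviving two-colour
  checks) are not modelled, and indels are out of scope entirely.
* E-genotyping positivity ("one read per allele") is exactly as
  specified and is knowingly permissive; its specificity comes from
  31-mer exactness, quantified here only under the simulated error
  model.
* The high-stringency preset (Phred 30, 4 reads) applied to simulated
  SOLiD qualities (centred near Phred 23) leaves few or no calls; the
  low-vs-high contrast is therefore reported as call/validation counts,
  not as a ratio calibrated to any published figure.
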