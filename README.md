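# snpXval

Cross-platform SNP discovery and in-silico validation for low-coverage,
multi-chemistry resequencing studies.

## The problem

Resequencing a few individuals at 3–8X is an effective way to find
single-nucleotide polymorphisms genome-wide, but at that coverage every
individual dataset is riddled with caller- and chemistry-specific false
positives, and stringent filtering throws away real heterozygotes that
simply lack reads. snpXval implements a validation strategy that keeps
calling permissive and gets its specificity from *independence*: a SNP is
**validated** when the identical unordered allele pair is observed
heterozygous at the identical chromosome/basepair position in two
independent datasets — the same animal sequenced with two chemistries, or
two different animals. Independent technologies do not share error modes,
so agreement is strong evidence.

Two engines implement the comparison:

* **Positional-allele comparison** — intersection of per-dataset
  heterozygote call lists by (chromosome, position, unordered allele
  pair), with per-allele support requirements (each allele ≥ 1 read at
  Phred ≥ 20; any allele with > 200 reads disqualifies the site as a
  presumed collapsed repeat).
* **E-genotyping** — in-silico genotyping of an *a-priori* SNP list
  directly against the raw reads of another dataset: one 31 bp probe per
  allele (15 bp reference flanks around the variant base, screened for
  unique mapping), matched **exactly** against every read, in nucleotide
  space or in SOLiD di-base colour space; a result is positive when every
  allele of the pair collects at least one exact-match read.

Around the two engines the package provides: a pileup heterozygote caller
parameterised by stringency profiles; the pairwise validation matrix with
deduplicated merging and unvalidated-SNP retention; collapsed-duplication
artifact screens (coverage-distribution comparison of all-animals-het
SNPs, and probe scanning of unplaced assembly sequence split into 150 bp
pseudo-reads); genomic-context annotation (synonymous / non-synonymous /
splice site / UTR / intronic / intergenic, per transcript); evaluation
statistics (genotype concordance against simulated truth, validation
efficiency, SNP density per chromosome, cross-species positional
overlap); and a multi-chemistry diploid read simulator with known truth
that exercises the entire pipeline end-to-end.

It is aimed at genomicists building or evaluating SNP resources for
species with a draft reference and a handful of resequenced individuals.

## Worked example

Simulate two sequencing chemistries for one individual drawn from a
small population, call heterozygotes permissively in each, and
cross-validate:

```r
library(snpXval)
ref   <- simulateReference(1, 50000, seed = 1)
truth <- simulatePopulation(ref, 2, hetRate = 2e-3, seed = 2)
sanger <- simulateReads(ref, truth, chemistryPreset("sanger", coverage = 8),
                        individual = "ind1", seed = 3)
frag   <- simulateReads(ref, truth, chemistryPreset("solid_frag", coverage = 8),
                        individual = "ind1", seed = 4)
frag
#> ReadSet 'ind1_solid_frag' (animal=ind1, chemistry=solid_frag, color space): 8000 reads

dsS <- callHeterozygotes(pileupReads(sanger, ref), lowStringency(), ref,
                         animal = "ind1", chemistry = "sanger")
dsF <- callHeterozygotes(pileupReads(frag, ref), lowStringency(), ref,
                         animal = "ind1", chemistry = "solid_frag")
dsS
#> SnpDataset 'ind1_sanger' (animal=ind1, chemistry=sanger, caller=snpXval): 102 calls

buildValidationMatrix(list(dsS, dsF))
#> ValidationMatrix over 2 datasets (68 validated SNP-pair entries)
#>                 ind1_sanger ind1_solid_frag
#> ind1_sanger              NA              NA
#> ind1_solid_frag          68              NA

pipe <- runCrossValidation(list(dsS, dsF),
                           list(ind1_sanger = sanger, ind1_solid_frag = frag),
                           ref)
nrow(pipe$merged)
#> [1] 92
head(pipe$merged[, c("chrom", "pos", "alleles", "nPairs", "supportingPairs")], 3)
#>   chrom  pos alleles nPairs             supportingPairs
#> 1    c1  803     A/G      1 ind1_sanger|ind1_solid_frag
#> 2    c1 1871     A/G      1 ind1_sanger|ind1_solid_frag
#> 3    c1 2731     A/G      1 ind1_sanger|ind1_solid_frag
```

Reading the numbers: the Sanger and SOLiD-fragment datasets called 102
and ~120 potential heterozygotes each from ~100 true het sites; 68 sites
carried the identical allele pair in both lists and validated
positionally. The e-genotyping rescue stage then built 31 bp probes from
the calls left unvalidated in each dataset and matched them exactly
against the other chemistry's raw reads, lifting the merged validated set
to 92 sites — 75% of this individual's true heterozygotes, at 8X + 8X
coverage, with every validated site supported by two independent
technologies. `writeValidatedVcf(pipe$merged, ref, "validated.vcf")`
exports the merged set (sites whose validated alleles exclude the
reference base are flagged `REF_MISMATCH` rather than dropped), and
`pipe$unvalidated` retains the rest for future validation.

The methods vignette (`vignettes/snpXval-methods.Rmd`) describes the
calling and validation model, the colour-space code, the probe-uniqueness
rule, the duplication screens and the simulator's assumptions in detail.

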