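# The full simulated study used by the end-to-end acceptance checks: a
# 2 Mb genome, three individuals at per-bp heterozygosity 1.5e-3 sharing
# segregating sites, Sanger 5.2X / SOLiD fragment 5X / SOLiD mate-pair 8X
# read sets per individual, one injected 50 kb collapsed duplication at
# 1e-3 copy divergence, and a 100 kb unplaced contig. Built once and
# memoised: several acceptance properties are measured on the same run.

.studyCache <- new.env(parent = emptyenv())

acceptanceStudy <- function() {
  if (is.null(.studyCache$study)) {
    sim <- simulateStudy(genomeLength = 2e6, nAnimals = 3,
                         hetRate = 1.5e-3,
                         chemistries = c("sanger", "solid_frag",
                                         "solid_matepair"),
                         dupLength = 5e4, dupDivergence = 1e-3,
                         unplacedLength = 1e5, seed = 42L)
    .studyCache$sim <- sim
    .studyCache$study <- runStudy(sim)
  }
  list(sim = .studyCache$sim, study = .studyCache$study)
}
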