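# Shared fixture builders; everything is generated in code at test time.

# a genome with no sequence attached
toyGenome <- function(L = 100, circular = TRUE, name = "toy") {
  GenomeModel(name, length = L, circular = circular)
}

# n unique sites placed uniformly at random (without replacement)
makeUniformTis <- function(L = 500000, n = 50000, seed = 1,
                           genome = toyGenome(L)) {
  set.seed(seed)
  TisTable(genome, positions = sort(sample.int(L, n)) - 1)
}

# small default-shaped synthetic study, cheap enough for unit tests
smallSynthConfig <- function(seed = 1, ...) {
  synthConfig(genomeLength = 100000, nGenes = 80, meanGeneLength = 900,
              nInsertions = 10000, protectedRegionCount = 10,
              protectedRegionLength = 500, seed = seed, ...)
}

plantedEssentialIds <- function(truth) {
  g <- truthGenes(truth)
  g$gene_id[g$class %in% c("essential", "essential_with_dispensable_domain")]
}
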