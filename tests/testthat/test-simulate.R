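test_that("probe map lays a regular grid with the requested geometry", {
  cfg <- simulationConfig(seed = 3, nChromosomes = 2,
                          probesPerChromosome = 100,
                          probeSpacingBp = 10000)
  pm <- generateProbeMap(cfg)
  expect_length(pm, 200)
  last <- tapply(start(pm), as.character(seqnames(pm)), max)
  expect_true(all(last == 1e6))
  # strictly increasing within chromosome
  for (chr in unique(as.character(seqnames(pm)))) {
    expect_true(all(diff(start(pm[seqnames(pm) == chr])) > 0))
  }
})

test_that("generation is deterministic in the seed", {
  cfg <- simulationConfig(seed = 5, nCases = 10, nControls = 10,
                          probesPerChromosome = 200, nGenes = 4)
  expect_identical(generateProbeMap(cfg), generateProbeMap(cfg))
  pm <- generateProbeMap(cfg)
  a1 <- generateAnnotation(cfg, pm)
  a2 <- generateAnnotation(cfg, pm)
  expect_identical(a1$genes, a2$genes)
  c1 <- simulateCohort(cfg, pm, a1)
  c2 <- simulateCohort(cfg, pm, a1)
  expect_identical(lrr(c1$intensity), lrr(c2$intensity))
  expect_identical(c1$truth, c2$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(probeSpacingBp = 0), "positive")
  expect_error(simulationConfig(delFraction = 1), "delFraction")
  expect_error(simulationConfig(caseBurdenMultiplier = 0.9), "Multiplier")
  expect_error(simulationConfig(delShift = 0.5), "delShift")
  expect_error(
    simulationConfig(riskGenes = data.frame(gene = "g", case_freq = 0.5,
                                            control_freq = 0.001)),
    "mafCeiling")
})

test_that("gene boundary is the longest transcript", {
  tx <- data.frame(gene = c("g1", "g1"), chrom = "chr1",
                   start = c(1000, 1000), end = c(11000, 26000))
  gb <- geneBoundaryFromTranscripts(tx)
  expect_equal(gb$end, 26000)
  expect_equal(nrow(gb), 1)
})

test_that("zero genes yields an empty model and an all-intergenic pipeline", {
  cfg <- simulationConfig(seed = 9, nCases = 5, nControls = 5,
                          probesPerChromosome = 300, nGenes = 0,
                          backgroundCnvRate = 1)
  pm <- generateProbeMap(cfg)
  ann <- generateAnnotation(cfg, pm)
  expect_length(ann$genes, 0)
  co <- simulateCohort(cfg, pm, ann)
  calls <- makeCalls("chr1", 50000, 70000, "case_0001", "DEL")
  anno <- annotateCNVs(calls, ann$genes, ann$exons, samples = "case_0001")
  expect_false(any(mcols(cnvCalls(anno))$genic))
})

test_that("capacity and precondition errors fire", {
  cfg <- simulationConfig(seed = 2, probesPerChromosome = 50, nGenes = 40)
  expect_error(generateAnnotation(cfg, generateProbeMap(cfg)), "capacity")
})

test_that("risk SNPs inside risk genes list themselves as reflexive proxies", {
  cfg <- simulationConfig(seed = 4, nGenes = 6,
                          riskGenes = data.frame(gene = "GENE002",
                                                 case_freq = 0.02,
                                                 control_freq = 0.002))
  pm <- generateProbeMap(cfg)
  ann <- generateAnnotation(cfg, pm)
  lead <- ann$riskSnps$snp[ann$riskSnps$trait == "disease"][1]
  self <- ann$ldTable[ann$ldTable$lead == lead & ann$ldTable$proxy == lead, ]
  expect_equal(nrow(self), 1)
  expect_equal(self$r2, 1)
  # and the lead really sits inside the gene boundary
  g <- ann$genes[mcols(ann$genes)$gene_id == "GENE002"]
  snp <- ann$riskSnps[ann$riskSnps$snp == lead, ]
  expect_true(snp$pos >= start(g) && snp$pos <= end(g))
})

test_that("a null genome has no truth events and only noise-scale intensity", {
  cfg <- simulationConfig(seed = 6, nCases = 10, nControls = 10,
                          probesPerChromosome = 500, backgroundCnvRate = 0,
                          nGenes = 0, nWaves = 0)
  co <- simulateCohort(cfg, generateProbeMap(cfg), NULL)
  expect_length(co$truth, 0)
  expect_lt(mean(abs(lrr(co$intensity))), 3 * cfg@noiseSdMean)
})

test_that("a single wave with near-zero noise gives a rank-1 matrix", {
  cfg <- simulationConfig(seed = 8, nCases = 10, nControls = 10,
                          probesPerChromosome = 300, backgroundCnvRate = 0,
                          nGenes = 0, nWaves = 1, noiseSdMean = 1e-8,
                          noiseSdSpread = 0)
  co <- simulateCohort(cfg, generateProbeMap(cfg), NULL)
  sv <- svd(lrr(co$intensity))$d
  expect_gt(sv[1], 1e-3)
  expect_lt(sv[2] / sv[1], 1e-4)
})

test_that("embedded events shift the configured probes by the configured amount", {
  cfg <- simulationConfig(seed = 10, nCases = 15, nControls = 15,
                          probesPerChromosome = 600, backgroundCnvRate = 2,
                          nGenes = 0, nWaves = 0, noiseSdMean = 1e-6,
                          noiseSdSpread = 0)
  pm <- generateProbeMap(cfg)
  co <- simulateCohort(cfg, pm, NULL)
  expect_gt(length(co$truth), 0)
  m <- lrr(co$intensity)
  for (i in head(seq_along(co$truth), 20)) {
    ev <- co$truth[i]
    pr <- which(as.character(seqnames(pm)) ==
                  as.character(seqnames(ev)) &
                  start(pm) >= start(ev) & start(pm) <= end(ev))
    expect_equal(length(pr), mcols(ev)$n_probes)
    shift <- if (mcols(ev)$type == "DEL") cfg@delShift else cfg@dupShift
    expect_equal(mean(m[pr, mcols(ev)$sample]), shift, tolerance = 1e-3)
  }
})

test_that("realized risk-locus carrier frequency respects the rarity ceiling", {
  cfg <- simulationConfig(seed = 12, nCases = 100, nControls = 100,
                          probesPerChromosome = 600, backgroundCnvRate = 0,
                          nGenes = 8, mafCeiling = 0.03,
                          riskGenes = data.frame(gene = "GENE001",
                                                 case_freq = 0.03,
                                                 control_freq = 0.03))
  pm <- generateProbeMap(cfg)
  ann <- generateAnnotation(cfg, pm)
  co <- simulateCohort(cfg, pm, ann)
  carriers <- length(unique(mcols(co$truth)$sample))
  expect_lte(carriers, floor(0.03 * 200))
})

test_that("deletion BAF loses the heterozygous band", {
  cfg <- simulationConfig(seed = 14, nCases = 5, nControls = 5,
                          probesPerChromosome = 500, backgroundCnvRate = 3,
                          cnvProbeCountRange = c(10L, 20L), nGenes = 0)
  pm <- generateProbeMap(cfg)
  co <- simulateCohort(cfg, pm, NULL)
  dels <- co$truth[mcols(co$truth)$type == "DEL"]
  expect_gt(length(dels), 0)
  b <- baf(co$intensity)
  ev <- dels[which.max(mcols(dels)$n_probes)]
  pr <- which(as.character(seqnames(pm)) == as.character(seqnames(ev)) &
                start(pm) >= start(ev) & start(pm) <= end(ev))
  expect_false(any(b[pr, mcols(ev)$sample] > 0.2 &
                     b[pr, mcols(ev)$sample] < 0.8))
})

test_that("case/control event-rate ratio follows the burden multiplier", {
  cfg <- simulationConfig(seed = 16, nCases = 600, nControls = 600,
                          probesPerChromosome = 1500, backgroundCnvRate = 4,
                          caseBurdenMultiplier = 1.5, nGenes = 0, nWaves = 0)
  pm <- generateProbeMap(cfg)
  co <- simulateCohort(cfg, pm, NULL)
  s <- mcols(co$truth)$sample
  caseRate <- sum(grepl("^case", s)) / 600
  ctrlRate <- sum(grepl("^ctrl", s)) / 600
  expect_equal(caseRate / ctrlRate, 1.5, tolerance = 0.12)
})
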