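test_that("standardisation gives per-probe mean 0 and sample SD 1", {
  expect_equal(unname(standardizeLRR(matrix(c(1, 2, 3), 1))[1, ]),
               c(-1, 0, 1))
  expect_error(standardizeLRR(matrix(1, 3, 4)), "zero-variance")
  set.seed(31)
  z <- standardizeLRR(matrix(rnorm(50 * 20), 50, 20))
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-10)
})

test_that("segmentation recovers an interior shifted segment exactly", {
  set.seed(32)
  z <- rnorm(100, sd = 1e-3)
  z[40:60] <- z[40:60] - 4
  segs <- segmentSample(z)
  hit <- segs[segs$mean_z < -2, ]
  expect_equal(nrow(hit), 1)
  expect_lte(abs(hit$start - 40), 1)
  expect_lte(abs(hit$end - 60), 1)
  # oracle: exhaustive two-change-point least squares on the same track
  oracle <- bestInteriorSegment(z)
  expect_equal(c(hit$start, hit$end), oracle)
})

test_that("a constant track yields no spurious change-points", {
  segs <- segmentSample(rep(0.3, 500))
  expect_true(all(abs(segs$mean_z - 0.3) < 1e-12))
  # bounded lookback may partition a long flat track, but no segment can
  # cross a mean-z call threshold
  expect_equal(nrow(callCNVs(segs)), 0)
})

test_that("segments never span a chromosome boundary", {
  set.seed(33)
  z <- rnorm(200, sd = 0.1)
  z[95:105] <- z[95:105] - 5   # straddles the boundary at 100/101
  chrom <- rep(c("chr1", "chr2"), each = 100)
  segs <- segmentSample(z, chrom)
  expect_false(any(segs$start <= 100 & segs$end > 100))
  hits <- segs[segs$mean_z < -2.5, ]
  expect_equal(nrow(hits), 2)   # one truncated event per chromosome
})

test_that("call thresholds enforce the probe-count window and z cuts", {
  segs <- data.frame(start = c(1, 10, 300, 600),
                     end = c(2, 259, 319, 619),
                     n_probes = c(2L, 250L, 20L, 20L),
                     mean_z = c(-6, -6, -3.5, 2.4))
  calls <- callCNVs(segs, callingThresholds(delZ = -2.5, dupZ = 2.0))
  expect_equal(calls$n_probes, c(20L, 20L))
  expect_equal(calls$type, c("DEL", "DUP"))
})

test_that("region, sample-count and rarity filters follow the stated rules", {
  excl <- GRanges("chr1", IRanges(1, 10000))
  samples <- sprintf("s%03d", 1:100)
  # one call overlapping the telomere stand-in by exactly 1 bp
  calls <- makeCalls("chr1", c(10000, 20000), c(15000, 30000),
                     c("s001", "s002"), c("DEL", "DEL"))
  f <- applyRegionRarityFilters(calls, excl, samples)
  expect_equal(mcols(f$calls)$sample, "s002")

  # 49 calls kept, 50 calls excluded
  mk <- function(id, n) {
    makeCalls("chr2", seq(1, by = 20000, length.out = n),
              seq(10000, by = 20000, length.out = n),
              rep(id, n), rep("DEL", n))
  }
  f49 <- applyRegionRarityFilters(mk("s001", 49), GRanges(), samples)
  expect_length(f49$excludedSamples, 0)
  f50 <- applyRegionRarityFilters(mk("s001", 50), GRanges(), samples)
  expect_equal(f50$excludedSamples, "s001")
  expect_length(f50$calls, 0)

  # a locus carried by 4% of samples is dropped by the rarity filter
  common <- makeCalls("chr3", rep(50000, 4), rep(60000, 4),
                      sprintf("s%03d", 1:4), rep("DUP", 4))
  fr <- applyRegionRarityFilters(common, GRanges(), samples)
  expect_length(fr$calls, 0)
  rare <- common[1:2]
  fr2 <- applyRegionRarityFilters(rare, GRanges(), samples)
  expect_length(fr2$calls, 2)
})

test_that("locus grouping uses reciprocal overlap and type", {
  calls <- makeCalls("chr1",
                     c(1000, 1100, 9000, 1000),
                     c(2000, 2100, 9900, 2000),
                     c("s1", "s2", "s3", "s4"),
                     c("DEL", "DEL", "DEL", "DUP"))
  loci <- groupCallsIntoLoci(calls, 100)
  expect_length(loci, 3)  # two near-identical DELs merge; DUP separate
  expect_equal(sort(mcols(loci)$n_carriers), c(1, 1, 2))
})

test_that("unique CNV counting collapses identical intervals of one type", {
  calls <- makeCalls("chr1", c(100, 100, 100), c(200, 200, 200),
                     c("a", "b", "c"), c("DEL", "DEL", "DUP"))
  expect_equal(countUniqueCNVs(calls), 2)
  expect_equal(countUniqueCNVs(calls[0]), 0)
})

test_that("cohort calling recovers strong spiked events and stays quiet on
           null data", {
  # a cohort large and sparse enough that per-probe standardisation
  # reflects the noise scale (rare-CNV regime)
  cfg <- simulationConfig(seed = 41, nCases = 100, nControls = 100,
                          nChromosomes = 2, probesPerChromosome = 3000,
                          backgroundCnvRate = 2,
                          cnvProbeCountRange = c(10L, 20L), nGenes = 0)
  pm <- generateProbeMap(cfg)
  co <- simulateCohort(cfg, pm, NULL)
  qc <- runQC(co$intensity)
  kp <- probeRanges(co$intensity)[
    match(qc$keptProbes, mcols(probeRanges(co$intensity))$probe_id)]
  calls <- callCohortCNVs(qc$adjusted, kp)
  expect_gt(recoveryRate(co$truth, calls), 0.9)
  # per-sample intervals are disjoint across types (segmentation partitions)
  for (s in head(unique(mcols(calls)$sample), 10)) {
    cs <- calls[mcols(calls)$sample == s]
    if (length(cs) > 1) {
      hits <- findOverlaps(cs, cs)
      expect_true(all(S4Vectors::queryHits(hits) ==
                        S4Vectors::subjectHits(hits)))
    }
  }
  # every call's probe count equals the kept probes inside its interval
  for (i in head(seq_along(calls), 20)) {
    pr <- sum(as.character(seqnames(kp)) ==
                as.character(seqnames(calls[i])) &
                start(kp) >= start(calls[i]) & start(kp) <= end(calls[i]))
    expect_equal(mcols(calls[i])$n_probes, pr)
  }
})
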