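# Shared fixture builders; everything is generated in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# small cohort used by several modules; memoised per session
tinyCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(seed = 101, nCases = 40, nControls = 80,
                              nChromosomes = 2, probesPerChromosome = 800,
                              backgroundCnvRate = 2,
                              cnvProbeCountRange = c(5L, 15L), nGenes = 12)
      pm <- generateProbeMap(cfg)
      ann <- generateAnnotation(cfg, pm)
      co <- simulateCohort(cfg, pm, ann)
      cache <<- list(cfg = cfg, probes = pm, ann = ann, cohort = co)
    }
    cache
  }
})

# hand-built calls GRanges
makeCalls <- function(chrom, start, end, sample, type,
                      n_probes = rep(5L, length(start)),
                      mean_z = ifelse(type == "DEL", -4, 3)) {
  GRanges(chrom, IRanges(start, end), sample = sample, type = type,
          n_probes = n_probes, mean_z = mean_z)
}

# brute-force interval overlap scan used as annotation oracle
bruteAnnotate <- function(calls, genes, exons) {
  n <- length(calls)
  genic <- logical(n); exonic <- logical(n)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_along(genes)) {
      ov <- overlapBp(start(calls)[i], end(calls)[i],
                      start(genes)[j], end(genes)[j],
                      as.character(seqnames(calls))[i],
                      as.character(seqnames(genes))[j])
      if (ov >= 1) {
        genic[i] <- TRUE
        hits[[length(hits) + 1L]] <- data.frame(
          call = i, gene = mcols(genes)$gene_id[j])
      }
    }
    for (j in seq_along(exons)) {
      ov <- overlapBp(start(calls)[i], end(calls)[i],
                      start(exons)[j], end(exons)[j],
                      as.character(seqnames(calls))[i],
                      as.character(seqnames(exons))[j])
      if (ov >= 1) exonic[i] <- TRUE
    }
  }
  list(genic = genic, exonic = exonic & genic,
       hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(call = integer(), gene = character()))
}

# exhaustive two-change-point least-squares search (segmentation oracle)
bestInteriorSegment <- function(z) {
  n <- length(z)
  cs <- cumsum(c(0, z))
  segCost <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    -(s * s) / (j - i + 1)
  }
  best <- c(NA, NA); bestCost <- Inf
  for (i in 2:(n - 1)) {
    for (j in i:(n - 1)) {
      cost <- segCost(1, i - 1) + segCost(i, j) +
        (if (j < n) segCost(j + 1, n) else 0)
      if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
    }
  }
  best
}

# match calls against truth by sample, type and reciprocal overlap
recoveryRate <- function(truth, calls, minReciprocal = 0.5) {
  if (length(truth) == 0L) return(NA_real_)
  ov <- findOverlaps(truth, calls)
  q <- queryHits(ov); s <- subjectHits(ov)
  ok <- mcols(truth)$sample[q] == mcols(calls)$sample[s] &
    mcols(truth)$type[q] == mcols(calls)$type[s]
  w <- width(pintersect(truth[q], calls[s]))
  rec <- ok & w >= minReciprocal * width(truth)[q] &
    w >= minReciprocal * width(calls)[s]
  length(unique(q[rec])) / length(truth)
}
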