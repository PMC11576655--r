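# Synthetic SNP-array cohort generator: probe grid, gene model, and LRR/BAF
# matrices with embedded rare CNVs of known truth.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a synthetic-cohort configuration
#'
#' Constructor for \linkS4class{SimulationConfig}. Defaults emulate a large
#' case-control array study of rare germline CNVs: background rate 4.9 events
#' per control genome, a 1.22-fold case excess, 57% deletions, per-probe noise
#' SD around 0.1 LRR units with sample-to-sample spread, and smooth wave
#' artifacts removable by principal-component adjustment.
#'
#' @param seed integer master seed; identical configurations give
#'   byte-identical cohorts.
#' @param nCases,nControls arm sizes.
#' @param nChromosomes,probesPerChromosome,probeSpacingBp probe grid geometry.
#' @param noiseSdMean,noiseSdSpread per-sample noise SD distribution (LRR).
#' @param nWaves,waveAmplitude smooth artifact components and their loading SD.
#' @param backgroundCnvRate Poisson mean CNVs per control sample.
#' @param caseBurdenMultiplier case-to-control event-rate ratio (>= 1).
#' @param delFraction fraction of background events that are deletions.
#' @param cnvProbeCountRange c(min, max) probes per embedded event.
#' @param delShift,dupShift signed LRR shifts for one-copy loss/gain.
#' @param nGenes,exonsPerGene synthetic gene-model size.
#' @param riskGenes data.frame(gene, case_freq, control_freq[, type]).
#' @param mafCeiling rarity ceiling on realized locus carrier frequency.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1, nCases = 20, nControls = 20)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nCases = 200L, nControls = 400L,
                             nChromosomes = 2L, probesPerChromosome = 2000L,
                             probeSpacingBp = 5000L,
                             noiseSdMean = 0.10, noiseSdSpread = 0.02,
                             nWaves = 3L, waveAmplitude = 0.05,
                             backgroundCnvRate = 4.9,
                             caseBurdenMultiplier = 1.22,
                             delFraction = 0.566,
                             cnvProbeCountRange = c(3L, 20L),
                             delShift = -0.5, dupShift = 0.3,
                             nGenes = 40L, exonsPerGene = 3L,
                             riskGenes = data.frame(),
                             mafCeiling = 0.03) {
  new("SimulationConfig",
      seed = as.integer(seed),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      nChromosomes = as.integer(nChromosomes),
      probesPerChromosome = as.integer(probesPerChromosome),
      probeSpacingBp = as.integer(probeSpacingBp),
      noiseSdMean = noiseSdMean, noiseSdSpread = noiseSdSpread,
      nWaves = as.integer(nWaves), waveAmplitude = waveAmplitude,
      backgroundCnvRate = backgroundCnvRate,
      caseBurdenMultiplier = caseBurdenMultiplier,
      delFraction = delFraction,
      cnvProbeCountRange = as.integer(cnvProbeCountRange),
      delShift = delShift, dupShift = dupShift,
      nGenes = as.integer(nGenes), exonsPerGene = as.integer(exonsPerGene),
      riskGenes = as.data.frame(riskGenes), mafCeiling = mafCeiling)
}

#' Generate the synthetic probe map
#'
#' Lays probes on a regular grid of \code{probeSpacingBp} within each
#' chromosome and draws per-probe array metadata: a GenTrain-like clustering
#' score (mostly high, a small tail of poorly clustered probes), and a mean
#' hybridisation intensity (mostly near 1, a small dim tail), so the probe
#' quality filters have realistic substrate.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return GRanges of probes ordered by (chromosome, position) with mcols
#'   \code{probe_id}, \code{gentrain}, \code{mean_intensity}.
#' @examples
#' pm <- generateProbeMap(simulationConfig(seed = 1))
#' head(pm)
#' @export
generateProbeMap <- function(config) {
  validObject(config)
  if (config@probeSpacingBp <= 0L) stop("probe spacing must be positive")
  P <- config@probesPerChromosome
  chroms <- paste0("chr", seq_len(config@nChromosomes))
  .withSeed(config@seed * 1000L + 1L, {
    pos <- rep(seq_len(P), times = config@nChromosomes) * config@probeSpacingBp
    chr <- rep(chroms, each = P)
    n <- length(pos)
    gentrain <- pmin(1, pmax(0, 0.9 - rexp(n, rate = 25)))
    dim_tail <- runif(n) < 0.02
    mi <- rnorm(n, mean = 1, sd = 0.15)
    mi[dim_tail] <- runif(sum(dim_tail), 0.02, 0.19)
    mi <- pmax(mi, 0.01)
    GRanges(chr, IRanges(pos, width = 1L),
            probe_id = sprintf("p%s_%06d", sub("chr", "", chr), pos %/%
                                 config@probeSpacingBp),
            gentrain = gentrain, mean_intensity = mi)
  })
}

#' Derive gene boundaries from transcripts (longest transcript rule)
#'
#' When a gene has several transcripts, the longest one defines the gene
#' boundary used for annotation and gene-centric association testing.
#'
#' @param transcripts data.frame with columns gene, chrom, start, end.
#' @return data.frame(gene, chrom, start, end), one row per gene, boundary
#'   taken from that gene's longest transcript.
#' @export
geneBoundaryFromTranscripts <- function(transcripts) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(transcripts)))
  if (any(transcripts$start > transcripts$end)) {
    stop("transcript with start > end")
  }
  len <- transcripts$end - transcripts$start + 1
  keep <- unlist(lapply(split(seq_len(nrow(transcripts)), transcripts$gene),
                        function(i) i[which.max(len[i])]))
  out <- transcripts[keep, c("gene", "chrom", "start", "end")]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Generate the synthetic annotation: genes, exons, exclusions, risk SNPs
#'
#' Places \code{nGenes} non-overlapping genes across the probe grid, each wide
#' enough to cover at least the minimum CNV probe count. Every gene gets 1-3
#' transcripts; the longest defines the gene boundary. Exons are placed
#' strictly inside the boundary. Telomere stand-in exclusion regions cover the
#' first and last two probe positions of every chromosome. A risk-SNP table
#' puts one lead SNP inside each designated risk gene (plus intergenic decoys)
#' and the LD table lists each lead as its own proxy (r2 = 1) plus one nearby
#' proxy.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param probeMap GRanges from \code{\link{generateProbeMap}}.
#' @return list with elements \code{genes} (GRanges, mcols gene_id),
#'   \code{exons} (GRanges, mcols gene_id), \code{transcripts} (data.frame),
#'   \code{exclusions} (GRanges), \code{riskSnps} (data.frame snp, chrom, pos,
#'   trait), \code{ldTable} (data.frame lead, proxy, proxy_pos, r2).
#' @export
generateAnnotation <- function(config, probeMap) {
  validObject(config)
  sp <- config@probeSpacingBp
  P <- config@probesPerChromosome
  chroms <- paste0("chr", seq_len(config@nChromosomes))
  minProbes <- config@cnvProbeCountRange[1]
  geneProbeSpan <- max(minProbes + 2L, 12L)   # probes per gene body
  gapProbes <- 4L
  # usable probe window excludes 2 telomeric probes each side
  usable <- P - 4L
  capPerChrom <- usable %/% (geneProbeSpan + gapProbes)
  if (config@nGenes > capPerChrom * config@nChromosomes) {
    stop("requested genes exceed genome capacity (",
         capPerChrom * config@nChromosomes, " fit)")
  }
  .withSeed(config@seed * 1000L + 2L, {
    txs <- list(); exs <- list()
    if (config@nGenes > 0L) {
      gchrom <- rep(chroms, length.out = config@nGenes)
      # slot genes left-to-right per chromosome
      slot <- ave(seq_len(config@nGenes), gchrom, FUN = seq_along)
      for (g in seq_len(config@nGenes)) {
        firstProbe <- 3L + (slot[g] - 1L) * (geneProbeSpan + gapProbes)
        gstart <- firstProbe * sp
        gend <- (firstProbe + geneProbeSpan - 1L) * sp
        gid <- sprintf("GENE%03d", g)
        ntx <- sample(1:3, 1)
        # transcripts share the 5' end; lengths vary, the longest spans the body
        lens <- sort(round(runif(ntx, 0.4, 1) * (gend - gstart)))
        lens[ntx] <- gend - gstart
        txs[[g]] <- data.frame(gene = gid, chrom = gchrom[g],
                               start = gstart, end = gstart + lens,
                               tx = sprintf("%s.t%d", gid, seq_len(ntx)))
        nex <- config@exonsPerGene
        bounds <- round(seq(gstart + sp, gend - sp, length.out = 2L * nex))
        exs[[g]] <- data.frame(gene = gid, chrom = gchrom[g],
                               start = bounds[seq(1, 2 * nex, 2)],
                               end = bounds[seq(2, 2 * nex, 2)])
      }
    }
    transcripts <- if (length(txs)) do.call(rbind, txs) else
      data.frame(gene = character(), chrom = character(),
                 start = integer(), end = integer(), tx = character())
    gb <- geneBoundaryFromTranscripts(transcripts)
    genes <- if (nrow(gb)) {
      GRanges(gb$chrom, IRanges(gb$start, gb$end), gene_id = gb$gene)
    } else GRanges(gene_id = character())
    exdf <- if (length(exs)) do.call(rbind, exs) else
      data.frame(gene = character(), chrom = character(),
                 start = integer(), end = integer())
    exons <- if (nrow(exdf)) {
      GRanges(exdf$chrom, IRanges(exdf$start, exdf$end), gene_id = exdf$gene)
    } else GRanges(gene_id = character())
    chromEnd <- P * sp
    exclusions <- GRanges(rep(chroms, each = 2L),
                          IRanges(rep(c(1L, chromEnd - 2L * sp + 1L),
                                      config@nChromosomes),
                                  rep(c(2L * sp, chromEnd),
                                      config@nChromosomes)))
    mcols(exclusions)$name <- rep(c("telomere_p", "telomere_q"),
                                  config@nChromosomes)
    # risk SNPs: one per risk gene + 3 intergenic decoys
    rs <- list(); ld <- list(); k <- 0L
    for (g in config@riskGenes$gene) {
      hit <- genes[mcols(genes)$gene_id == g]
      if (!length(hit)) next
      k <- k + 1L
      pos <- (start(hit) + end(hit)) %/% 2L
      id <- sprintf("rs%d", 10000L + k)
      rs[[length(rs) + 1L]] <- data.frame(
        snp = id, chrom = as.character(seqnames(hit)), pos = pos,
        trait = "disease")
      ld[[length(ld) + 1L]] <- data.frame(
        lead = id, proxy = c(id, paste0(id, "_px")),
        proxy_pos = c(pos, pos + sp %/% 2L), r2 = c(1, 0.9))
    }
    for (d in seq_len(3L)) {
      k <- k + 1L
      id <- sprintf("rs%d", 10000L + k)
      pos <- (P - 3L) * sp - d * 7L * sp
      rs[[length(rs) + 1L]] <- data.frame(
        snp = id, chrom = chroms[1], pos = pos, trait = "decoy")
      ld[[length(ld) + 1L]] <- data.frame(lead = id, proxy = id,
                                          proxy_pos = pos, r2 = 1)
    }
    list(genes = genes, exons = exons, transcripts = transcripts,
         exclusions = exclusions,
         riskSnps = do.call(rbind, rs),
         ldTable = do.call(rbind, ld))
  })
}

# place n background events for one sample without within-sample overlap;
# returns data.frame(chrom_i, start_probe, n_probes, type)
.placeEvents <- function(n, nChrom, P, rangeProbes, delFraction) {
  if (n == 0L) {
    return(data.frame(chrom_i = integer(), start_probe = integer(),
                      n_probes = integer(), type = character()))
  }
  out <- vector("list", n)
  occupied <- vector("list", nChrom)
  for (i in seq_len(n)) {
    for (attempt in seq_len(50L)) {
      ci <- sample.int(nChrom, 1L)
      np <- sample(seq(rangeProbes[1], rangeProbes[2]), 1L)
      if (np > P) np <- P
      s <- sample.int(P - np + 1L, 1L)
      iv <- c(s, s + np - 1L)
      clash <- FALSE
      for (o in occupied[[ci]]) {
        if (iv[1] <= o[2] && o[1] <= iv[2]) { clash <- TRUE; break }
      }
      if (!clash) {
        occupied[[ci]] <- c(occupied[[ci]], list(iv))
        out[[i]] <- data.frame(chrom_i = ci, start_probe = s, n_probes = np,
                               type = NA_character_)
        break
      }
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  out$type <- ifelse(runif(nrow(out)) < delFraction, "DEL", "DUP")
  out
}

#' Simulate a case-control cohort with embedded rare CNVs
#'
#' Builds the probe-by-sample LRR matrix as the sum of (i) \code{nWaves}
#' smooth sinusoidal wave components with per-sample Gaussian loadings, (ii)
#' per-sample Gaussian noise with heterogeneous SD and (iii) the signed
#' \code{delShift}/\code{dupShift} over the probes of every embedded event.
#' Background event counts are Poisson with mean \code{backgroundCnvRate}
#' (controls) times \code{caseBurdenMultiplier} (cases); designated risk genes
#' receive events at their configured case/control carrier frequencies. Any
#' locus whose realized carrier frequency would exceed \code{mafCeiling} is
#' resampled (background) or thinned (risk genes). BAF is emitted consistent
#' with copy number: diploid heterozygotes sit near 0.5, deletion probes lose
#' the heterozygous band, duplication heterozygotes split towards 1/3 and 2/3.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param probeMap GRanges from \code{\link{generateProbeMap}}.
#' @param annotation list from \code{\link{generateAnnotation}} (used for
#'   risk-gene placement); may be NULL when no risk genes are configured.
#' @return list with \code{intensity} (a \linkS4class{CNVIntensitySet}),
#'   \code{phenotypes} (data.frame sample, status) and \code{truth} (GRanges
#'   with mcols sample, type, n_probes: the embedded ground-truth events).
#' @export
simulateCohort <- function(config, probeMap, annotation = NULL) {
  validObject(config)
  if (nrow(config@riskGenes) &&
      any(config@riskGenes$case_freq > 1 | config@riskGenes$control_freq > 1)) {
    stop("carrier frequency > 1")
  }
  P <- config@probesPerChromosome
  nChrom <- config@nChromosomes
  nTot <- config@nCases + config@nControls
  sampleIds <- c(sprintf("case_%04d", seq_len(config@nCases)),
                 sprintf("ctrl_%04d", seq_len(config@nControls)))
  status <- rep(c("case", "control"), c(config@nCases, config@nControls))
  chroms <- paste0("chr", seq_len(nChrom))
  probeChromI <- as.integer(factor(as.character(seqnames(probeMap)),
                                   levels = chroms))
  nProbes <- length(probeMap)
  sp <- config@probeSpacingBp

  .withSeed(config@seed * 1000L + 3L, {
    # --- waves: smooth in genome position, per-sample loadings ---
    lrrM <- matrix(0, nProbes, nTot)
    if (config@nWaves > 0L) {
      t01 <- (seq_len(nProbes) - 1) / nProbes
      for (w in seq_len(config@nWaves)) {
        freq <- runif(1, 2, 12)
        phase <- runif(1, 0, 2 * pi)
        shape <- sin(2 * pi * freq * t01 + phase)
        loading <- rnorm(nTot, 0, config@waveAmplitude)
        lrrM <- lrrM + outer(shape, loading)
      }
    }
    # --- heterogeneous per-sample noise ---
    noiseSd <- pmax(config@noiseSdMean / 4,
                    rnorm(nTot, config@noiseSdMean, config@noiseSdSpread))
    lrrM <- lrrM + matrix(rnorm(nProbes * nTot), nProbes, nTot) *
      rep(noiseSd, each = nProbes)

    # --- background events ---
    rate <- ifelse(status == "case",
                   config@backgroundCnvRate * config@caseBurdenMultiplier,
                   config@backgroundCnvRate)
    nEv <- rpois(nTot, rate)
    evs <- vector("list", nTot)
    for (s in seq_len(nTot)) {
      e <- .placeEvents(nEv[s], nChrom, P, config@cnvProbeCountRange,
                        config@delFraction)
      if (nrow(e)) e$sample <- sampleIds[s]
      evs[[s]] <- e
    }
    ev <- do.call(rbind, evs[vapply(evs, nrow, 1L) > 0])
    if (is.null(ev)) {
      ev <- data.frame(chrom_i = integer(), start_probe = integer(),
                       n_probes = integer(), type = character(),
                       sample = character())
    }
    # rarity ceiling on identical background loci: resample the excess
    maxCarriers <- max(1L, floor(config@mafCeiling * nTot))
    if (nrow(ev)) {
      repeat {
        key <- paste(ev$chrom_i, ev$start_probe, ev$n_probes, ev$type)
        tab <- table(key)
        over <- names(tab)[tab > maxCarriers]
        if (!length(over)) break
        for (k in over) {
          idx <- which(key == k)
          redo <- idx[-seq_len(maxCarriers)]
          for (i in redo) {
            np <- ev$n_probes[i]
            ev$chrom_i[i] <- sample.int(nChrom, 1L)
            ev$start_probe[i] <- sample.int(P - np + 1L, 1L)
          }
        }
      }
    }

    # --- risk-gene events at configured carrier frequencies ---
    if (nrow(config@riskGenes)) {
      if (is.null(annotation)) stop("annotation required for risk genes")
      genes <- annotation$genes
      rg <- config@riskGenes
      if (is.null(rg$type)) rg$type <- "DEL"
      for (r in seq_len(nrow(rg))) {
        hit <- genes[mcols(genes)$gene_id == rg$gene[r]]
        if (!length(hit)) stop("risk gene not in gene model: ", rg$gene[r])
        pfreq <- ifelse(status == "case", rg$case_freq[r], rg$control_freq[r])
        carrier <- runif(nTot) < pfreq
        if (sum(carrier) > maxCarriers) {     # enforce the rarity ceiling
          keep <- sample(which(carrier), maxCarriers)
          carrier[] <- FALSE; carrier[keep] <- TRUE
        }
        if (!any(carrier)) next
        ci <- match(as.character(seqnames(hit)), chroms)
        sProbe <- max(1L, as.integer(ceiling(start(hit) / sp)))
        eProbe <- min(P, as.integer(end(hit) %/% sp))
        ev <- rbind(ev, data.frame(
          chrom_i = ci, start_probe = sProbe,
          n_probes = eProbe - sProbe + 1L, type = rg$type[r],
          sample = sampleIds[carrier]))
      }
    }

    # --- apply shifts; emit truth ---
    sampleIdx <- match(ev$sample, sampleIds)
    if (nrow(ev)) {
      shift <- ifelse(ev$type == "DEL", config@delShift, config@dupShift)
      for (i in seq_len(nrow(ev))) {
        pr <- (ev$chrom_i[i] - 1L) * P + ev$start_probe[i] +
          seq_len(ev$n_probes[i]) - 1L
        lrrM[pr, sampleIdx[i]] <- lrrM[pr, sampleIdx[i]] + shift[i]
      }
    }
    truth <- GRanges(chroms[ev$chrom_i],
                     IRanges(ev$start_probe * sp,
                             (ev$start_probe + ev$n_probes - 1L) * sp),
                     sample = ev$sample, type = ev$type,
                     n_probes = ev$n_probes)
    truth <- truth[order(match(mcols(truth)$sample, sampleIds),
                         as.integer(factor(as.character(seqnames(truth)),
                                           levels = chroms)),
                         start(truth))]

    # --- BAF consistent with copy number ---
    het <- matrix(runif(nProbes * nTot) < 0.35, nProbes, nTot)
    bafM <- matrix(ifelse(runif(nProbes * nTot) < 0.5, 0, 1), nProbes, nTot)
    bafM[het] <- rnorm(sum(het), 0.5, 0.02)
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        pr <- (ev$chrom_i[i] - 1L) * P + ev$start_probe[i] +
          seq_len(ev$n_probes[i]) - 1L
        sc <- sampleIdx[i]
        if (ev$type[i] == "DEL") {
          bafM[pr, sc] <- ifelse(runif(length(pr)) < 0.5, 0, 1)  # het band lost
        } else {
          h <- het[pr, sc]
          bafM[pr, sc][h] <- ifelse(runif(sum(h)) < 0.5, 1 / 3, 2 / 3) +
            rnorm(sum(h), 0, 0.02)
        }
      }
    }
    bafM[] <- pmin(1, pmax(0, bafM))
    dimnames(lrrM) <- list(mcols(probeMap)$probe_id, sampleIds)
    dimnames(bafM) <- dimnames(lrrM)

    se <- SummarizedExperiment(
      assays = list(lrr = lrrM, baf = bafM),
      rowRanges = probeMap,
      colData = DataFrame(status = status, noise_sd = noiseSd,
                          sex_flag = FALSE, row.names = sampleIds))
    intensity <- as(se, "CNVIntensitySet")
    validObject(intensity)
    list(intensity = intensity,
         phenotypes = data.frame(sample = sampleIds, status = status),
         truth = truth)
  })
}
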