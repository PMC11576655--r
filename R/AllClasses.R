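#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData assayNames
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom stats rnorm rpois runif rbinom rexp ave sd var t.test qt pt
#'   pnorm qnorm phyper cor.test setNames
#' @importFrom utils head tail
#' @useDynLib rareCNV, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Configuration of the synthetic SNP-array cohort generator
#'
#' Bundles every tunable of the synthetic cohort: array geometry, the
#' per-sample intensity noise model, smooth "genomic wave" artifact
#' components, the background rate of rare CNVs per genome, the case/control
#' burden ratio, CNV intensity shifts and designated risk genes.
#'
#' The defaults reproduce the conditions of a large cancer case-control
#' array study: a background of about 4.9 rare CNVs per control
#' genome, a 1.22-fold excess burden in cases, a 57% deletion fraction,
#' per-probe noise SD about 0.1 LRR units, and one-copy intensity shifts of
#' -0.5 (deletion) and +0.3 (duplication) on the Log R Ratio scale.
#'
#' @slot seed integer; master seed, same seed implies byte-identical output.
#' @slot nCases,nControls integer; cohort arm sizes.
#' @slot nChromosomes,probesPerChromosome,probeSpacingBp integer; probe grid.
#' @slot noiseSdMean,noiseSdSpread numeric; per-sample Gaussian LRR noise SD
#'   is drawn from N(mean, spread^2), truncated below at mean/4.
#' @slot nWaves,waveAmplitude numeric; number and amplitude (LRR units) of
#'   smooth sinusoidal wave components with per-sample loadings.
#' @slot backgroundCnvRate numeric; Poisson mean CNVs per control sample.
#' @slot caseBurdenMultiplier numeric >= 1; case rate multiplier.
#' @slot delFraction numeric in (0,1); fraction of background events that are
#'   deletions.
#' @slot cnvProbeCountRange integer(2); min/max probes per embedded event.
#' @slot delShift,dupShift numeric; signed LRR segment-mean shifts, with
#'   delShift < 0 < dupShift.
#' @slot nGenes,exonsPerGene integer; synthetic gene model size.
#' @slot riskGenes data.frame with columns \code{gene}, \code{case_freq},
#'   \code{control_freq} and optionally \code{type} (default DEL): designated
#'   risk genes with enriched case carrier frequency.
#' @slot mafCeiling numeric; rarity ceiling on realized per-locus carrier
#'   frequency (0.03 = "rare").
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nCases = "integer", nControls = "integer",
    nChromosomes = "integer", probesPerChromosome = "integer",
    probeSpacingBp = "integer",
    noiseSdMean = "numeric", noiseSdSpread = "numeric",
    nWaves = "integer", waveAmplitude = "numeric",
    backgroundCnvRate = "numeric", caseBurdenMultiplier = "numeric",
    delFraction = "numeric", cnvProbeCountRange = "integer",
    delShift = "numeric", dupShift = "numeric",
    nGenes = "integer", exonsPerGene = "integer",
    riskGenes = "data.frame", mafCeiling = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(
    nCases = object@nCases, nControls = object@nControls,
    nChromosomes = object@nChromosomes,
    probesPerChromosome = object@probesPerChromosome,
    probeSpacingBp = object@probeSpacingBp
  )
  bad <- names(counts)[counts <= 0L | is.na(counts)]
  if (length(bad)) {
    msg <- c(msg, paste0("counts must be positive: ", paste(bad, collapse = ", ")))
  }
  if (object@nWaves < 0L) msg <- c(msg, "nWaves must be >= 0")
  if (!(object@delFraction > 0 && object@delFraction < 1)) {
    msg <- c(msg, "delFraction must lie strictly in (0, 1)")
  }
  if (!(object@delShift < 0 && object@dupShift > 0)) {
    msg <- c(msg, "need delShift < 0 < dupShift")
  }
  if (object@caseBurdenMultiplier < 1) {
    msg <- c(msg, "caseBurdenMultiplier must be >= 1")
  }
  if (length(object@cnvProbeCountRange) != 2L ||
      object@cnvProbeCountRange[1] < 1L ||
      diff(object@cnvProbeCountRange) < 0L) {
    msg <- c(msg, "cnvProbeCountRange must be c(min, max) with 1 <= min <= max")
  }
  if (object@backgroundCnvRate < 0) msg <- c(msg, "backgroundCnvRate must be >= 0")
  if (!(object@mafCeiling > 0 && object@mafCeiling <= 1)) {
    msg <- c(msg, "mafCeiling must lie in (0, 1]")
  }
  rg <- object@riskGenes
  if (nrow(rg)) {
    if (!all(c("gene", "case_freq", "control_freq") %in% names(rg))) {
      msg <- c(msg, "riskGenes needs columns gene, case_freq, control_freq")
    } else if (any(rg$case_freq > 1 | rg$control_freq > 1 |
                   rg$case_freq < 0 | rg$control_freq < 0)) {
      msg <- c(msg, "risk-gene carrier frequencies must lie in [0, 1]")
    } else if (any(rg$case_freq > object@mafCeiling |
                   rg$control_freq > object@mafCeiling)) {
      msg <- c(msg, "risk-gene carrier frequencies must not exceed mafCeiling")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Probe-by-sample intensity container
#'
#' A \linkS4class{RangedSummarizedExperiment} holding the Log R Ratio
#' (assay \code{"lrr"}) and B-allele frequency (assay \code{"baf"}) matrices,
#' probes as rows (a \code{GRanges} ordered by chromosome then position, with
#' per-probe metadata \code{probe_id}, \code{gentrain} clustering score and
#' \code{mean_intensity}) and samples as columns (\code{colData$status} in
#' \{case, control\}).
#'
#' @export
setClass("CNVIntensitySet", contains = "RangedSummarizedExperiment")

setValidity("CNVIntensitySet", function(object) {
  msg <- character()
  if (!all(c("lrr", "baf") %in% assayNames(object))) {
    msg <- c(msg, "assays must include 'lrr' and 'baf'")
  }
  rr <- rowRanges(object)
  need <- c("probe_id", "gentrain", "mean_intensity")
  if (!all(need %in% names(mcols(rr)))) {
    msg <- c(msg, paste0("rowRanges needs mcols: ", paste(need, collapse = ", ")))
  }
  if (!"status" %in% names(colData(object))) {
    msg <- c(msg, "colData needs a 'status' column")
  } else if (!all(object$status %in% c("case", "control"))) {
    msg <- c(msg, "status must be 'case' or 'control'")
  }
  if (length(rr) > 1L) {
    pos <- start(rr)
    chr <- as.character(seqnames(rr))
    ord <- order(factor(chr, levels = unique(chr)), pos)
    if (!identical(ord, seq_along(rr))) {
      msg <- c(msg, "probes must be ordered by (chromosome, position)")
    }
    if (any(tapply(pos, chr, function(p) any(diff(p) <= 0)))) {
      msg <- c(msg, "positions must be strictly increasing within chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CNV calls annotated with gene and exon overlap
#'
#' Holds post-filter CNV calls together with their gene-overlap relation.
#' \code{calls} is a \code{GRanges} with mcols \code{sample}, \code{type}
#' (DEL/DUP), \code{n_probes} (and \code{mean_z} when the calls came from
#' the caller rather than a truth table), plus annotation flags
#' \code{genic} and \code{exonic}. \code{geneHits} records one row per
#' (call, gene) overlap of at least 1 bp, with the containment relation the
#' loss-of-function model needs: \code{cnv_contains_gene} (the CNV spans the
#' whole gene body) and \code{cnv_within_gene}.
#'
#' @slot calls GRanges of annotated calls.
#' @slot geneHits data.frame with columns call, gene, overlap_bp,
#'   cnv_contains_gene, cnv_within_gene.
#' @slot samples character; all cohort samples (so zero-call samples keep rows
#'   in downstream count tables).
#' @export
setClass("AnnotatedCNVs",
  representation(calls = "GRanges", geneHits = "data.frame",
                 samples = "character")
)

setValidity("AnnotatedCNVs", function(object) {
  msg <- character()
  m <- mcols(object@calls)
  need <- c("sample", "type", "n_probes", "genic", "exonic")
  if (!all(need %in% names(m))) {
    msg <- c(msg, paste0("calls need mcols: ", paste(need, collapse = ", ")))
  } else {
    if (any(m$exonic & !m$genic)) msg <- c(msg, "exonic implies genic")
    if (!all(m$type %in% c("DEL", "DUP"))) msg <- c(msg, "type must be DEL or DUP")
  }
  gh <- object@geneHits
  needh <- c("call", "gene", "overlap_bp", "cnv_contains_gene", "cnv_within_gene")
  if (!all(needh %in% names(gh))) {
    msg <- c(msg, paste0("geneHits needs columns: ", paste(needh, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohort: %d cases + %d controls (seed %d)\n",
              object@nCases, object@nControls, object@seed))
  cat(sprintf("  array: %d chromosome(s) x %d probes, spacing %d bp\n",
              object@nChromosomes, object@probesPerChromosome,
              object@probeSpacingBp))
  cat(sprintf("  noise SD ~ N(%.3g, %.3g^2); %d wave(s), amplitude %.3g\n",
              object@noiseSdMean, object@noiseSdSpread, object@nWaves,
              object@waveAmplitude))
  cat(sprintf("  CNVs: rate %.3g/sample, case multiplier %.3g, del fraction %.2f\n",
              object@backgroundCnvRate, object@caseBurdenMultiplier,
              object@delFraction))
  cat(sprintf("  shifts: DEL %.2f / DUP %.2f; %d-%d probes per event; MAF ceiling %.3g\n",
              object@delShift, object@dupShift, object@cnvProbeCountRange[1],
              object@cnvProbeCountRange[2], object@mafCeiling))
  cat(sprintf("  genes: %d (%d risk gene(s))\n", object@nGenes,
              nrow(object@riskGenes)))
  invisible(NULL)
})

setMethod("show", "AnnotatedCNVs", function(object) {
  m <- mcols(object@calls)
  cat(sprintf("AnnotatedCNVs: %d calls in %d samples (%d genic, %d exonic)\n",
              length(object@calls), length(object@samples),
              sum(m$genic), sum(m$exonic)))
  invisible(NULL)
})
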