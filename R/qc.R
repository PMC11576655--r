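# Sample- and probe-level quality control: DLRS, principal-component
# adjustment of LRR (wave/batch removal), and the exclusion thresholds.

#' Quality-control thresholds
#'
#' Defaults are the published exclusion rules: samples above mean + 3.5 SD of
#' the cohort DLRS distribution (before and, separately, after PC
#' adjustment), samples more than 4.89 SD from the mean BAF heterozygosity,
#' samples carrying 50 or more called CNVs, probes with clustering score
#' below 0.15 or mean intensity below 0.2 or LRR variance more than 2 SD
#' above the mean probe variance.
#'
#' @param dlrsSdMultiplier,hetSdMultiplier,maxCnvsPerSample,minGentrain,minMeanIntensity,probeVarSdMultiplier,nPcaComponents
#'   see Details; all multipliers must be positive.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(dlrsSdMultiplier = 3.5, hetSdMultiplier = 4.89,
                         maxCnvsPerSample = 50L, minGentrain = 0.15,
                         minMeanIntensity = 0.2, probeVarSdMultiplier = 2.0,
                         nPcaComponents = 10L) {
  stopifnot(dlrsSdMultiplier > 0, hetSdMultiplier > 0,
            probeVarSdMultiplier > 0, maxCnvsPerSample >= 1)
  list(dlrs_sd_multiplier = dlrsSdMultiplier,
       het_sd_multiplier = hetSdMultiplier,
       max_cnvs_per_sample = as.integer(maxCnvsPerSample),
       min_gentrain = minGentrain,
       min_mean_intensity = minMeanIntensity,
       probe_var_sd_multiplier = probeVarSdMultiplier,
       n_pca_components = as.integer(nPcaComponents))
}

#' Derivative log ratio spread (DLRS) of one sample
#'
#' Spread of probe-to-probe LRR differences along the genome: the SD of
#' successive within-chromosome differences divided by sqrt(2). Differences
#' are never taken across a chromosome boundary. The sqrt(2) divisor makes
#' DLRS an estimator of the per-probe noise SD: for iid noise with SD sigma,
#' successive differences have SD sigma * sqrt(2). DLRS is invariant to
#' adding a constant to the track (and to any slowly varying trend, to first
#' order) and scales linearly with the track.
#'
#' @param values numeric LRR track for one sample, genome-ordered.
#' @param chrom chromosome of each probe (same length as \code{values});
#'   NULL treats the track as one chromosome.
#' @return non-negative DLRS value (LRR units).
#' @examples
#' computeDLRS(c(0.1, -0.1, 0.1, -0.1))  # sd(c(-.2,.2,-.2))/sqrt(2)
#' @export
computeDLRS <- function(values, chrom = NULL) {
  if (length(values) < 3L) stop("DLRS needs at least 3 probes")
  if (is.null(chrom)) chrom <- rep("chr1", length(values))
  d <- unlist(lapply(split(values, factor(chrom, levels = unique(chrom))),
                     diff), use.names = FALSE)
  if (length(d) < 2L) stop("DLRS needs at least 2 within-chromosome differences")
  sd(d) / sqrt(2)
}

#' DLRS for every sample of an intensity matrix
#'
#' @param lrrMat probes x samples matrix, probes genome-ordered.
#' @param chrom per-probe chromosome vector.
#' @return named numeric vector, one DLRS per sample.
#' @export
sampleDLRS <- function(lrrMat, chrom) {
  idx <- split(seq_len(nrow(lrrMat)), factor(chrom, levels = unique(chrom)))
  d <- do.call(rbind, lapply(idx, function(i) diff(lrrMat[i, , drop = FALSE])))
  apply(d, 2, sd) / sqrt(2)
}

#' Remove leading principal components from an LRR matrix
#'
#' Mean-centres each probe across samples, then removes the top
#' \code{nComponents} sample-space components of the centred matrix (economy
#' SVD via the sample-by-sample cross-product). This absorbs genomic waves
#' and batch intensity artifacts that are shared across samples with varying
#' loadings, reducing DLRS; the residual matrix is orthogonal to the removed
#' components.
#'
#' @param lrrMat probes x samples matrix.
#' @param nComponents number of components to remove; 0 returns the
#'   mean-centred matrix unchanged.
#' @return residual matrix of the same dimension.
#' @export
pcaAdjust <- function(lrrMat, nComponents = 10L) {
  nComponents <- as.integer(nComponents)
  ns <- ncol(lrrMat)
  if (nComponents >= ns) stop("nComponents must be < number of samples")
  xc <- lrrMat - rowMeans(lrrMat)
  if (nComponents == 0L) return(xc)
  cp <- crossprod(xc)                       # samples x samples
  eg <- eigen(cp, symmetric = TRUE)
  v <- eg$vectors[, seq_len(nComponents), drop = FALSE]
  xc - (xc %*% v) %*% t(v)
}

#' BAF heterozygosity per sample
#'
#' Fraction of probes with BAF strictly inside (0.2, 0.8) — the heterozygous
#' band of a diploid genome.
#'
#' @param bafMat probes x samples BAF matrix.
#' @return named numeric vector in [0, 1].
#' @export
sampleHeterozygosity <- function(bafMat) {
  colMeans(bafMat > 0.2 & bafMat < 0.8)
}

#' Sample exclusion by QC metrics
#'
#' Single-pass exclusion chain: (1) DLRS before adjustment above the cohort
#' mean + multiplier * SD; (2) DLRS after adjustment above the mean +
#' multiplier * SD recomputed among samples surviving step 1; (3) BAF
#' heterozygosity more than \code{het_sd_multiplier} SD from the mean (either
#' direction); (4) samples flagged with sex-chromosome abnormalities. All
#' boundaries are strict (a sample exactly at the threshold is kept); with
#' zero cohort SD nothing is excluded. The >= 50-CNV exclusion belongs to the
#' calling stage, not here. Each excluded sample records the first rule that
#' fired.
#'
#' @param qcRecords data.frame with columns sample, dlrs_pre, dlrs_post,
#'   heterozygosity, sex_flag (logical).
#' @param thresholds list from \code{\link{qcThresholds}}.
#' @return list with \code{kept} (character sample ids) and \code{records}
#'   (the input with logical \code{excluded} and character \code{reason}).
#' @export
filterSamples <- function(qcRecords, thresholds = qcThresholds()) {
  need <- c("sample", "dlrs_pre", "dlrs_post", "heterozygosity", "sex_flag")
  if (!all(need %in% names(qcRecords))) {
    stop("qcRecords needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(qcRecords) == 0L) stop("empty cohort")
  rec <- qcRecords
  rec$excluded <- FALSE
  rec$reason <- NA_character_
  k <- thresholds$dlrs_sd_multiplier

  thrPre <- mean(rec$dlrs_pre) + k * sd(rec$dlrs_pre)
  hit <- !is.na(thrPre) & rec$dlrs_pre > thrPre
  rec$excluded[hit] <- TRUE; rec$reason[hit] <- "dlrs_pre"

  alive <- !rec$excluded
  thrPost <- mean(rec$dlrs_post[alive]) + k * sd(rec$dlrs_post[alive])
  hit <- alive & !is.na(thrPost) & rec$dlrs_post > thrPost
  rec$excluded[hit] <- TRUE; rec$reason[hit] <- "dlrs_post"

  alive <- !rec$excluded
  mh <- mean(rec$heterozygosity[alive]); sh <- sd(rec$heterozygosity[alive])
  hit <- alive & !is.na(sh) & sh > 0 &
    abs(rec$heterozygosity - mh) > thresholds$het_sd_multiplier * sh
  rec$excluded[hit] <- TRUE; rec$reason[hit] <- "heterozygosity"

  hit <- !rec$excluded & as.logical(rec$sex_flag)
  rec$excluded[hit] <- TRUE; rec$reason[hit] <- "sex_flag"

  list(kept = rec$sample[!rec$excluded], records = rec)
}

#' Probe exclusion by array metrics
#'
#' Keeps probes with clustering score >= \code{min_gentrain} AND mean
#' intensity >= \code{min_mean_intensity} AND LRR variance <= mean variance +
#' \code{probe_var_sd_multiplier} * SD of variance over all probes. Removal
#' boundaries are strict, matching the published "< 0.15" / "< 0.2" rules: a
#' probe exactly at a cut point is kept.
#'
#' @param probeMetrics data.frame with columns probe_id, gentrain,
#'   mean_intensity, lrr_var.
#' @param thresholds list from \code{\link{qcThresholds}}.
#' @return character vector of kept probe ids.
#' @export
filterProbes <- function(probeMetrics, thresholds = qcThresholds()) {
  need <- c("probe_id", "gentrain", "mean_intensity", "lrr_var")
  miss <- setdiff(need, names(probeMetrics))
  if (length(miss)) stop("missing metric column(s): ", paste(miss, collapse = ", "))
  vThr <- mean(probeMetrics$lrr_var) +
    thresholds$probe_var_sd_multiplier * sd(probeMetrics$lrr_var)
  keep <- probeMetrics$gentrain >= thresholds$min_gentrain &
    probeMetrics$mean_intensity >= thresholds$min_mean_intensity &
    probeMetrics$lrr_var <= vThr
  probeMetrics$probe_id[keep]
}

#' Run the full QC chain on an intensity set
#'
#' Computes pre-adjustment DLRS, removes principal components, recomputes
#' DLRS, applies the sample filters, then the probe filters on the adjusted
#' matrix restricted to kept samples.
#'
#' @param ints a \linkS4class{CNVIntensitySet}.
#' @param thresholds list from \code{\link{qcThresholds}}.
#' @return list: \code{adjusted} (adjusted LRR matrix, kept probes x kept
#'   samples), \code{sampleQC} (per-sample record data.frame),
#'   \code{keptSamples}, \code{keptProbes}, \code{probeMetrics}.
#' @export
runQC <- function(ints, thresholds = qcThresholds()) {
  stopifnot(is(ints, "CNVIntensitySet"))
  chrom <- as.character(seqnames(probeRanges(ints)))
  lrrMat <- lrr(ints)
  dlrsPre <- sampleDLRS(lrrMat, chrom)
  adj <- pcaAdjust(lrrMat, thresholds$n_pca_components)
  dlrsPost <- sampleDLRS(adj, chrom)
  het <- sampleHeterozygosity(baf(ints))
  sexFlag <- if ("sex_flag" %in% names(colData(ints))) {
    as.logical(colData(ints)$sex_flag)
  } else rep(FALSE, ncol(ints))
  rec <- data.frame(sample = colnames(ints), dlrs_pre = dlrsPre,
                    dlrs_post = dlrsPost, heterozygosity = het,
                    sex_flag = sexFlag, row.names = NULL)
  fs <- filterSamples(rec, thresholds)
  keptS <- fs$kept
  adjKept <- adj[, keptS, drop = FALSE]
  pm <- data.frame(probe_id = mcols(probeRanges(ints))$probe_id,
                   gentrain = mcols(probeRanges(ints))$gentrain,
                   mean_intensity = mcols(probeRanges(ints))$mean_intensity,
                   lrr_var = apply(adjKept, 1, var))
  keptP <- filterProbes(pm, thresholds)
  list(adjusted = adjKept[match(keptP, pm$probe_id), , drop = FALSE],
       sampleQC = fs$records, keptSamples = keptS, keptProbes = keptP,
       probeMetrics = pm)
}
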