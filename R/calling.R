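# Rare CNV calling from adjusted LRR: per-probe z-scores across samples,
# penalised mean-shift segmentation per sample, call thresholds, and the
# region / sample-count / rarity filters.

#' Calling thresholds
#'
#' Deletion calls require a segment mean z at or below \code{delZ};
#' duplications at or above \code{dupZ} (asymmetric because a one-copy gain
#' shifts LRR less than a one-copy loss). Only segments of 3-200 probes
#' become calls.
#'
#' @param delZ,dupZ segment mean-z thresholds.
#' @param minProbes,maxProbes retained probe-count range.
#' @param penaltyScale segmentation penalty is
#'   \code{penaltyScale * log(n)} per chromosome of n probes.
#' @return named list.
#' @export
callingThresholds <- function(delZ = -2.5, dupZ = 2.0,
                              minProbes = 3L, maxProbes = 200L,
                              penaltyScale = 3) {
  list(del_z = delZ, dup_z = dupZ, min_probes = as.integer(minProbes),
       max_probes = as.integer(maxProbes), penalty_scale = penaltyScale)
}

#' Standardise adjusted LRR to per-probe z-scores
#'
#' Each probe row is standardised to mean 0, SD 1 (n - 1 denominator) across
#' samples, so a rare carrier's intensity shift is expressed in units of that
#' probe's cohort noise.
#'
#' @param adjMat probes x samples adjusted-LRR matrix (QC-passed only).
#' @return z-score matrix of the same dimension.
#' @export
standardizeLRR <- function(adjMat) {
  mu <- rowMeans(adjMat)
  s <- sqrt(rowSums((adjMat - mu)^2) / (ncol(adjMat) - 1L))
  if (any(s == 0 | !is.finite(s))) {
    stop("zero-variance probe encountered; run filterProbes first")
  }
  (adjMat - mu) / s
}

#' Segment one sample's z-score track
#'
#' Penalised least-squares mean-shift change-point detection (optimal
#' partitioning with a bounded maximum segment length) applied independently
#' within each chromosome, so no segment spans a chromosome boundary. The
#' default penalty is \code{penaltyScale * log(n)} per chromosome of n
#' probes.
#'
#' @param zTrack numeric genome-ordered z values for one sample.
#' @param chrom per-probe chromosome (NULL = single chromosome).
#' @param penalty change-point penalty; NULL uses the default.
#' @param penaltyScale multiplier for the default penalty.
#' @param maxSegLen bounded lookback: maximum segment length considered by
#'   the dynamic program (must exceed the largest callable event; default
#'   256 > the 200-probe call cap). Change-free stretches longer than this
#'   are emitted as chains of near-zero-mean segments.
#' @return data.frame(start, end, n_probes, mean_z) of segments in track
#'   index coordinates; segments partition the track.
#' @export
segmentSample <- function(zTrack, chrom = NULL, penalty = NULL,
                          penaltyScale = 3, maxSegLen = 256L) {
  if (length(zTrack) == 0L) stop("empty track")
  if (is.null(chrom)) chrom <- rep("chr1", length(zTrack))
  idx <- split(seq_along(zTrack), factor(chrom, levels = unique(chrom)))
  segs <- lapply(idx, function(i) {
    pen <- if (is.null(penalty)) penaltyScale * log(length(i)) else penalty
    ends <- segment_meanshift(zTrack[i], pen, as.integer(maxSegLen))
    starts <- c(1L, head(ends, -1L) + 1L)
    data.frame(start = i[starts], end = i[ends])
  })
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out$n_probes <- out$end - out$start + 1L
  cs <- cumsum(c(0, zTrack))
  out$mean_z <- (cs[out$end + 1L] - cs[out$start]) / out$n_probes
  out
}

#' Turn segments into CNV calls
#'
#' Keeps segments of \code{min_probes}-\code{max_probes} probes whose mean z
#' crosses a call threshold; everything else is dropped.
#'
#' @param segments data.frame from \code{\link{segmentSample}}.
#' @param thresholds list from \code{\link{callingThresholds}}.
#' @return the calling segments with a \code{type} column (DEL/DUP).
#' @export
callCNVs <- function(segments, thresholds = callingThresholds()) {
  ok <- segments$n_probes >= thresholds$min_probes &
    segments$n_probes <= thresholds$max_probes
  del <- ok & segments$mean_z <= thresholds$del_z
  dup <- ok & segments$mean_z >= thresholds$dup_z
  out <- segments[del | dup, , drop = FALSE]
  out$type <- ifelse(out$mean_z <= thresholds$del_z, "DEL", "DUP")
  rownames(out) <- NULL
  out
}

#' Call CNVs for a whole cohort
#'
#' Standardises the adjusted LRR matrix, segments every sample per
#' chromosome, and applies the call thresholds. Interval coordinates are the
#' first and last probe positions of the segment (1-based inclusive).
#'
#' @param adjMat probes x samples adjusted-LRR matrix.
#' @param probes GRanges of the (kept) probes, rows aligned with
#'   \code{adjMat}.
#' @param thresholds list from \code{\link{callingThresholds}}.
#' @return GRanges of calls with mcols sample, type, n_probes, mean_z.
#' @export
callCohortCNVs <- function(adjMat, probes,
                           thresholds = callingThresholds()) {
  stopifnot(nrow(adjMat) == length(probes))
  z <- standardizeLRR(adjMat)
  chrom <- as.character(seqnames(probes))
  pos <- start(probes)
  res <- vector("list", ncol(z))
  for (s in seq_len(ncol(z))) {
    segs <- segmentSample(z[, s], chrom,
                          penaltyScale = thresholds$penalty_scale)
    calls <- callCNVs(segs, thresholds)
    if (nrow(calls)) {
      calls$sample <- colnames(z)[s]
      res[[s]] <- calls
    }
  }
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res) || nrow(res) == 0L) {
    return(GRanges(sample = character(), type = character(),
                   n_probes = integer(), mean_z = numeric()))
  }
  GRanges(chrom[res$start], IRanges(pos[res$start], pos[res$end]),
          sample = res$sample, type = res$type,
          n_probes = res$n_probes, mean_z = res$mean_z)
}

# connected components by union-find over an edge list
.components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 1L)
}

#' Group calls into loci by reciprocal overlap
#'
#' Two calls of the same type belong to one locus when their reciprocal
#' overlap is at least \code{minReciprocal} (transitively closed). The locus
#' interval is the span of its member calls; its frequency is the number of
#' distinct carrier samples over the cohort size.
#'
#' @param calls GRanges of calls (mcols sample, type).
#' @param nSamples cohort size for the frequency denominator.
#' @param minReciprocal reciprocal-overlap fraction (default 0.5).
#' @return GRanges of loci with mcols type, n_carriers, frequency and a
#'   \code{locus} index also attached to the input order via the returned
#'   attribute "membership" (integer vector, one entry per call).
#' @export
groupCallsIntoLoci <- function(calls, nSamples, minReciprocal = 0.5) {
  n <- length(calls)
  if (n == 0L) {
    out <- GRanges(type = character(), n_carriers = integer(),
                   frequency = numeric())
    attr(out, "membership") <- integer()
    return(out)
  }
  hits <- findOverlaps(calls, calls)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- q < s & mcols(calls)$type[q] == mcols(calls)$type[s]
  q <- q[keep]; s <- s[keep]
  if (length(q)) {
    ov <- width(pintersect(calls[q], calls[s]))
    rec <- ov >= minReciprocal * width(calls[q]) &
      ov >= minReciprocal * width(calls[s])
    q <- q[rec]; s <- s[rec]
  }
  memb <- .components(n, q, s)
  memb <- match(memb, unique(memb))
  loci <- lapply(split(seq_len(n), memb), function(i) {
    GRanges(seqnames(calls)[i[1]],
            IRanges(min(start(calls[i])), max(end(calls[i]))),
            type = mcols(calls)$type[i[1]],
            n_carriers = length(unique(mcols(calls)$sample[i])))
  })
  out <- do.call(c, unname(loci))
  mcols(out)$frequency <- mcols(out)$n_carriers / nSamples
  attr(out, "membership") <- memb
  out
}

#' Region, sample-count and rarity filters on CNV calls
#'
#' Drops calls overlapping (>= 1 bp) any exclusion region (immune loci,
#' centromeres, telomeres); then excludes every sample left with
#' \code{maxCnvsPerSample} or more calls, dropping all of its calls; finally
#' groups the remainder into loci by 50% reciprocal overlap and same type and
#' drops loci whose carrier frequency exceeds \code{mafCeiling}.
#'
#' @param calls GRanges from \code{\link{callCohortCNVs}}.
#' @param exclusions GRanges of excluded regions.
#' @param samples character vector of all (QC-passed) cohort samples — the
#'   frequency denominator.
#' @param maxCnvsPerSample exclusion threshold (a sample with this many or
#'   more calls is removed).
#' @param mafCeiling locus rarity ceiling.
#' @return list: \code{calls} (kept GRanges), \code{excludedSamples},
#'   \code{loci} (locus GRanges after the rarity filter).
#' @export
applyRegionRarityFilters <- function(calls, exclusions, samples,
                                     maxCnvsPerSample = 50L,
                                     mafCeiling = 0.03) {
  if (length(calls) && length(exclusions)) {
    hit <- unique(S4Vectors::queryHits(findOverlaps(calls, exclusions)))
    if (length(hit)) calls <- calls[-hit]
  }
  counts <- table(factor(mcols(calls)$sample, levels = samples))
  excluded <- names(counts)[counts >= maxCnvsPerSample]
  if (length(excluded)) {
    calls <- calls[!mcols(calls)$sample %in% excluded]
  }
  keptSamples <- setdiff(samples, excluded)
  loci <- groupCallsIntoLoci(calls, length(keptSamples))
  memb <- attr(loci, "membership")
  rare <- mcols(loci)$frequency <= mafCeiling
  keepCall <- if (length(calls)) rare[memb] else logical()
  list(calls = calls[keepCall], excludedSamples = excluded,
       loci = loci[rare])
}

#' Count unique CNVs
#'
#' A unique CNV is a distinct (chromosome, start, end, type) tuple.
#'
#' @param calls GRanges of calls.
#' @return integer count.
#' @export
countUniqueCNVs <- function(calls) {
  if (length(calls) == 0L) return(0L)
  length(unique(paste(seqnames(calls), start(calls), end(calls),
                      mcols(calls)$type)))
}
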