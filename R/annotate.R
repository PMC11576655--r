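# Gene/exon annotation of CNV calls and per-sample counts by genomic class.

#' Overlap length of two 1-based inclusive intervals
#'
#' \code{max(0, min(aEnd, bEnd) - max(aStart, bStart) + 1)}; zero when the
#' chromosomes differ. Book-ended intervals sharing a single base overlap by
#' 1 bp, satisfying the ">= 1 bp" annotation rule.
#'
#' @param aStart,aEnd,bStart,bEnd interval bounds (vectorised).
#' @param aChrom,bChrom optional chromosome labels.
#' @return integer overlap in bp.
#' @examples
#' overlapBp(100, 200, 200, 300)  # 1
#' overlapBp(100, 200, 201, 300)  # 0
#' @export
overlapBp <- function(aStart, aEnd, bStart, bEnd,
                      aChrom = NULL, bChrom = NULL) {
  if (any(aStart > aEnd) || any(bStart > bEnd)) stop("interval start > end")
  ov <- pmax(0L, pmin(aEnd, bEnd) - pmax(aStart, bStart) + 1L)
  if (!is.null(aChrom) && !is.null(bChrom)) ov[aChrom != bChrom] <- 0L
  ov
}

#' Restrict a gene model to canonical chromosomes
#'
#' Genes on anything but chr1-chr22, chrX/chr23 (scaffolds, chrM, alt
#' contigs) are rejected at load.
#'
#' @param genes GRanges with mcols gene_id.
#' @return filtered GRanges.
#' @export
keepCanonicalChromosomes <- function(genes) {
  ok <- as.character(seqnames(genes)) %in%
    c(paste0("chr", 1:23), "chrX", as.character(1:23), "X")
  genes[ok]
}

#' Annotate CNV calls with gene and exon overlap
#'
#' A call is genic when it overlaps (>= 1 bp) at least one gene boundary and
#' exonic when it overlaps at least one exon; intergenic otherwise. For every
#' (call, gene) pair the containment relation is recorded:
#' \code{cnv_contains_gene} when the call spans the entire gene body and
#' \code{cnv_within_gene} when the gene contains the whole call — the
#' loss-of-function association model needs this to decide whether a
#' duplication is transcript-disrupting.
#'
#' @param calls GRanges of filtered calls (mcols sample, type, n_probes,
#'   mean_z).
#' @param genes GRanges of gene boundaries (mcols gene_id).
#' @param exons GRanges of exons (mcols gene_id).
#' @param samples all cohort samples (kept even with zero calls).
#' @return an \linkS4class{AnnotatedCNVs}.
#' @export
annotateCNVs <- function(calls, genes, exons,
                         samples = unique(mcols(calls)$sample)) {
  genes <- keepCanonicalChromosomes(genes)
  hitsG <- findOverlaps(calls, genes)
  q <- S4Vectors::queryHits(hitsG); s <- S4Vectors::subjectHits(hitsG)
  gh <- data.frame(
    call = q,
    gene = mcols(genes)$gene_id[s],
    overlap_bp = if (length(q)) width(pintersect(calls[q], genes[s])) else integer(),
    cnv_contains_gene = start(calls)[q] <= start(genes)[s] &
      end(calls)[q] >= end(genes)[s],
    cnv_within_gene = start(calls)[q] >= start(genes)[s] &
      end(calls)[q] <= end(genes)[s])
  genic <- logical(length(calls)); genic[unique(q)] <- TRUE
  exonic <- logical(length(calls))
  if (length(exons)) {
    exonic[unique(S4Vectors::queryHits(findOverlaps(calls, exons)))] <- TRUE
  }
  exonic <- exonic & genic
  mcols(calls)$genic <- genic
  mcols(calls)$exonic <- exonic
  new("AnnotatedCNVs", calls = calls, geneHits = gh,
      samples = as.character(samples))
}

#' Per-sample CNV counts by genomic class and type
#'
#' Twelve columns per sample: \{all, genic, exonic, intergenic\} crossed with
#' \{ALL, DEL, DUP\}. \code{all = genic + intergenic} for every sample and
#' type; samples with no calls appear with zeros.
#'
#' @param annotated an \linkS4class{AnnotatedCNVs}.
#' @return data.frame, one row per sample, columns sample plus
#'   \code{<class>_<TYPE>}.
#' @export
perSampleCounts <- function(annotated) {
  calls <- cnvCalls(annotated)
  samples <- cohortSamples(annotated)
  m <- mcols(calls)
  sampleF <- factor(m$sample, levels = samples)
  classes <- list(all = rep(TRUE, length(calls)), genic = m$genic,
                  exonic = m$exonic, intergenic = !m$genic)
  types <- list(ALL = rep(TRUE, length(calls)), DEL = m$type == "DEL",
                DUP = m$type == "DUP")
  out <- data.frame(sample = samples)
  for (cl in names(classes)) {
    for (ty in names(types)) {
      sel <- classes[[cl]] & types[[ty]]
      out[[paste(cl, ty, sep = "_")]] <-
        as.integer(table(sampleF[sel]))
    }
  }
  out
}
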