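# Plain-text readers and writers for the pipeline's interchange formats:
# probe map TSV, LRR/BAF matrices, gene model GFF3, exclusion BED, BED-like
# call/truth TSVs, phenotype TSV.

#' @importFrom data.table fread fwrite as.data.table
NULL

#' Write / read the probe map
#'
#' TSV with columns probe_id, chrom, pos, gentrain_like_score,
#' mean_intensity.
#'
#' @param probes GRanges with mcols probe_id, gentrain, mean_intensity.
#' @param path file path.
#' @return \code{readProbeMap} returns the probe GRanges.
#' @export
writeProbeMap <- function(probes, path) {
  fwrite(data.table::data.table(
    probe_id = mcols(probes)$probe_id,
    chrom = as.character(seqnames(probes)),
    pos = start(probes),
    gentrain_like_score = mcols(probes)$gentrain,
    mean_intensity = mcols(probes)$mean_intensity), path, sep = "\t")
  invisible(path)
}

#' @rdname writeProbeMap
#' @export
readProbeMap <- function(path) {
  d <- fread(path, sep = "\t", data.table = FALSE)
  GRanges(d$chrom, IRanges(d$pos, width = 1L), probe_id = d$probe_id,
          gentrain = d$gentrain_like_score,
          mean_intensity = d$mean_intensity)
}

#' Write / read a probes-by-samples matrix as TSV
#'
#' First column \code{probe_id}, one column per sample.
#'
#' @param mat numeric matrix with rownames (probe ids) and colnames
#'   (samples).
#' @param path file path.
#' @return \code{readIntensityMatrix} returns the matrix.
#' @export
writeIntensityMatrix <- function(mat, path) {
  d <- data.table::as.data.table(mat, keep.rownames = "probe_id")
  fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(path) {
  d <- fread(path, sep = "\t", data.table = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write / read the gene model as GFF3
#'
#' Genes and exons round-trip through GFF3 (1-based inclusive, like the rest
#' of the pipeline).
#'
#' @param genes,exons GRanges with mcols gene_id.
#' @param path file path.
#' @return \code{readGeneModel} returns list(genes, exons).
#' @export
writeGeneModel <- function(genes, exons, path) {
  g <- genes
  mcols(g) <- DataFrame(type = "gene", ID = mcols(genes)$gene_id)
  e <- exons
  mcols(e) <- DataFrame(type = "exon", Parent = mcols(exons)$gene_id)
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' @rdname writeGeneModel
#' @export
readGeneModel <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  mcols(genes) <- DataFrame(gene_id = as.character(genes$ID))
  exons <- gr[gr$type == "exon"]
  parent <- as.character(unlist(exons$Parent))
  mcols(exons) <- DataFrame(gene_id = parent)
  list(genes = genes, exons = exons)
}

#' Write / read exclusion regions as BED
#'
#' BED is 0-based half-open on disk; conversion to the pipeline's 1-based
#' inclusive convention happens at this boundary (via rtracklayer).
#'
#' @param regions GRanges.
#' @param path file path.
#' @return \code{readExclusions} returns a GRanges.
#' @export
writeExclusions <- function(regions, path) {
  rtracklayer::export(regions, path, format = "bed")
  invisible(path)
}

#' @rdname writeExclusions
#' @export
readExclusions <- function(path) {
  rtracklayer::import(path, format = "bed")
}

#' Write / read CNV calls (or truth events) as BED-like TSV
#'
#' Columns chrom, start, end (1-based inclusive), sample, type, n_probes and
#' mean_z when present.
#'
#' @param calls GRanges with mcols sample, type, n_probes (and optionally
#'   mean_z).
#' @param path file path.
#' @return \code{readCalls} returns the GRanges.
#' @export
writeCalls <- function(calls, path) {
  d <- data.table::data.table(
    chrom = as.character(seqnames(calls)), start = start(calls),
    end = end(calls), sample = mcols(calls)$sample,
    type = mcols(calls)$type, n_probes = mcols(calls)$n_probes)
  if (!is.null(mcols(calls)$mean_z)) d$mean_z <- mcols(calls)$mean_z
  fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  d <- fread(path, sep = "\t", data.table = FALSE)
  gr <- GRanges(d$chrom, IRanges(d$start, d$end), sample = d$sample,
                type = d$type, n_probes = d$n_probes)
  if ("mean_z" %in% names(d)) mcols(gr)$mean_z <- d$mean_z
  gr
}

#' Write / read the phenotype table
#'
#' Two-column TSV: sample, status in \{case, control\}.
#'
#' @param phenotypes data.frame(sample, status).
#' @param path file path.
#' @return \code{readPhenotypes} returns the data.frame.
#' @export
writePhenotypes <- function(phenotypes, path) {
  fwrite(phenotypes[, c("sample", "status")], path, sep = "\t")
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  d <- fread(path, sep = "\t", data.table = FALSE)
  if (!all(d$status %in% c("case", "control"))) {
    stop("status must be case/control")
  }
  d
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  out
}
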