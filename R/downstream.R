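# Post-GWAS characterisation: risk-SNP colocalisation with LD expansion,
# hypergeometric over-representation, expression categories and
# dosage-sensitivity testing.

#' Overlap of candidate CNVs with risk SNPs (direct or via LD proxies)
#'
#' A pair is a \code{direct} overlap when the lead SNP position lies inside
#' the CNV interval (1-based inclusive, same chromosome); an \code{ld_proxy}
#' overlap when any proxy with r2 strictly above \code{r2Min} lies inside.
#' Each (CNV, SNP) pair is reported once with the strongest kind (direct
#' beats ld_proxy).
#'
#' @param cnvs GRanges of candidate CNVs (mcols sample, type at least).
#' @param riskSnps data.frame(snp, chrom, pos, trait).
#' @param ldTable data.frame(lead, proxy, proxy_pos, r2); proxies are on the
#'   lead SNP's chromosome.
#' @param r2Min LD threshold (strict >; default 0.8).
#' @return data.frame(cnv, chrom, start, end, snp, trait, kind).
#' @export
snpCnvOverlap <- function(cnvs, riskSnps, ldTable = NULL, r2Min = 0.8) {
  out <- list()
  chromC <- as.character(seqnames(cnvs))
  for (i in seq_len(nrow(riskSnps))) {
    lead <- riskSnps[i, ]
    same <- chromC == lead$chrom
    direct <- same & start(cnvs) <= lead$pos & end(cnvs) >= lead$pos
    proxy <- rep(FALSE, length(cnvs))
    if (!is.null(ldTable)) {
      px <- ldTable[ldTable$lead == lead$snp & ldTable$r2 > r2Min, ,
                    drop = FALSE]
      for (j in seq_len(nrow(px))) {
        proxy <- proxy | (same & start(cnvs) <= px$proxy_pos[j] &
                            end(cnvs) >= px$proxy_pos[j])
      }
    }
    hit <- direct | proxy
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        cnv = which(hit), chrom = chromC[hit], start = start(cnvs)[hit],
        end = end(cnvs)[hit], snp = lead$snp, trait = lead$trait,
        kind = ifelse(direct[hit], "direct", "ld_proxy"))
    }
  }
  if (!length(out)) {
    return(data.frame(cnv = integer(), chrom = character(),
                      start = integer(), end = integer(), snp = character(),
                      trait = character(), kind = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation test
#'
#' One-sided enrichment p-value \code{P(X >= overlap)} for drawing the query
#' from a universe of \code{N} genes containing a set of \code{K}, with
#' Bonferroni adjustment across \code{nSets} tested sets.
#'
#' @param query character query genes (must lie in the universe).
#' @param geneSet character gene set.
#' @param universe character vector of universe genes, or its size.
#' @param nSets number of sets tested (Bonferroni multiplier).
#' @return data.frame(overlap, set_size, query_size, universe_size, p_value,
#'   p_adjusted).
#' @examples
#' hypergeometricORA(c("g1", "g2"), c("g1", "g2", "g3"), paste0("g", 1:10))
#' @export
hypergeometricORA <- function(query, geneSet, universe, nSets = 1L) {
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    K <- length(unique(geneSet))
    n <- length(unique(query))
    ov <- length(intersect(unique(query), unique(geneSet)))
  } else {
    universe <- unique(universe)
    query <- unique(query)
    geneSet <- intersect(unique(geneSet), universe)
    if (!all(query %in% universe)) stop("query genes outside the universe")
    N <- length(universe); K <- length(geneSet); n <- length(query)
    ov <- length(intersect(query, geneSet))
  }
  if (n > N) stop("query larger than universe")
  p <- phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(overlap = ov, set_size = K, query_size = n, universe_size = N,
             p_value = p, p_adjusted = min(1, p * nSets))
}

#' Enrichment of several gene sets with Bonferroni correction
#'
#' @param query character query genes.
#' @param geneSets named list of character gene sets (e.g. read from GMT).
#' @param universe character universe.
#' @return data.frame, one row per set, Bonferroni-adjusted across all sets.
#' @export
oraTable <- function(query, geneSets, universe) {
  rows <- lapply(names(geneSets), function(nm) {
    cbind(data.frame(set = nm),
          hypergeometricORA(query, geneSets[[nm]], universe,
                            nSets = length(geneSets)))
  })
  out <- do.call(rbind, rows)
  out[order(out$p_adjusted, out$p_value), , drop = FALSE]
}

#' Expression category from TPM
#'
#' \code{tpm < 0.5}: not detected; \code{0.5 <= tpm < 10}: low;
#' \code{tpm >= 10}: high. The cut points are lower-inclusive.
#'
#' @param tpm non-negative transcripts-per-million values (vectorised).
#' @return character vector of categories.
#' @examples
#' expressionCategory(c(0, 5, 50))
#' @export
expressionCategory <- function(tpm) {
  if (any(tpm < 0)) stop("negative TPM")
  ifelse(tpm < 0.5, "not_detected", ifelse(tpm < 10, "low", "high"))
}

#' Dosage sensitivity of one gene
#'
#' Spearman rank correlation of gene copy number against expression across
#' tumour samples; the gene is dosage sensitive when the correlation is
#' positive and the two-sided p-value is below \code{pThreshold} (default
#' 1e-4). A constant copy-number vector makes the correlation undefined and
#' flags the gene untestable.
#'
#' @param copyNumber,expression equal-length numeric vectors, n >= 10.
#' @param pThreshold significance threshold.
#' @return one-row data.frame: correlation, p_value, dosage_sensitive,
#'   untestable.
#' @export
dosageSensitivity <- function(copyNumber, expression, pThreshold = 1e-4) {
  if (length(copyNumber) != length(expression)) stop("length mismatch")
  if (length(copyNumber) < 10L) stop("need at least 10 samples")
  if (sd(copyNumber) == 0 || sd(expression) == 0) {
    return(data.frame(correlation = NA_real_, p_value = NA_real_,
                      dosage_sensitive = FALSE, untestable = TRUE))
  }
  ct <- suppressWarnings(cor.test(copyNumber, expression,
                                  method = "spearman"))
  rho <- unname(ct$estimate)
  data.frame(correlation = rho, p_value = ct$p.value,
             dosage_sensitive = rho > 0 & ct$p.value < pThreshold,
             untestable = FALSE)
}
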