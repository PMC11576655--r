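# Global CNV burden: case vs control mean per-sample counts, Student's
# two-sample t-test, CI on the mean difference, and fold change.

#' Two-sample burden test for one CNV class
#'
#' Pooled-variance (Student) two-sample t-test of mean per-sample CNV counts
#' in cases vs controls, with the 95% CI on the mean difference built from
#' the pooled SE and the t quantile on n1 + n2 - 2 df, and fold change
#' defined as the ratio of group means.
#'
#' @param caseCounts,controlCounts non-negative per-sample counts.
#' @param conf confidence level for the CI.
#' @return one-row data.frame: mean_cases, mean_controls, mean_difference,
#'   ci_low, ci_high, t, p_value, fold_change.
#' @examples
#' burdenTest(c(7, 5, 6, 8), c(4, 5, 4, 5))
#' @export
burdenTest <- function(caseCounts, controlCounts, conf = 0.95) {
  if (length(caseCounts) < 2L || length(controlCounts) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (any(caseCounts < 0) || any(controlCounts < 0)) stop("counts must be >= 0")
  if (var(caseCounts) == 0 && var(controlCounts) == 0 &&
      mean(caseCounts) != mean(controlCounts)) {
    stop("degenerate zero pooled variance with unequal means")
  }
  tt <- t.test(caseCounts, controlCounts, var.equal = TRUE,
               conf.level = conf)
  m1 <- mean(caseCounts); m0 <- mean(controlCounts)
  data.frame(mean_cases = m1, mean_controls = m0,
             mean_difference = m1 - m0,
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             t = unname(tt$statistic), p_value = tt$p.value,
             fold_change = if (m0 > 0) m1 / m0 else NA_real_)
}

#' Full burden table (4 genomic classes x 3 CNV types)
#'
#' One burden test per \{all, genic, exonic, intergenic\} x \{ALL, DEL, DUP\}
#' cell of the per-sample count table, rows ordered class-major (all CNVs
#' first, then genic, exonic, intergenic; ALL/DEL/DUP within each class). A
#' class with zero counts in both groups is emitted with means 0 and
#' \code{p_value = NA} (flagged \code{degenerate}).
#'
#' @param sampleCounts data.frame from \code{\link{perSampleCounts}}.
#' @param phenotypes data.frame(sample, status) with status case/control.
#' @return data.frame of 12 rows with columns class, type and the
#'   \code{\link{burdenTest}} columns plus \code{degenerate}.
#' @export
burdenTable <- function(sampleCounts, phenotypes) {
  if (!setequal(sampleCounts$sample, phenotypes$sample)) {
    stop("phenotype/sample mismatch between count table and phenotypes")
  }
  status <- phenotypes$status[match(sampleCounts$sample, phenotypes$sample)]
  isCase <- status == "case"
  rows <- list()
  for (cl in c("all", "genic", "exonic", "intergenic")) {
    for (ty in c("ALL", "DEL", "DUP")) {
      x <- sampleCounts[[paste(cl, ty, sep = "_")]]
      ca <- x[isCase]; co <- x[!isCase]
      degenerate <- (var(ca) == 0 && var(co) == 0)
      if (degenerate) {
        row <- data.frame(mean_cases = mean(ca), mean_controls = mean(co),
                          mean_difference = mean(ca) - mean(co),
                          ci_low = NA_real_, ci_high = NA_real_,
                          t = NA_real_, p_value = NA_real_,
                          fold_change = if (mean(co) > 0) mean(ca) / mean(co)
                                        else NA_real_)
      } else {
        row <- burdenTest(ca, co)
      }
      row <- cbind(data.frame(class = cl, type = ty), row,
                   data.frame(degenerate = degenerate))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
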