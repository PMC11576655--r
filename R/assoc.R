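# Gene-centric CNV-GWAS: carrier matrices for the three association models,
# per-gene logistic regression (Firth-penalised under separation), Bonferroni
# thresholds, candidate flags, and the Wakefield Bayesian false discovery
# probability.

#' Build the per-gene carrier sets for one association model
#'
#' DEL model: a sample carries a gene when any of its deletions overlaps the
#' gene boundary (>= 1 bp). DUP model: likewise for duplications. LOF model:
#' all deletions, plus duplications that only partially overlap the gene —
#' a duplication spanning the entire gene body leaves an intact extra copy
#' and is excluded, while one breaking within the gene (including a
#' duplication fully inside the gene body, which disrupts the transcript) is
#' counted. A sample carrying several qualifying CNVs in one gene counts
#' once; the LOF carrier set of every gene is a superset of its DEL set.
#'
#' @param annotated an \linkS4class{AnnotatedCNVs}.
#' @param model "DEL", "DUP" or "LOF".
#' @return named list of character carrier-sample vectors, one per gene with
#'   at least one carrier.
#' @export
buildCarrierMatrix <- function(annotated, model = c("DEL", "DUP", "LOF")) {
  model <- match.arg(model)
  calls <- cnvCalls(annotated)
  gh <- geneHits(annotated)
  if (nrow(gh) == 0L) return(list())
  type <- mcols(calls)$type[gh$call]
  qualifies <- switch(model,
    DEL = type == "DEL",
    DUP = type == "DUP",
    LOF = type == "DEL" | (type == "DUP" & !gh$cnv_contains_gene))
  gh <- gh[qualifies, , drop = FALSE]
  if (nrow(gh) == 0L) return(list())
  carriers <- lapply(split(mcols(calls)$sample[gh$call], gh$gene),
                     function(s) sort(unique(s)))
  carriers[order(names(carriers))]
}

# Firth-penalised logistic fit on an aggregated 2x2 design
# (intercept + carrier indicator), Newton-Raphson on the modified score.
.firth2x2 <- function(a, b, n1, n0, maxit = 100, tol = 1e-10) {
  x <- rbind(c(1, 0), c(1, 1))             # rows: non-carrier, carrier
  y <- c(n1 - a, a)                        # cases per row
  m <- c(n1 + n0 - a - b, a + b)           # totals per row
  pll <- function(beta) {                  # penalised binomial log-likelihood
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- m * p * (1 - p)
    sum(y * eta - m * log1p(exp(eta))) +
      0.5 * determinant(t(x * w) %*% x)$modulus
  }
  beta <- c(log((n1 + 0.5) / (n0 + 0.5)), 0)
  llOld <- pll(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- m * p * (1 - p)
    info <- t(x * w) %*% x
    infoInv <- solve(info)
    h <- rowSums((x %*% infoInv) * x) * w   # hat diagonal
    U <- drop(t(x) %*% (y - m * p + h * (0.5 - p)))
    step <- drop(infoInv %*% U)
    # damped Newton: halve until the penalised likelihood does not decrease
    for (half in seq_len(30L)) {
      cand <- beta + step
      llNew <- pll(cand)
      if (is.finite(llNew) && llNew >= llOld - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step
    converged <- max(abs(step)) < tol
    llOld <- pll(beta)
    if (converged) break
  }
  eta <- drop(x %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- m * p * (1 - p)
  se <- sqrt(diag(solve(t(x * w) %*% x)))
  list(beta = beta[2], se = se[2])
}

#' Per-gene logistic association test
#'
#' Logistic regression of case/control status on the binary carrier
#' indicator, no covariates. With a single binary predictor the maximum
#' likelihood estimate equals the crude 2x2 cross-product odds ratio, so the
#' closed form is used whenever all four cells are nonzero (log OR with
#' Wald SE = sqrt(sum of reciprocal cells)); a zero cell (separation) falls
#' back to Firth penalised likelihood, which always yields a finite OR.
#'
#' @param carriersCases,carriersControls carrier counts a, b.
#' @param nCases,nControls arm sizes N1, N0.
#' @return one-row data.frame: carriers_cases, carriers_controls, odds_ratio,
#'   ci_low, ci_high, p_value, method ("wald" or "firth").
#' @examples
#' geneLogisticTest(6, 4, 4115, 17818)  # OR = (6*17814)/(4*4109) = 6.50
#' @export
geneLogisticTest <- function(carriersCases, carriersControls,
                             nCases, nControls) {
  a <- carriersCases; b <- carriersControls
  if (nCases <= 0 || nControls <= 0) stop("arm sizes must be positive")
  if (a + b == 0L) stop("gene has no carriers; not testable")
  if (a > nCases || b > nControls) stop("more carriers than samples")
  cells <- c(a, nCases - a, b, nControls - b)
  if (all(cells > 0)) {
    logOR <- log(a) - log(nCases - a) - log(b) + log(nControls - b)
    se <- sqrt(sum(1 / cells))
    method <- "wald"
  } else {
    fit <- .firth2x2(a, b, nCases, nControls)
    logOR <- fit$beta
    se <- fit$se
    method <- "firth"
  }
  z <- logOR / se
  data.frame(carriers_cases = a, carriers_controls = b,
             odds_ratio = exp(logOR),
             ci_low = exp(logOR - qnorm(0.975) * se),
             ci_high = exp(logOR + qnorm(0.975) * se),
             p_value = 2 * pnorm(-abs(z)), method = method)
}

#' Per-model genome-wide Bonferroni threshold
#'
#' 0.05 divided by the number of genes tested in that model (genes with at
#' least one qualifying carrier), so each model has its own denominator.
#'
#' @param nGenesTested positive integer.
#' @return p-value threshold.
#' @examples
#' genomeWideThreshold(6014)  # 8.31e-6
#' @export
genomeWideThreshold <- function(nGenesTested) {
  if (nGenesTested < 1) stop("no genes tested")
  0.05 / nGenesTested
}

#' Wakefield Bayesian false discovery probability
#'
#' Given a log odds-ratio estimate \code{thetaHat} with variance \code{V},
#' the approximate Bayes factor of the null against the alternative with a
#' N(0, W) prior on the log OR is
#' \code{sqrt((V + W) / V) * exp(-Z^2 * W / (2 * (V + W)))} where
#' \code{Z = thetaHat / sqrt(V)}; combined with the prior odds of the null
#' \code{(1 - pi1) / pi1} this gives the posterior probability of no
#' association. \code{W} is set so that \code{orBound} is the 97.5th
#' percentile of the prior odds ratio: \code{W = (log(orBound) / 1.96)^2}.
#'
#' @param thetaHat log odds-ratio estimate.
#' @param V its variance (> 0).
#' @param pi1 prior probability of association (tiers 0.5 / 0.2 / 0.05).
#' @param orBound upper prior bound on the odds ratio (default 8).
#' @return BFDP in [0, 1]; small values mean the association is likely real.
#' @export
bfdp <- function(thetaHat, V, pi1, orBound = 8.0) {
  if (any(V <= 0)) stop("V must be positive")
  if (any(pi1 <= 0 | pi1 >= 1)) stop("pi1 must lie in (0, 1)")
  W <- (log(orBound) / qnorm(0.975))^2
  Z <- thetaHat / sqrt(V)
  bf <- sqrt((V + W) / V) * exp(-Z^2 * W / (2 * (V + W)))
  po <- (1 - pi1) / pi1
  bf * po / (bf * po + 1)
}

#' Run the three-model gene-centric CNV-GWAS
#'
#' For each model (deletion-only, duplication-only, loss-of-function) builds
#' the carrier matrix, tests every gene with at least one carrier, flags
#' candidates (p < 0.01) and genome-wide significant genes
#' (p < 0.05 / n genes tested in that model), and computes the BFDP with the
#' gene's prior tier (0.05 when the gene is absent from the prior table).
#'
#' @param annotated an \linkS4class{AnnotatedCNVs}.
#' @param phenotypes data.frame(sample, status).
#' @param priors optional data.frame(gene, prior) with prior in
#'   \{0.5, 0.2, 0.05\}.
#' @param models character subset of c("DEL", "DUP", "LOF").
#' @param candidateP candidate threshold (default 0.01).
#' @return named list of per-model data.frames (gene, carriers, OR, CI, p,
#'   candidate, genome_wide_significant, bfdp) with attributes
#'   \code{n_genes_tested} and \code{gw_threshold}.
#' @export
runCnvGwas <- function(annotated, phenotypes, priors = NULL,
                       models = c("DEL", "DUP", "LOF"),
                       candidateP = 0.01) {
  status <- setNames(phenotypes$status, phenotypes$sample)
  samples <- cohortSamples(annotated)
  status <- status[samples]
  if (anyNA(status)) stop("phenotype missing for some cohort samples")
  n1 <- sum(status == "case"); n0 <- sum(status == "control")
  caseIds <- names(status)[status == "case"]
  out <- list()
  for (model in models) {
    cm <- buildCarrierMatrix(annotated, model)
    res <- vector("list", length(cm))
    for (i in seq_along(cm)) {
      a <- sum(cm[[i]] %in% caseIds)
      b <- length(cm[[i]]) - a
      r <- geneLogisticTest(a, b, n1, n0)
      r <- cbind(data.frame(gene = names(cm)[i], model = model), r)
      res[[i]] <- r
    }
    tab <- if (length(res)) do.call(rbind, res) else
      data.frame(gene = character(), model = character(),
                 carriers_cases = integer(), carriers_controls = integer(),
                 odds_ratio = numeric(), ci_low = numeric(),
                 ci_high = numeric(), p_value = numeric(),
                 method = character())
    nTested <- nrow(tab)
    thr <- if (nTested) genomeWideThreshold(nTested) else NA_real_
    tab$candidate <- tab$p_value < candidateP
    tab$genome_wide_significant <- tab$p_value < thr
    pi1 <- rep(0.05, nTested)
    if (!is.null(priors) && nTested) {
      m <- match(tab$gene, priors$gene)
      pi1[!is.na(m)] <- priors$prior[m[!is.na(m)]]
    }
    if (nTested) {
      V <- ((log(tab$ci_high) - log(tab$ci_low)) / (2 * qnorm(0.975)))^2
      tab$bfdp <- bfdp(log(tab$odds_ratio), V, pi1)
    } else {
      tab$bfdp <- numeric()
    }
    attr(tab, "n_genes_tested") <- nTested
    attr(tab, "gw_threshold") <- thr
    out[[model]] <- tab
  }
  out
}
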