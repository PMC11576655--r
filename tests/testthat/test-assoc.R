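test_that("carrier matrices implement the three model definitions", {
  genes <- GRanges("chr1", IRanges(c(1000, 10000), c(5000, 15000)),
                   gene_id = c("gA", "gB"))
  exons <- GRanges("chr1", IRanges(1200, 1300), gene_id = "gA")
  calls <- makeCalls("chr1",
                     c(2000, 900, 12000, 11000),
                     c(3000, 5500, 16000, 12000),
                     c("s1", "s2", "s3", "s4"),
                     c("DEL", "DUP", "DUP", "DUP"))
  # s1: deletion inside gA; s2: duplication containing all of gA
  # s3: duplication over gB's 3' half; s4: duplication inside gB
  anno <- annotateCNVs(calls, genes, exons, paste0("s", 1:4))
  del <- buildCarrierMatrix(anno, "DEL")
  dup <- buildCarrierMatrix(anno, "DUP")
  lof <- buildCarrierMatrix(anno, "LOF")
  expect_equal(del, list(gA = "s1"))
  expect_equal(dup, list(gA = "s2", gB = c("s3", "s4")))
  # LOF: deletion in gA; dup containing gA excluded; partial and internal
  # duplications of gB included
  expect_equal(lof, list(gA = "s1", gB = c("s3", "s4")))
  expect_error(buildCarrierMatrix(anno, "XXX"))
})

test_that("LOF carriers are a superset of DEL carriers on synthetic data", {
  fix <- tinyCohort()
  anno <- annotateCNVs(fix$cohort$truth, fix$ann$genes, fix$ann$exons,
                       samples = colnames(fix$cohort$intensity))
  del <- buildCarrierMatrix(anno, "DEL")
  lof <- buildCarrierMatrix(anno, "LOF")
  for (g in names(del)) {
    expect_true(all(del[[g]] %in% lof[[g]]))
  }
})

test_that("the logistic test equals the 2x2 cross-product odds ratio", {
  r <- geneLogisticTest(6, 4, 4115, 17818)
  expect_equal(r$odds_ratio, (6 * 17814) / (4 * 4109), tolerance = 1e-10)
  expect_equal(round(r$odds_ratio, 2), 6.50)
  # equal carrier frequencies: OR 1, p ~ 1
  r0 <- geneLogisticTest(10, 40, 1000, 4000)
  expect_equal(r0$odds_ratio, 1, tolerance = 1e-12)
  expect_gt(r0$p_value, 0.99)
  # closed form within 1e-6 of the crude OR whenever all cells are nonzero
  set.seed(81)
  for (i in 1:20) {
    a <- sample(1:30, 1); b <- sample(1:30, 1)
    r <- geneLogisticTest(a, b, 500, 2000)
    expect_equal(r$odds_ratio, (a / (500 - a)) / (b / (2000 - b)),
                 tolerance = 1e-6)
  }
  expect_error(geneLogisticTest(0, 0, 10, 10), "no carriers")
})

test_that("the closed form agrees with an actual glm fit", {
  a <- 12; b <- 30; n1 <- 400; n0 <- 1600
  fit <- glm(cbind(c(n1 - a, a), c(n0 - b, b)) ~ c(0, 1),
             family = binomial())
  r <- geneLogisticTest(a, b, n1, n0)
  expect_equal(log(r$odds_ratio), unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(r$p_value, summary(fit)$coefficients[2, 4], tolerance = 1e-4)
})

test_that("separation falls back to a finite Firth estimate", {
  r <- geneLogisticTest(3, 0, 100, 200)
  expect_equal(r$method, "firth")
  expect_true(is.finite(r$odds_ratio) && r$odds_ratio > 1)
  expect_true(r$p_value > 0 && r$p_value < 1)
  # oracle: Firth on a saturated 2x2 equals adding 1/2 to every cell
  expect_equal(log(r$odds_ratio),
               log((3.5 * 200.5) / (0.5 * 97.5)), tolerance = 1e-6)
  r2 <- geneLogisticTest(0, 5, 150, 300)
  expect_equal(log(r2$odds_ratio),
               log((0.5 * 295.5) / (5.5 * 150.5)), tolerance = 1e-6)
})

test_that("genome-wide thresholds reproduce the per-model Bonferroni cuts", {
  expect_equal(signif(genomeWideThreshold(6014), 3), 8.31e-6)
  expect_equal(signif(genomeWideThreshold(8377), 3), 5.97e-6)
  expect_equal(signif(genomeWideThreshold(8613), 3), 5.81e-6)
  expect_equal(genomeWideThreshold(1), 0.05)
  expect_error(genomeWideThreshold(0), "no genes")
})

test_that("BFDP matches direct normal-density evaluation", {
  # oracle: ratio of the two marginal densities of thetaHat
  oracle <- function(th, V, pi1, bound = 8) {
    W <- (log(bound) / qnorm(0.975))^2
    bf <- dnorm(th, 0, sqrt(V)) / dnorm(th, 0, sqrt(V + W))
    po <- (1 - pi1) / pi1
    bf * po / (bf * po + 1)
  }
  for (th in c(0, 0.3, log(2))) {
    for (V in c(0.01, 0.2)) {
      for (pi1 in c(0.5, 0.2, 0.05)) {
        expect_equal(bfdp(th, V, pi1), oracle(th, V, pi1),
                     tolerance = 1e-12)
      }
    }
  }
  # strong, precise effect: association nearly certain
  expect_lt(bfdp(log(2), 0.01, 0.05), 1e-7)
  expect_equal(bfdp(log(2), 0.01, 0.05), 9e-9, tolerance = 0.2)
  # Z = 0 with V = W: BF = sqrt(2), bfdp = sqrt(2)/(1 + sqrt(2)) at pi 0.5
  W <- (log(8) / qnorm(0.975))^2
  expect_equal(bfdp(0, W, 0.5), sqrt(2) / (1 + sqrt(2)), tolerance = 1e-12)
  # W -> 0: the data cannot discriminate, posterior = prior of the null
  expect_equal(bfdp(1, 0.04, 0.2, orBound = 1 + 1e-12), 0.8,
               tolerance = 1e-6)
  expect_error(bfdp(1, 0, 0.5), "positive")
})

test_that("BFDP is monotone in |Z| and in the prior", {
  V <- 0.05
  zs <- seq(0, 6, by = 0.5)
  vals <- bfdp(zs * sqrt(V), V, 0.2)
  expect_true(all(diff(vals) < 0))
  pis <- c(0.5, 0.2, 0.05)
  v2 <- bfdp(0.5, V, pis)
  expect_true(all(diff(v2) > 0))   # smaller prior of association -> larger bfdp
})

test_that("the three-model GWAS flags candidates and applies priors", {
  fix <- tinyCohort()
  anno <- annotateCNVs(fix$cohort$truth, fix$ann$genes, fix$ann$exons,
                       samples = colnames(fix$cohort$intensity))
  priors <- data.frame(gene = "GENE001", prior = 0.5)
  gwas <- runCnvGwas(anno, fix$cohort$phenotypes, priors = priors)
  expect_setequal(names(gwas), c("DEL", "DUP", "LOF"))
  for (m in names(gwas)) {
    tab <- gwas[[m]]
    expect_equal(attr(tab, "n_genes_tested"), nrow(tab))
    expect_equal(attr(tab, "gw_threshold"), 0.05 / nrow(tab))
    # genome-wide significance implies candidate
    expect_true(all(tab$candidate[tab$genome_wide_significant]))
    expect_true(all(tab$bfdp >= 0 & tab$bfdp <= 1))
    expect_true(all(tab$carriers_cases + tab$carriers_controls >= 1))
  }
  # a gene with a generous prior gets a smaller bfdp than the default tier
  del <- gwas$DEL
  if ("GENE001" %in% del$gene) {
    i <- which(del$gene == "GENE001")
    V <- ((log(del$ci_high[i]) - log(del$ci_low[i])) / (2 * qnorm(0.975)))^2
    expect_lt(del$bfdp[i],
              bfdp(log(del$odds_ratio[i]), V, 0.05) + 1e-12)
  }
})

test_that("an enriched risk gene is detected by the matching model", {
  # carrier draw mirrors the generator's risk-gene mechanism
  set.seed(91)
  hits <- 0L
  for (i in 1:50) {
    a <- rbinom(1, 4000, 0.005)
    b <- rbinom(1, 18000, 0.0005)
    if (a + b == 0) next
    if (geneLogisticTest(a, b, 4000, 18000)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 48)
})
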