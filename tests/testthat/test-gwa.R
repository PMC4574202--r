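makePanel <- function(seed, L = 60, m = 200, maf = c(0.05, 0.5)) {
  simulateGenotypes(simulationConfig(n_lines = L, n_variants = m,
                                     maf_range = maf, seed = seed))
}

test_that("MAF filter keeps the inclusive boundary and matches a recount oracle", {
  # constructed boundary panel: 100 lines, variants at exactly 4% and 5%
  geno <- rbind(v04 = c(rep(2, 4), rep(0, 96)),
                v05 = c(rep(2, 5), rep(0, 95)),
                mono = rep(0, 100),
                v50 = rep(c(0, 2), 50))
  lines <- sprintf("l%03d", 1:100)
  colnames(geno) <- lines
  vr <- GenomicRanges::GRanges("2L", IRanges::IRanges(1:4 * 1000, width = 1),
                               id = rownames(geno), type = "SNP")
  gp <- GenotypePanel(geno, vr, data.frame(wolbachia = rep(FALSE, 100),
                                           row.names = lines))
  fp <- suppressMessages(filterVariants(gp, maf_min = 0.05))
  expect_setequal(variantIds(fp), c("v05", "v50"))
  # recount oracle on a simulated spectrum
  gp2 <- makePanel(5, L = 80, m = 300, maf = c(0.02, 0.5))
  fp2 <- suppressMessages(filterVariants(gp2, maf_min = 0.1))
  g <- genoMatrix(gp2)
  brute <- sum(vapply(seq_len(nrow(g)), function(v) {
    f <- mean(g[v, ]) / 2
    min(f, 1 - f) >= 0.1
  }, logical(1)))
  expect_equal(nrow(genoMatrix(fp2)), brute)
  gp3 <- makePanel(6, L = 80, m = 40, maf = c(0.02, 0.3))
  expect_error(suppressMessages(filterVariants(gp3, maf_min = 0.5)),
               "no variants")
})

test_that("covariate adjustment is a projection: residuals orthogonal to the design", {
  gp <- makePanel(11, L = 80, m = 50)
  set.seed(11)
  tv <- setNames(rnorm(80, 12, 3) + 1.5 * lineData(gp)$wolbachia,
                 lineIds(gp))
  ca <- suppressMessages(covariateAdjust(tv, gp))
  X <- model.matrix(ca$model)
  r <- ca$adjusted - mean(tv[names(ca$adjusted)])
  expect_lt(max(abs(crossprod(X, r))), 1e-8)
  expect_true("wolbachia" %in% ca$anova$term)
  expect_equal(mean(ca$adjusted), mean(tv[names(ca$adjusted)]),
               tolerance = 1e-10)
})

test_that("constant covariates give an identity adjustment; aliased terms error", {
  gp <- makePanel(12, L = 30, m = 20)
  ld <- lineData(gp)
  ld$wolbachia <- FALSE
  ld$In2Lt <- "ST"; ld$In2RNS <- "ST"; ld$In3RP <- "ST"
  ld$In3RK <- "ST"; ld$In3RMo <- "ST"
  gp2 <- GenotypePanel(genoMatrix(gp), variantRanges(gp), ld)
  tv <- setNames(rnorm(30), lineIds(gp2))
  ca <- suppressMessages(covariateAdjust(tv, gp2))
  expect_null(ca$anova)
  expect_equal(unname(ca$adjusted), unname(tv[names(ca$adjusted)]))
  # duplicated covariate column => aliased
  ld3 <- lineData(gp)
  ld3$wolb_copy <- ld3$wolbachia
  gp3 <- GenotypePanel(genoMatrix(gp), variantRanges(gp), ld3)
  expect_error(suppressMessages(
    covariateAdjust(tv, gp3, covariates = c("wolbachia", "wolb_copy"))),
    "aliased")
})

test_that("covariate detection rate matches the analytic power of the F test", {
  L <- 182; effect <- 1; sd_lm <- 3.2; nsim <- 120
  set.seed(77)
  wol <- rep(c(TRUE, FALSE), length.out = L)
  hits <- vapply(seq_len(nsim), function(i) {
    y <- rnorm(L, 12, sd_lm) + effect * wol
    summary(lm(y ~ wol))$coefficients[2, 4] < 0.05
  }, logical(1))
  ncp <- effect / (sd_lm * sqrt(4 / L))
  pow <- pt(qt(0.975, L - 2), L - 2, ncp, lower.tail = FALSE) +
    pt(qt(0.025, L - 2), L - 2, ncp)
  expect_lt(abs(mean(hits) - pow), 3 * sqrt(pow * (1 - pow) / nsim))
})

test_that("GRM construction: identical lines, PSD, near-identity for independent genotypes", {
  gp <- makePanel(31, L = 50, m = 400)
  G <- computeGRM(gp)
  expect_equal(G, t(G), tolerance = 1e-12)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  offd <- G[upper.tri(G)]
  expect_lt(abs(mean(offd)), 0.02)
  # duplicating a line: its relatedness to the copy equals the diagonal
  geno <- genoMatrix(gp)
  geno2 <- cbind(geno, dup = geno[, 1])
  ld <- rbind(as.data.frame(lineData(gp)),
              dup = as.data.frame(lineData(gp))[1, ])
  gp2 <- GenotypePanel(geno2, variantRanges(gp), ld)
  G2 <- computeGRM(gp2)
  expect_equal(G2["dup", colnames(geno)[1]], G2["dup", "dup"],
               tolerance = 1e-10)
})

test_that("with an identity GRM the mixed-model scan reduces exactly to OLS", {
  gp <- makePanel(41, L = 60, m = 80)
  set.seed(41)
  tv <- setNames(rnorm(60, 10, 2), lineIds(gp))
  G <- diag(60); dimnames(G) <- list(lineIds(gp), lineIds(gp))
  assoc <- lmmAssociation(tv, gp, G)
  g <- genoMatrix(gp)
  for (v in sample(assoc$variant_id, 10)) {
    sm <- summary(lm(tv ~ g[v, names(tv)]))$coefficients
    row <- assoc[assoc$variant_id == v, ]
    expect_equal(row$effect, sm[2, 1], tolerance = 1e-10)
    expect_equal(row$se, sm[2, 2], tolerance = 1e-10)
    expect_equal(row$P, sm[2, 4], tolerance = 1e-10)
  }
})

test_that("relabeling the coded allele flips the effect and preserves P", {
  gp <- makePanel(43, L = 50, m = 30)
  set.seed(43)
  tv <- setNames(rnorm(50), lineIds(gp))
  a1 <- lmmAssociation(tv, gp, computeGRM(gp))
  flipped <- 2 - genoMatrix(gp)
  gp2 <- GenotypePanel(flipped, variantRanges(gp), lineData(gp))
  a2 <- lmmAssociation(tv, gp2, computeGRM(gp2))
  m1 <- a1[order(a1$variant_id), ]; m2 <- a2[order(a2$variant_id), ]
  expect_equal(m1$effect, -m2$effect, tolerance = 1e-9)
  expect_equal(m1$P, m2$P, tolerance = 1e-9)
})

test_that("missing genotype calls drop lines per variant only", {
  gp <- makePanel(47, L = 40, m = 20)
  geno <- genoMatrix(gp)
  geno[3, 1:5] <- NA
  gp2 <- GenotypePanel(geno, variantRanges(gp), lineData(gp))
  set.seed(47)
  tv <- setNames(rnorm(40), lineIds(gp2))
  G <- diag(40); dimnames(G) <- list(lineIds(gp2), lineIds(gp2))
  assoc <- lmmAssociation(tv, gp2, G)
  v3 <- variantIds(gp2)[3]
  expect_equal(assoc$n[assoc$variant_id == v3], 35)
  expect_true(all(assoc$n[assoc$variant_id != v3] == 40))
  # complete-case OLS oracle for the missing variant
  keep <- !is.na(geno[3, ])
  sm <- summary(lm(tv[keep] ~ geno[3, keep]))$coefficients
  expect_equal(assoc$P[assoc$variant_id == v3], sm[2, 4],
               tolerance = 1e-9)
})

test_that("GRM adjustment restores type-I control under polygenic relatedness", {
  # clustered panel: 12 clusters of 5 closely related lines
  set.seed(55)
  L <- 60; m <- 600
  cl <- rep(1:12, each = 5)
  anc <- matrix(rbinom(12 * m, 1, 0.5) * 2, nrow = m, ncol = 12)
  geno <- anc[, cl]
  flip <- matrix(rbinom(m * L, 1, 0.05) == 1, m, L)
  geno[flip] <- 2 - geno[flip]
  lines <- sprintf("l%02d", 1:L)
  dimnames(geno) <- list(paste0("v", 1:m), lines)
  poly <- geno[1:300, ]                 # polygenic background
  test_idx <- 301:600                   # null variants for testing
  beta <- rnorm(300, 0, 0.25)
  y <- drop(crossprod(poly, beta)) + rnorm(L, 0, 1)
  names(y) <- lines
  vr <- GenomicRanges::GRanges("3R", IRanges::IRanges(seq_len(m) * 100,
                                                      width = 1),
                               id = rownames(geno), type = "SNP")
  gp <- GenotypePanel(geno, vr, data.frame(wolbachia = rep(FALSE, L),
                                           row.names = lines))
  keep <- variantMAF(gp) > 0
  keep[1:300] <- FALSE
  gpt <- gp[which(keep), ]
  G <- computeGRM(gp[which(variantMAF(gp) > 0), ])
  adj <- lmmAssociation(y, gpt, G)
  I <- diag(L); dimnames(I) <- list(lines, lines)
  raw <- lmmAssociation(y, gpt, I)
  rate_adj <- mean(adj$P < 0.05)
  rate_raw <- mean(raw$P < 0.05)
  n <- nrow(adj)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n   # wide CI; correlated tests
  expect_gt(rate_raw, 0.10)                    # unadjusted scan is inflated
  expect_lt(rate_adj, rate_raw / 2)
  expect_lt(rate_adj, 0.10)
})

test_that("gene assignment respects the 1 kb window to the base pair", {
  genes <- GenomicRanges::GRanges(
    "3R", IRanges::IRanges(c(10000, 50000), c(12000, 55000)),
    gene_id = c("geneA", "geneB"))
  rec <- data.frame(
    chrom = c("3R", "3R", "3R", "3R", "3R", "X"),
    pos = c(11000,        # inside geneA
            9826,         # 174 bp upstream of geneA start
            13000,        # exactly 1000 beyond geneA end
            13001,        # 1001 beyond: not assigned
            9000,         # exactly 1000 before geneA start
            1234))        # unknown arm
  expect_warning(ann <- annotateVariants(rec, genes), "X")
  expect_equal(ann$genes,
               c("geneA", "geneA", "geneA", "", "geneA", ""))
  # overlapping windows can assign several genes
  rec2 <- data.frame(chrom = "3R", pos = 50500)
  genes2 <- GenomicRanges::GRanges(
    "3R", IRanges::IRanges(c(50000, 51000), c(50400, 52000)),
    gene_id = c("g1", "g2"))
  ann2 <- annotateVariants(rec2, genes2)
  expect_equal(ann2$genes, "g1,g2")
})

test_that("annotation equals a brute-force interval scan on random inputs", {
  set.seed(9)
  genes_df <- data.frame(chrom = sample(c("2L", "2R"), 30, TRUE),
                         start = sample.int(100000, 30))
  genes_df$end <- genes_df$start + sample.int(5000, 30)
  genes_df$gene_id <- sprintf("g%02d", 1:30)
  genes <- GenomicRanges::GRanges(genes_df$chrom,
                                  IRanges::IRanges(genes_df$start,
                                                   genes_df$end),
                                  gene_id = genes_df$gene_id)
  rec <- data.frame(chrom = sample(c("2L", "2R"), 100, TRUE),
                    pos = sample.int(110000, 100))
  ann <- annotateVariants(rec, genes, window = 750)
  brute <- bruteAssign(rec$chrom, rec$pos, genes_df, 750)
  sortcsv <- function(s) vapply(strsplit(s, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  expect_equal(sortcsv(ann$genes), sortcsv(brute))
})

test_that("GFF3 gene models are read with ids and 1-based coordinates", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "genes.gff3")
  writeLines(c(
    "##gff-version 3",
    "3R\tFlyBase\tgene\t13636500\t13638000\t.\t+\t.\tID=FBgn0001;Name=CG18012",
    "3R\tFlyBase\tmRNA\t13636500\t13638000\t.\t+\t.\tID=tr1;Parent=FBgn0001",
    "2L\tFlyBase\tgene\t5000\t9000\t.\t-\t.\tID=FBgn0002;Name=tinc"), p)
  genes <- readGeneModels(p)
  expect_length(genes, 2)
  expect_setequal(genes$gene_id, c("CG18012", "tinc"))
  expect_equal(GenomicRanges::start(genes[genes$gene_id == "CG18012"]),
               13636500)
})

test_that("trait vectors implement the four codings", {
  lt <- data.frame(line = rep(c("a", "b", "c"), each = 2),
                   sex = rep(c("F", "M"), 3), n = 6,
                   mean = c(10, 8, 12, 11, 9, 9.5),
                   sd = c(1, 1, 2, 1, 1, 1))
  lt <- lt[-2, ]                       # line a measured only in females
  tv <- traitVectors(lt, "mean")
  expect_equal(tv["a", "female"], 10)
  expect_true(is.na(tv["a", "avg"]) && is.na(tv["a", "diff"]))
  expect_equal(tv["b", "avg"], 11.5)
  expect_equal(tv["b", "diff"], 1)
  expect_equal(tv["c", "diff"], -0.5)
})
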