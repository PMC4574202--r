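test_that("one treatment vs control reduces exactly to the pooled t-test", {
  set.seed(1)
  vals <- c(rnorm(8, 10), rnorm(9, 11))
  grp <- rep(c("ctrl", "kd"), c(8, 9))
  d <- dunnettTest(vals, grp, "ctrl")
  tt <- t.test(vals[grp == "kd"], vals[grp == "ctrl"], var.equal = TRUE)
  expect_equal(d$P_adj, tt$p.value, tolerance = 1e-12)
  expect_equal(d$P_raw, tt$p.value, tolerance = 1e-12)
  expect_equal(d$estimate, unname(diff(rev(tt$estimate))),
               tolerance = 1e-12)
  expect_equal(d$t, unname(tt$statistic), tolerance = 1e-12)
})

test_that("Dunnett adjusted P agrees with an independent implementation", {
  skip_if_not_installed("multcomp")
  set.seed(2)
  vals <- c(rnorm(10, 10), rnorm(10, 10.8), rnorm(10, 9.1), rnorm(8, 10.4))
  grp <- factor(rep(c("ctrl", "g1", "g2", "g3"), c(10, 10, 10, 8)),
                levels = c("ctrl", "g1", "g2", "g3"))
  d <- dunnettTest(vals, as.character(grp), "ctrl")
  mc <- multcomp::glht(stats::aov(vals ~ grp),
                       linfct = multcomp::mcp(grp = "Dunnett"))
  ref <- summary(mc, test = multcomp::adjusted("single-step"))
  refp <- as.numeric(ref$test$pvalues)
  expect_equal(d$P_adj[match(c("g1", "g2", "g3"), d$group)], refp,
               tolerance = 3e-3)
})

test_that("Dunnett adjustment is monotone and location-shift invariant", {
  set.seed(3)
  vals <- c(rnorm(6, 0), rnorm(6, 0.5), rnorm(6, -0.7), rnorm(6, 1.2))
  grp <- rep(c("c", "a", "b", "d"), each = 6)
  d <- dunnettTest(vals, grp, "c")
  expect_true(all(d$P_adj >= d$P_raw - 1e-12))
  d2 <- dunnettTest(vals + 100, grp, "c")
  expect_equal(d$P_adj, d2$P_adj, tolerance = 1e-12)
  expect_equal(d$estimate, d2$estimate, tolerance = 1e-12)
})

test_that("pairwise Levene matches a brute-force deviation ANOVA", {
  x <- c(1, 2, 3, 4); y <- c(0, 3, 6, 9)
  res <- pairwiseLevene(x, y)
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- rep(c("a", "b"), each = 4)
  bf <- bruteOnewayF(z, g)
  expect_equal(res$F, bf$F, tolerance = 1e-12)
  expect_equal(res$P, bf$P, tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 6)
  # identical samples
  r0 <- pairwiseLevene(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$F, 0); expect_equal(r0$P, 1)
})

test_that("pairwise Levene power is reproducible across independent seed batches", {
  sim_batch <- function(seeds, inflate) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      pairwiseLevene(rnorm(12, 0, 1), rnorm(12, 0, sqrt(inflate)))$P < 0.05
    }, logical(1)))
  }
  p1 <- sim_batch(1:150, 3)
  p2 <- sim_batch(151:300, 3)
  se <- sqrt(p1 * (1 - p1) / 150 + p2 * (1 - p2) / 150)
  expect_lt(abs(p1 - p2), 3 * se)
  expect_gt(p1, 0.3)   # 3x variance inflation is detectable at n = 12
})

test_that("SNP-cross contrast uses genotype means, flips under relabeling", {
  set.seed(4)
  dat <- data.frame(
    allele_class = rep(c("major", "minor"), each = 55),
    genotype = paste0("g", rep(1:10, each = 11)),
    sex = "F",
    adjusted_ul = rnorm(110, 10) +
      rep(c(0.4, 0), each = 55) + rep(rnorm(10, 0, 0.3), each = 11))
  res <- snpCrossTest(dat)
  expect_equal(res$unit, "genotype")
  expect_equal(res$n_major, 5); expect_equal(res$n_minor, 5)
  expect_equal(res$df, 8)
  # manual genotype-mean oracle
  gm <- tapply(dat$adjusted_ul, dat$genotype, mean)
  cls <- tapply(dat$allele_class, dat$genotype, unique)
  tt <- t.test(gm[cls == "major"], gm[cls == "minor"], var.equal = TRUE)
  expect_equal(res$P, tt$p.value, tolerance = 1e-12)
  expect_equal(res$effect, unname(tt$estimate[1] - tt$estimate[2]),
               tolerance = 1e-12)
  # swapping classes flips the sign, preserves P
  dat2 <- dat
  dat2$allele_class <- ifelse(dat$allele_class == "major", "minor", "major")
  res2 <- snpCrossTest(dat2, major = "major")
  expect_equal(res2$effect, -res$effect, tolerance = 1e-12)
  expect_equal(res2$P, res$P, tolerance = 1e-12)
})

test_that("identical class distributions give zero effect and P near 1", {
  vals <- rep(c(9, 10, 11), 10)
  dat <- data.frame(allele_class = rep(c("major", "minor"), each = 15),
                    genotype = paste0("g", rep(1:6, each = 5)),
                    sex = "M", adjusted_ul = vals)
  res <- snpCrossTest(dat)
  expect_equal(res$effect, 0, tolerance = 1e-12)
  expect_gt(res$P, 0.99)
})

test_that("single-genotype classes fall back to vial units with a warning", {
  dat <- data.frame(allele_class = rep(c("major", "minor"), each = 6),
                    genotype = rep(c("g1", "g2"), each = 6),
                    sex = "F", adjusted_ul = rnorm(12))
  expect_warning(res <- snpCrossTest(dat), "single F1 genotype")
  expect_equal(res$unit, "vial")
})

test_that("a female-specific cross effect shows female power and male type-I control", {
  # 5 F1 genotypes x 11 vials per class; genotype SD 0.2, vial SD 0.5
  simCross <- function(seed, eff) {
    set.seed(seed)
    g <- rep(1:10, each = 11)
    cls <- rep(c("major", "minor"), each = 55)
    data.frame(allele_class = cls, genotype = paste0("g", g), sex = "F",
               adjusted_ul = rnorm(110, 10, 0.5) +
                 rep(rnorm(10, 0, 0.2), each = 11) +
                 ifelse(cls == "major", eff, 0))
  }
  nsim <- 120
  pf_ <- vapply(1:nsim, function(s)
    snpCrossTest(simCross(s, 0.36))$P < 0.05, logical(1))
  pm <- vapply(1:nsim, function(s)
    snpCrossTest(simCross(s + nsim, 0))$P < 0.05, logical(1))
  # male-null arm at the nominal rate
  expect_lt(abs(mean(pm) - 0.05), 3 * sqrt(0.05 * 0.95 / nsim))
  # female arm: power well above the nominal rate
  expect_gt(mean(pf_), 0.35)
})

test_that("permutation null reproduces the t-test P on a toy cross", {
  set.seed(6)
  gm <- c(rnorm(5, 10.5, 0.3), rnorm(5, 10, 0.3))   # genotype means
  cls <- rep(c("major", "minor"), each = 5)
  tobs <- abs(t.test(gm[cls == "major"], gm[cls == "minor"],
                     var.equal = TRUE)$statistic)
  perm <- mean(replicate(20000, {
    p <- sample(cls)
    abs(t.test(gm[p == "major"], gm[p == "minor"],
               var.equal = TRUE)$statistic) >= tobs - 1e-12
  }))
  pt_ <- t.test(gm[cls == "major"], gm[cls == "minor"],
                var.equal = TRUE)$p.value
  expect_lt(abs(pt_ - perm), 3 * sqrt(perm * (1 - perm) / 20000) + 5e-3)
})

test_that("effect attenuation report is coherent", {
  b <- beavisComparison(1.37, 0.36)
  expect_equal(b$ratio, 0.36 / 1.37, tolerance = 1e-12)
  expect_true(b$direction_replicated)
  expect_equal(beavisComparison(2, 2)$ratio, 1)
  expect_warning(bd <- beavisComparison(1.5, -0.2), "direction")
  expect_false(bd$direction_replicated)
  expect_error(beavisComparison(0, 1), "nonzero")
})

test_that("all validation tests are invariant to a common location shift", {
  set.seed(8)
  x <- rnorm(10); y <- rnorm(10, 0, 2)
  r1 <- pairwiseLevene(x, y)
  r2 <- pairwiseLevene(x + 55, y + 55)
  expect_equal(r1$F, r2$F, tolerance = 1e-9)
  dat <- data.frame(allele_class = rep(c("major", "minor"), each = 10),
                    genotype = paste0("g", rep(1:4, each = 5)),
                    sex = "F", adjusted_ul = rnorm(20))
  s1 <- snpCrossTest(dat)
  dat$adjusted_ul <- dat$adjusted_ul + 7
  s2 <- snpCrossTest(dat)
  expect_equal(s1$P, s2$P, tolerance = 1e-9)
  expect_equal(s1$effect, s2$effect, tolerance = 1e-9)
})
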