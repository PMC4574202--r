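# nodes and weights for Gauss-Legendre quadrature on [a, b], via
# Golub-Welsch on the Jacobi matrix of the Legendre recurrence
gaussLegendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

# Gauss-Hermite (physicists' weight exp(-x^2)), rescaled for N(0,1)
gaussHermiteNorm <- function(n) {
  i <- seq_len(n - 1)
  beta <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = sqrt(2) * e$values, w = e$vectors[1, ]^2)  # weights sum to 1
}

# P(max_i |T_i| <= q) for the Dunnett statistic: T_i = (lam_i Z0 +
# sqrt(1 - lam_i^2) e_i) / S with S^2 ~ chisq_nu / nu.  The one-factor
# structure of the correlation matrix makes this a smooth 2-D integral,
# evaluated by deterministic quadrature.
dunnettQuadNodes <- function(nu, nodes = c(48L, 96L)) {
  gh <- gaussHermiteNorm(nodes[1])
  slo <- sqrt(stats::qchisq(1e-12, nu) / nu)
  shi <- sqrt(stats::qchisq(1 - 1e-12, nu) / nu)
  gl <- gaussLegendre(nodes[2], slo, shi)
  list(z = gh$x, wz = gh$w, s = gl$x,
       ws = gl$w * stats::dchisq(nu * gl$x^2, nu) * 2 * nu * gl$x)
}

dunnettCentralProb <- function(q, lam, nu, nodes = c(48L, 96L),
                               grid = NULL) {
  if (is.null(grid)) grid <- dunnettQuadNodes(nu, nodes)
  zs <- outer(grid$z, rep(1, length(grid$s)))       # z x s grids
  qs <- outer(rep(1, length(grid$z)), q * grid$s)
  pr <- 1
  tab <- table(lam)                 # balanced groups share one factor
  for (i in seq_along(tab)) {
    li <- as.numeric(names(tab)[i])
    ci <- sqrt(1 - li^2)
    pr <- pr * (stats::pnorm((qs - li * zs) / ci) -
                  stats::pnorm((-qs - li * zs) / ci))^tab[[i]]
  }
  min(1, max(0, sum(grid$wz * pr %*% grid$ws)))
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares each treatment group's mean with the control using the
#' Dunnett procedure: two-sided adjusted P-values are tail probabilities
#' of the maximum absolute component of a multivariate t vector with
#' pooled-variance df and correlation
#' `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))` (the equicorrelated
#' 1/2 case when balanced).  That correlation matrix always has a
#' one-factor structure, so the tail probability is evaluated as an exact
#' two-dimensional integral by deterministic Gauss-Hermite x
#' Gauss-Legendre quadrature (balanced and unbalanced designs alike);
#' the one-comparison case reduces analytically to the pooled two-sample
#' t-test.
#'
#' @param values numeric response (e.g. adjusted per-fly intake).
#' @param group group labels, one per value.
#' @param control label of the control group.
#' @param nodes integer length 2: quadrature nodes for the common factor
#'   and the pooled-SD scale (defaults give ~1e-8 accuracy).
#' @return data.frame of class `cafeDunnett`: `group`, `n`, `estimate`
#'   (group mean minus control mean), `t`, `df`, `P_raw` (unadjusted
#'   two-sample pooled t), `P_adj` (Dunnett-adjusted).
#' @export
dunnettTest <- function(values, group, control, nodes = c(48L, 96L)) {
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' not found")
  ok <- !is.na(values)
  values <- values[ok]; group <- group[ok]
  n <- table(group)
  if (any(n < 2)) stop("every group needs >= 2 observations")
  means <- tapply(values, group, mean)
  k <- length(n) - 1L
  N <- length(values)
  nu <- N - length(n)
  s2 <- sum((values - means[group])^2) / nu
  if (s2 <= 0) stop("zero pooled variance; comparisons undefined")
  trt <- setdiff(names(n), control)
  n0 <- n[[control]]
  ni <- as.numeric(n[trt])
  est <- as.numeric(means[trt] - means[[control]])
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
  praw <- 2 * pt(-abs(tstat), nu)
  lam <- sqrt(ni / (ni + n0))
  grid <- if (k > 1) dunnettQuadNodes(nu, nodes)
  padj <- if (k == 1) praw else vapply(seq_len(k), function(i) {
    1 - dunnettCentralProb(abs(tstat[i]), lam, nu, grid = grid)
  }, numeric(1))
  out <- data.frame(group = trt, n = ni, estimate = est, t = tstat,
                    df = nu, P_raw = praw, P_adj = pmax(padj, praw),
                    stringsAsFactors = FALSE)
  attr(out, "control") <- control
  class(out) <- c("cafeDunnett", "data.frame")
  out
}

#' Two-group (pairwise) Levene test of unequal variances
#'
#' The two-sample case of the Levene procedure: absolute deviations from
#' each group's mean, compared by one-way ANOVA with k = 2.
#'
#' @param x,y numeric samples (e.g. knockdown and control vials).
#' @param labels optional group labels for the report.
#' @return list of class `cafeVarHet` (same shape as
#'   [varianceHeterogeneityTest()]).
#' @export
pairwiseLevene <- function(x, y, labels = c("group1", "group2")) {
  if (length(x) < 2 || length(y) < 2)
    stop("every group needs >= 2 observations")
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- rep(labels, c(length(x), length(y)))
  ow <- onewayF(z, g)
  structure(list(test = "levene_pairwise", sex = "all", F = ow$F,
                 df1 = ow$df1, df2 = ow$df2, P = ow$P, n_lines = 2L),
            class = "cafeVarHet")
}

#' Major/minor allele contrast from an F1 SNP-cross design
#'
#' Tests whether outbred F1 genotypes homozygous for the major allele of a
#' focal variant differ from those homozygous for the minor allele.  The
#' experimental unit is the F1 genotype: vial values are averaged per
#' genotype and the two allele classes compared with a pooled-variance
#' two-sample t-test, separately per sex.  `effect` is the major-class
#' mean minus the minor-class mean.  If either class has a single
#' genotype the test falls back to vial-level units with a warning and a
#' flag; vial-level units can also be requested directly.
#'
#' @param data data.frame with columns `allele_class` (exactly two
#'   levels, e.g. major/minor), `genotype`, `sex`, and the value column.
#' @param major label of the major allele class (default the class named
#'   `"major"`, else the first level).
#' @param unit `"genotype"` (default) or `"vial"`.
#' @param value name of the intake column.
#' @return data.frame of class `cafeSnpCross`: `sex`, `effect`, `t`,
#'   `df`, `P`, `n_major`, `n_minor`, `unit`.
#' @export
snpCrossTest <- function(data, major = NULL, unit = c("genotype", "vial"),
                         value = "adjusted_ul") {
  unit <- match.arg(unit)
  stopifnot_cols(data, c("allele_class", "genotype", "sex", value),
                 "SNP-cross table")
  classes <- unique(as.character(data$allele_class))
  if (length(classes) != 2)
    stop("need exactly two allele classes; got: ",
         paste(classes, collapse = ", "))
  major <- major %||% if ("major" %in% classes) "major" else classes[1]
  minor <- setdiff(classes, major)
  res <- lapply(unique(data$sex), function(s) {
    sub <- data[data$sex == s, ]
    u <- unit
    ngen <- tapply(sub$genotype, sub$allele_class,
                   function(g) length(unique(g)))
    if (u == "genotype" && any(ngen < 2)) {
      warning("allele class with a single F1 genotype; ",
              "falling back to vial-level units for sex ", s)
      u <- "vial"
    }
    if (u == "genotype") {
      gm <- aggregate(sub[[value]],
                      by = list(class = sub$allele_class,
                                genotype = sub$genotype), FUN = mean)
      xa <- gm$x[gm$class == major]; xb <- gm$x[gm$class == minor]
    } else {
      xa <- sub[[value]][sub$allele_class == major]
      xb <- sub[[value]][sub$allele_class == minor]
    }
    tt <- t.test(xa, xb, var.equal = TRUE)
    data.frame(sex = s, effect = mean(xa) - mean(xb),
               t = unname(tt$statistic), df = unname(tt$parameter),
               P = tt$p.value, n_major = length(xa), n_minor = length(xb),
               unit = u, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "major") <- major
  class(out) <- c("cafeSnpCross", "data.frame")
  out
}

#' Effect-size attenuation report (winner's-curse comparison)
#'
#' Compares the effect size estimated in the association scan with the
#' effect measured in an independent validation cross.  Because scans
#' report only loci passing a significance threshold, scan effects are
#' upward-biased (the Beavis effect); the validated/scan ratio quantifies
#' the attenuation.  Both inputs must be on the same allele-contrast
#' convention.
#'
#' @param gwa_effect effect size from the association scan (uL).
#' @param validated_effect effect size from the validation experiment
#'   (uL), same contrast.
#' @return list of class `cafeBeavis`: `gwa_effect`, `validated_effect`,
#'   `ratio` (validated / scan), `direction_replicated`.
#' @examples
#' beavisComparison(1.37, 0.36)  # ratio ~ 0.263
#' @export
beavisComparison <- function(gwa_effect, validated_effect) {
  if (!is.finite(gwa_effect) || gwa_effect == 0)
    stop("scan effect must be nonzero")
  same_dir <- sign(gwa_effect) == sign(validated_effect) &&
    validated_effect != 0
  if (!same_dir) warning("direction not replicated")
  structure(list(gwa_effect = gwa_effect,
                 validated_effect = validated_effect,
                 ratio = validated_effect / gwa_effect,
                 direction_replicated = same_dir,
                 contrast = "per-allele (same convention for both inputs)"),
            class = "cafeBeavis")
}

#' @export
print.cafeBeavis <- function(x, ...) {
  cat(sprintf("effect attenuation: scan %.3f uL vs validated %.3f uL (ratio %.3f)%s\n",
              x$gwa_effect, x$validated_effect, x$ratio,
              if (x$direction_replicated) "" else "  [direction not replicated]"))
  invisible(x)
}
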