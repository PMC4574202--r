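# Independent oracle implementations, deliberately naive: dense-matrix
# restricted likelihood, closed-form balanced ANOVA estimators, brute-force
# one-way ANOVA.  These never call the package's own solvers.

# -2 * restricted log-likelihood (up to a theta-independent constant) for
# y = X beta + sum_k Z_k u_k + e, computed with dense n x n algebra.
denseRemlM2LL <- function(y, X, Zs, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Zs))
    V <- V + theta[k] * tcrossprod(Zs[[k]])
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(r) %*% Vi %*% r)
}

# Closed-form ANOVA/moment estimators for balanced designs (method of
# moments on expected mean squares, truncated at zero).
balancedOneWayMoments <- function(y, line) {
  line <- factor(line)
  n <- unique(tabulate(line))
  stopifnot(length(n) == 1)
  L <- nlevels(line)
  gm <- tapply(y, line, mean)
  msl <- n * sum((gm - mean(y))^2) / (L - 1)
  mse <- sum((y - gm[line])^2) / (L * (n - 1))
  c(sigma2_line = max((msl - mse) / n, 0), sigma2_error = mse)
}

balancedTwoWayMoments <- function(y, line, sex) {
  line <- factor(line); sex <- factor(sex)
  L <- nlevels(line); S <- nlevels(sex)
  cell <- interaction(line, sex)
  n <- unique(tabulate(cell))
  stopifnot(length(n) == 1, S == 2)
  ybar <- mean(y)
  ml <- tapply(y, line, mean); ms <- tapply(y, sex, mean)
  mc <- tapply(y, cell, mean)
  ssl <- S * n * sum((ml - ybar)^2)
  sscell <- n * sum((mc - ybar)^2)
  sss <- L * n * sum((ms - ybar)^2)
  sssl <- sscell - ssl - sss
  mse <- sum((y - mc[cell])^2) / (L * S * (n - 1))
  msl <- ssl / (L - 1)
  mssl <- sssl / ((L - 1) * (S - 1))
  c(sigma2_line = max((msl - mssl) / (S * n), 0),
    sigma2_sexline = max((mssl - mse) / n, 0),
    sigma2_error = mse)
}

# brute-force one-way ANOVA F via lm/anova (base route, independent of the
# package's group-sum formulas)
bruteOnewayF <- function(z, g) {
  a <- anova(lm(z ~ factor(g)))
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       P = a$`Pr(>F)`[1])
}

# brute-force interval assignment for variant annotation
bruteAssign <- function(chrom, pos, genes_df, window) {
  vapply(seq_along(pos), function(i) {
    hit <- genes_df$chrom == chrom[i] &
      pos[i] >= genes_df$start - window & pos[i] <= genes_df$end + window
    paste(unique(genes_df$gene_id[hit]), collapse = ",")
  }, character(1))
}
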