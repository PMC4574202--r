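# internal helpers shared across modules

#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats rnorm rbinom runif sd var aggregate pf pt qnorm setNames
#'   coef lm anova resid fitted optimHess nlminb cor cov complete.cases
#'   t.test cor.test alias model.matrix p.adjust ks.test median quantile
#'   drop1 contr.sum rchisq
NULL

# Deterministic sub-seed for a named random-number stream, so that e.g.
# genotype draws never perturb phenotype draws.  Kept below 2^31.
subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# one-way ANOVA of a response across groups, computed from group sums;
# the work-horse behind the Levene-family statistics.
onewayF <- function(z, g) {
  g <- factor(g)
  n <- tabulate(g)
  k <- nlevels(g)
  N <- length(z)
  gm <- rowsum(z, g)[, 1] / n
  grand <- mean(z)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum((z - gm[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- N - k
  if (df1 < 1L || df2 < 1L) stop("need >=2 groups and residual df >= 1")
  msb <- ssb / df1
  msw <- ssw / df2
  Fv <- if (msw == 0) ifelse(msb == 0, 0, Inf) else msb / msw
  P <- if (msw == 0 && msb == 0) 1 else pf(Fv, df1, df2, lower.tail = FALSE)
  list(F = Fv, df1 = df1, df2 = df2, P = P, msb = msb, msw = msw)
}
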