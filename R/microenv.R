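#' Levene / Brown-Forsythe test for heterogeneity of within-line variance
#'
#' Transforms each vial to its absolute deviation from the line center
#' (`center = "mean"` gives Levene's test, `center = "median"` the
#' Brown-Forsythe variant; medians use the midpoint convention for even
#' counts) and runs a one-way ANOVA of the deviations across lines.  A
#' significant F indicates genetic heterogeneity of micro-environmental
#' variance.  Lines with a single vial are dropped with a warning.
#'
#' @param vials vial records with `line`, `sex` and the value column.
#' @param sex optional `"F"`/`"M"` filter; default uses all rows (callers
#'   normally test each sex separately).
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`
#'   (Levene).
#' @param value name of the per-fly intake column.
#' @return list of class `cafeVarHet`: `test`, `sex`, `F`, `df1` (k - 1),
#'   `df2` (N - k), `P`, `n_lines`.
#' @examples
#' v <- data.frame(line = rep(c("a", "b"), each = 3), sex = "F",
#'                 adjusted_ul = c(1, 2, 3, 1, 2, 3))
#' varianceHeterogeneityTest(v, center = "mean")  # identical spreads: F = 0
#' @export
varianceHeterogeneityTest <- function(vials, sex = NULL,
                                      center = c("median", "mean"),
                                      value = "adjusted_ul") {
  center <- match.arg(center)
  stopifnot_cols(vials, c("line", value), "vial table")
  if (!is.null(sex)) vials <- vials[vials$sex == sex, , drop = FALSE]
  y <- vials[[value]]
  g <- as.character(vials$line)
  cnt <- table(g)
  if (any(cnt < 2)) {
    warning(sprintf("dropping %d line(s) with a single vial",
                    sum(cnt < 2)))
    keep <- g %in% names(cnt)[cnt >= 2]
    y <- y[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2) stop("need >= 2 lines with >= 2 vials")
  ctr <- if (center == "median") tapply(y, g, median) else tapply(y, g, mean)
  z <- abs(y - ctr[g])
  ow <- onewayF(z, g)
  structure(list(test = if (center == "median") "brown_forsythe"
                        else "levene",
                 sex = sex %||% "all", F = ow$F, df1 = ow$df1,
                 df2 = ow$df2, P = ow$P, n_lines = length(unique(g))),
            class = "cafeVarHet")
}

#' @export
print.cafeVarHet <- function(x, ...) {
  cat(sprintf("%s test (%s): F(%d, %d) = %.4f, P = %.4g [%d lines]\n",
              x$test, x$sex, x$df1, x$df2, x$F, x$P, x$n_lines))
  invisible(x)
}

#' Per-line CV_E values suitable for variance GWAS
#'
#' Extracts `CV_E = 100 * SD / mean` (percent) per line and sex from a
#' line phenotype table, excluding cells whose mean is not positive or
#' whose replicate count is below `min_reps`; exclusions are listed with
#' reasons in `attr(, "excluded")`.
#'
#' @param line_table output of [summarizeLines()].
#' @param min_reps minimum replicate vials (default 3).
#' @return data.frame `line`, `sex`, `n`, `cv_e`; excluded cells in
#'   `attr(, "excluded")` (`line`, `sex`, `reason`).
#' @export
cveTable <- function(line_table, min_reps = 3L) {
  stopifnot_cols(line_table, c("line", "sex", "n", "mean", "sd"),
                 "line table")
  reason <- rep(NA_character_, nrow(line_table))
  reason[line_table$n < min_reps] <- "too few replicates"
  reason[is.na(reason) & !(line_table$mean > 0)] <- "non-positive mean"
  keep <- is.na(reason)
  out <- line_table[keep, c("line", "sex", "n")]
  out$cv_e <- 100 * line_table$sd[keep] / line_table$mean[keep]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    line = line_table$line[!keep], sex = line_table$sex[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairs with missing values are dropped.  The two-sided P comes from the
#' t reference distribution with n - 2 df and the 95% CI from the Fisher
#' transform, `tanh(atanh(r) +/- z_0.975 / sqrt(n - 3))` (delegated to
#' [stats::cor.test]).
#'
#' @param x,y numeric vectors of per-line values (same length).
#' @param labels optional length-2 character: trait pair labels.
#' @return list of class `cafeCorr`: `labels`, `n`, `r`, `P`, `ci`
#'   (length 2), `r_squared`.
#' @export
pearsonCorrelation <- function(x, y, labels = c("x", "y")) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in ", paste(labels[c(sd(x) == 0, sd(y) == 0)],
                                    collapse = " and "))
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  structure(list(labels = labels, n = n, r = unname(ct$estimate),
                 P = ct$p.value, ci = as.numeric(ct$conf.int),
                 r_squared = unname(ct$estimate)^2),
            class = "cafeCorr")
}

#' @export
print.cafeCorr <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s) = %.3f (n = %d), P = %.4g, 95%% CI [%.3f, %.3f]\n",
              x$labels[1], x$labels[2], x$r, x$n, x$P, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Mean-variance association and cross-sex CV_E correlation
#'
#' For each sex, correlates line means with line CV_E values (a negative
#' correlation indicates that high-intake lines are relatively less
#' variable), reporting r-squared as "variance explained"; also
#' correlates CV_E between the sexes over lines with both measured.
#'
#' @param line_table output of [summarizeLines()].
#' @param min_reps minimum replicates for CV_E cells (see [cveTable()]).
#' @return list of class `cafeMeanVar` with `cafeCorr` elements
#'   `mean_cve_female`, `mean_cve_male`, `cve_cross_sex`.
#' @export
meanVarianceAssociation <- function(line_table, min_reps = 3L) {
  cv <- cveTable(line_table, min_reps = min_reps)
  key <- paste(line_table$line, line_table$sex)
  mu <- setNames(line_table$mean, key)
  res <- list()
  for (s in c("F", "M")) {
    sub <- cv[cv$sex == s, ]
    nm <- paste0("mean_cve_", if (s == "F") "female" else "male")
    res[[nm]] <- pearsonCorrelation(mu[paste(sub$line, s)], sub$cv_e,
                                    labels = c(paste0("mean_", s),
                                               paste0("cv_e_", s)))
  }
  wf <- cv[cv$sex == "F", c("line", "cv_e")]
  wm <- cv[cv$sex == "M", c("line", "cv_e")]
  mrg <- merge(wf, wm, by = "line", suffixes = c("_F", "_M"))
  res$cve_cross_sex <- pearsonCorrelation(mrg$cv_e_F, mrg$cv_e_M,
                                          labels = c("cv_e_F", "cv_e_M"))
  class(res) <- "cafeMeanVar"
  res
}

#' @export
print.cafeMeanVar <- function(x, ...) {
  for (el in unclass(x)) print(el)
  invisible(x)
}

#' Correlations of line means with other quantitative traits
#'
#' Pearson correlations (with unadjusted P, mirroring the nominal
#' reporting convention for panel-wide trait scans) of per-line food
#' intake values against each column of a line x trait table, plus a
#' Benjamini-Hochberg adjusted column for convenience.
#'
#' @param values named numeric vector of per-line phenotype values (names
#'   are line ids).
#' @param traits data.frame of other traits, one row per line; rownames
#'   or a `line` column identify lines.
#' @return data.frame: `trait`, `n`, `r`, `P`, `ci_lo`, `ci_hi`, `P_bh`.
#' @export
traitCorrelations <- function(values, traits) {
  if ("line" %in% names(traits)) {
    rownames(traits) <- traits$line
    traits$line <- NULL
  }
  lines <- intersect(names(values), rownames(traits))
  if (length(lines) < 4) stop("fewer than 4 lines shared with trait table")
  out <- do.call(rbind, lapply(names(traits), function(tr) {
    res <- tryCatch(pearsonCorrelation(values[lines], traits[lines, tr],
                                       labels = c("intake", tr)),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(trait = tr, n = res$n, r = res$r, P = res$P,
               ci_lo = res$ci[1], ci_hi = res$ci[2],
               stringsAsFactors = FALSE)
  }))
  out$P_bh <- p.adjust(out$P, method = "BH")
  out
}
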