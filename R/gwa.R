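#' Filter variants by minor allele frequency and missingness
#'
#' Retains variants with MAF at or above `maf_min` (inclusive boundary,
#' matching the conventional "MAF >= 0.05" panel filter), excluding
#' monomorphic variants and those with a missing-call fraction above
#' `max_missing`.
#'
#' @param panel a [GenotypePanel-class].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param max_missing maximum fraction of missing calls (default 0.2).
#' @return the filtered [GenotypePanel-class]; removal counts are messaged.
#' @export
filterVariants <- function(panel, maf_min = 0.05, max_missing = 0.2) {
  maf <- variantMAF(panel)
  miss <- variantMissingness(panel)
  keep <- maf >= maf_min & maf > 0 & miss <= max_missing
  message(sprintf(
    "filterVariants: kept %d / %d (%d below MAF %.3g, %d above missingness %.3g)",
    sum(keep), length(keep), sum(maf < maf_min | maf == 0), maf_min,
    sum(miss > max_missing), max_missing))
  if (!any(keep)) stop("no variants pass the MAF/missingness filter")
  panel[which(keep), ]
}

#' Line-level trait vectors for the four association codings
#'
#' From the per-line summaries, builds the four trait codings used for
#' association: females, males, the sex average `(F + M)/2` and the sex
#' difference `F - M` (equivalent to the sex-by-line interaction); the
#' latter two are defined only for lines measured in both sexes.
#'
#' @param line_table output of [summarizeLines()].
#' @param trait `"mean"` or `"cv_e"`.
#' @param min_reps replicate threshold applied to CV_E cells (see
#'   [cveTable()]).
#' @return data.frame with rownames = line ids and columns `female`,
#'   `male`, `avg`, `diff`.
#' @export
traitVectors <- function(line_table, trait = c("mean", "cv_e"),
                         min_reps = 3L) {
  trait <- match.arg(trait)
  tab <- if (trait == "mean") {
    line_table[, c("line", "sex", "mean")]
  } else {
    cv <- cveTable(line_table, min_reps = min_reps)
    data.frame(line = cv$line, sex = cv$sex, mean = cv$cv_e)
  }
  lines <- sort(unique(tab$line))
  fv <- setNames(rep(NA_real_, length(lines)), lines)
  mv <- fv
  f <- tab[tab$sex == "F", ]; m <- tab[tab$sex == "M", ]
  fv[f$line] <- f$mean; mv[m$line] <- m$mean
  data.frame(female = fv, male = mv, avg = (fv + mv) / 2, diff = fv - mv,
             row.names = lines)
}

#' Test and remove covariate effects before association
#'
#' Fits a linear model of the line-level trait on Wolbachia infection and
#' inversion karyotypes, reports the per-term marginal (Type III) F tests,
#' and returns the adjusted trait (residuals plus grand mean).  Lines
#' missing any covariate are dropped (and listed); covariates constant
#' across the remaining lines are dropped from the model (identity
#' adjustment when all are constant); aliased (confounded) covariates are
#' an error naming the terms.
#'
#' @param trait named numeric vector of line-level values (names = line
#'   ids); `NA` entries are dropped.
#' @param panel [GenotypePanel-class] supplying the covariates.
#' @param covariates character; which `lineData` columns to use (default
#'   all).
#' @return list of class `cafeCovAdj`: `anova` (term, df, F, P),
#'   `adjusted` (named vector), `dropped_lines`, `dropped_terms`,
#'   `model`.
#' @export
covariateAdjust <- function(trait, panel, covariates = NULL) {
  ld <- as.data.frame(lineData(panel))
  covariates <- covariates %||% colnames(ld)
  miss <- setdiff(covariates, colnames(ld))
  if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  trait <- trait[!is.na(trait)]
  lines <- intersect(names(trait), rownames(ld))
  df <- data.frame(y = trait[lines], ld[lines, covariates, drop = FALSE])
  ok <- complete.cases(df)
  dropped_lines <- lines[!ok]
  if (length(dropped_lines))
    message("covariateAdjust: dropping ", length(dropped_lines),
            " line(s) with missing covariates")
  df <- df[ok, , drop = FALSE]
  constant <- vapply(df[-1], function(v) length(unique(v)) < 2, logical(1))
  dropped_terms <- covariates[constant]
  if (length(dropped_terms))
    message("covariateAdjust: dropping constant covariate(s): ",
            paste(dropped_terms, collapse = ", "))
  terms <- covariates[!constant]
  if (!length(terms)) {
    adj <- setNames(df$y, rownames(df))
    return(structure(list(anova = NULL, adjusted = adj,
                          dropped_lines = dropped_lines,
                          dropped_terms = dropped_terms, model = NULL),
                     class = "cafeCovAdj"))
  }
  mod <- lm(stats::reformulate(terms, response = "y"), data = df)
  if (any(is.na(coef(mod)))) {
    al <- names(coef(mod))[is.na(coef(mod))]
    stop("confounded (aliased) covariate term(s): ",
         paste(al, collapse = ", "))
  }
  d1 <- drop1(mod, test = "F")   # marginal SS == Type III (no interactions)
  at <- data.frame(term = rownames(d1)[-1], df = d1$Df[-1],
                   F = d1$`F value`[-1], P = d1$`Pr(>F)`[-1],
                   stringsAsFactors = FALSE)
  adj <- setNames(resid(mod) + mean(df$y), rownames(df))
  structure(list(anova = at, adjusted = adj, dropped_lines = dropped_lines,
                 dropped_terms = dropped_terms, model = mod),
            class = "cafeCovAdj")
}

#' @export
print.cafeCovAdj <- function(x, ...) {
  cat("covariate adjustment of line-level trait\n")
  if (is.null(x$anova)) cat("  (no varying covariates; identity adjustment)\n")
  else print(x$anova, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Genomic relatedness matrix from centered genotypes
#'
#' `G = Xc Xc' / (m * vbar)` where `Xc` is the lines x variants genotype
#' matrix with each variant centered on its mean (missing calls imputed to
#' the variant mean), `m` the variant count and `vbar` the mean per-variant
#' variance.  The construction is symmetric positive semi-definite with
#' diagonal mean close to 1.
#'
#' @param panel a (normally MAF-filtered) [GenotypePanel-class].
#' @return lines x lines numeric matrix with line-id dimnames.
#' @export
computeGRM <- function(panel) {
  X <- t(genoMatrix(panel))
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- cm[j]
  }
  Xc <- sweep(X, 2, colMeans(X))
  n <- nrow(Xc)
  vbar <- mean(colSums(Xc^2) / (n - 1))
  if (vbar <= 0) stop("all variants are monomorphic; GRM undefined")
  G <- tcrossprod(Xc) / (ncol(Xc) * vbar)
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

# EMMA-style null REML for y = 1*mu + g + e, Var = vg*G + ve*I,
# parameterized by delta = ve/vg on the eigenbasis of G.
nullREML <- function(y, G) {
  n <- length(y)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  p <- 1L
  prof <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lam + d)
    xwx <- sum(xt^2 * w)
    beta <- sum(xt * yt * w) / xwx
    r <- yt - xt * beta
    rvr <- sum(r^2 * w)
    vg <- rvr / (n - p)
    (n - p) * (1 + log(2 * pi * vg)) + sum(log(lam + d)) + log(xwx)
  }
  op <- stats::optimize(prof, c(-12, 12), tol = 1e-9)
  d <- exp(op$minimum)
  w <- 1 / (lam + d)
  xwx <- sum(xt^2 * w)
  beta <- sum(xt * yt * w) / xwx
  rvr <- sum((yt - xt * beta)^2 * w)
  vg <- rvr / (n - p)
  list(vg = vg, ve = vg * d, delta = d, U = U, lambda = lam,
       minus2ll = op$objective, converged = is.finite(op$objective))
}

#' Single-variant mixed-model association scan
#'
#' Two-step association: the polygenic and residual variance components of
#' the null model `y = mu + g + e`, `Var(g) = vg * GRM`, are estimated
#' once by REML; each variant is then tested by generalized least squares
#' under the fixed null covariance (the population-parameters-previously-
#' estimated scheme), with a per-variant residual scale so that the test
#' statistic is exactly t-distributed with n - 2 df when the covariance is
#' proportional to the truth.  With `grm = identity` the scan reduces
#' exactly to ordinary least squares.  Lines with missing genotype calls
#' are dropped for that variant only.
#'
#' The reported `effect` is the slope on the 0/2 homozygous coding, i.e.
#' the per-allele substitution effect; homozygous line classes differ by
#' `2 * effect`.
#'
#' @param trait named numeric vector of (covariate-adjusted) line values.
#' @param panel a filtered [GenotypePanel-class].
#' @param grm relatedness matrix from [computeGRM()]; identity behaviour
#'   when `NULL` is *not* assumed -- the GRM is computed from `panel`.
#' @param top_p nominal reporting threshold (default `1e-5`).
#' @param bonferroni_alpha family-wise alpha for the Bonferroni flag
#'   (default 0.05, i.e. `0.05 / n_variants`).
#' @param min_lines warn when fewer lines than this enter the scan.
#' @return data.frame sorted by P: `variant_id`, `chrom`, `pos`, `type`,
#'   `maf`, `n`, `effect`, `se`, `t`, `P`, `top`, `bonferroni`; the null
#'   variance-component fit is in `attr(, "null_fit")`.
#' @export
lmmAssociation <- function(trait, panel, grm = NULL, top_p = 1e-5,
                           bonferroni_alpha = 0.05, min_lines = 30L) {
  trait <- trait[!is.na(trait)]
  lines <- intersect(names(trait), lineIds(panel))
  if (length(lines) < 3) stop("fewer than 3 lines shared between trait and panel")
  if (length(lines) < min_lines)
    warning("association scan on only ", length(lines), " lines")
  y <- trait[lines]
  geno <- genoMatrix(panel)[, lines, drop = FALSE]
  if (is.null(grm)) grm <- computeGRM(panel)
  if (!all(lines %in% rownames(grm)))
    stop("GRM does not cover all trait lines")
  G <- grm[lines, lines]
  null <- nullREML(y, G)
  if (!null$converged) stop("null variance-component fit did not converge")
  n <- length(y)
  w <- 1 / (null$lambda + null$delta)
  U <- null$U
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))

  vr <- variantRanges(panel)
  maf <- variantMAF(panel)   # from all panel lines (panel-level MAF)
  m <- nrow(geno)
  eff <- se <- tv <- pv <- rep(NA_real_, m)
  nv <- integer(m)
  for (v in seq_len(m)) {
    g <- geno[v, ]
    ok <- !is.na(g)
    nv[v] <- sum(ok)
    if (nv[v] < 3 || length(unique(g[ok])) < 2) next
    if (all(ok)) {
      gt <- drop(crossprod(U, g))
      X <- cbind(ot, gt)
      XtWX <- crossprod(X * sqrt(w))
      XtWy <- crossprod(X, w * yt)
      b <- solve(XtWX, XtWy)
      r <- yt - X %*% b
      s2 <- sum(w * r^2) / (n - 2)
      cv <- s2 * solve(XtWX)[2, 2]
    } else {
      Vs <- solve(null$vg * G[ok, ok] + null$ve * diag(sum(ok)))
      X <- cbind(1, g[ok])
      XtWX <- t(X) %*% Vs %*% X
      b <- solve(XtWX, t(X) %*% Vs %*% y[ok])
      r <- y[ok] - X %*% b
      s2 <- drop(t(r) %*% Vs %*% r) / (nv[v] - 2)
      cv <- s2 * solve(XtWX)[2, 2]
    }
    eff[v] <- b[2]
    se[v] <- sqrt(cv)
    tv[v] <- b[2] / se[v]
    pv[v] <- 2 * pt(-abs(tv[v]), nv[v] - 2)
  }
  tested <- !is.na(pv)
  out <- data.frame(
    variant_id = vr$id[tested],
    chrom = as.character(GenomicRanges::seqnames(vr))[tested],
    pos = GenomicRanges::start(vr)[tested],
    type = vr$type[tested],
    maf = unname(maf[tested]), n = nv[tested], effect = eff[tested],
    se = se[tested], t = tv[tested], P = pv[tested],
    stringsAsFactors = FALSE)
  out$top <- out$P < top_p
  out$bonferroni <- out$P < bonferroni_alpha / nrow(out)
  out <- out[order(out$P), ]
  rownames(out) <- NULL
  attr(out, "null_fit") <- null[c("vg", "ve", "delta", "minus2ll")]
  out
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and returns gene features as a `GRanges` with a
#' `gene_id` metadata column (taken from `Name`, `ID` or `gene_id`,
#' whichever is present).  GFF3 coordinates are 1-based inclusive, the
#' convention used throughout.
#'
#' @param path GFF3 file.
#' @return `GRanges` of gene bodies.
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path)
  if ("type" %in% colnames(S4Vectors::mcols(gr)) &&
      any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- mc$Name %||% mc$ID %||% mc$gene_id
  if (is.null(id)) stop("no gene identifier (Name/ID/gene_id) in GFF")
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::ranges(gr),
                         strand = GenomicRanges::strand(gr),
                         gene_id = as.character(id))
}

#' Assign genes within a window of each associated variant
#'
#' A variant is assigned every gene whose body, extended by `window` bp on
#' each side (1-based inclusive arithmetic: a variant exactly `window` bp
#' beyond a gene end is assigned, `window + 1` bp is not), contains the
#' variant position.  Variants on chromosome arms absent from the gene set
#' are left unannotated with a warning.
#'
#' @param records association records (from [lmmAssociation()]) with
#'   `chrom` and `pos` columns.
#' @param genes `GRanges` of gene bodies with a `gene_id` column (see
#'   [readGeneModels()]).
#' @param window assignment window in bp (default 1000).
#' @return `records` with a `genes` column (comma-separated gene ids,
#'   `""` when none).
#' @export
annotateVariants <- function(records, genes, window = 1000L) {
  stopifnot_cols(records, c("chrom", "pos"), "association records")
  known <- as.character(GenomeInfoDb::seqlevels(genes))
  unknown <- setdiff(unique(records$chrom), known)
  if (length(unknown))
    warning("chromosome arm(s) absent from gene models, left unannotated: ",
            paste(unknown, collapse = ", "))
  ext <- genes
  GenomicRanges::start(ext) <- pmax(1L, GenomicRanges::start(genes) - window)
  GenomicRanges::end(ext) <- GenomicRanges::end(genes) + window
  vr <- GenomicRanges::GRanges(
    records$chrom, IRanges::IRanges(records$pos, width = 1))
  GenomeInfoDb::seqlevels(vr) <-
    union(GenomeInfoDb::seqlevels(vr), known)
  hits <- GenomicRanges::findOverlaps(vr, ext, ignore.strand = TRUE)
  assigned <- rep("", nrow(records))
  if (length(hits)) {
    byv <- split(ext$gene_id[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    idx <- as.integer(names(byv))
    assigned[idx] <- vapply(byv, function(g)
      paste(unique(g), collapse = ","), character(1))
  }
  records$genes <- assigned
  records
}
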