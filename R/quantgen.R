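# REML variance components for line-panel designs.
#
# Both models used in the analysis reduce, after collapsing each line x sex
# cell to its mean, to small independent per-line covariance blocks (2 x 2
# at most), so the restricted likelihood and its analytic gradient are
# computed exactly in O(#lines) per evaluation:
#   pooled : Y = mu + Sex + Line + Sex:Line + E,  theta = (vL, vSL, vE)
#   oneway : Y = mu + Line + E (one sex),         theta = (vL, vE)
# Within-cell contrasts contribute (N - C) log vE + RSS_w / vE; cell means
# contribute block terms with Var = vL*J + vSL*I + vE*D^-1.

remlPrepOneWay <- function(line, y) {
  key <- as.character(line)
  mu <- tapply(y, key, mean)
  n <- table(key)[names(mu)]
  rssw <- sum((y - mu[key])^2)
  list(model = "oneway", N = length(y), C = length(mu), rssw = rssw,
       n1 = as.numeric(n), m1 = as.numeric(mu), vary = var(y))
}

remlPrepPooled <- function(line, sex, y) {
  key <- paste(line, sex, sep = "\r")
  mu <- tapply(y, key, mean)
  n <- table(key)
  rssw <- sum((y - mu[key])^2)
  parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  cl <- parts[, 1]; cs <- parts[, 2]
  lines <- unique(cl)
  hasF <- lines %in% cl[cs == "F"]
  hasM <- lines %in% cl[cs == "M"]
  both <- lines[hasF & hasM]
  single <- lines[!(hasF & hasM)]
  idx <- function(l, s) match(paste(l, s, sep = "\r"), names(mu))
  iF <- idx(both, "F"); iM <- idx(both, "M")
  sidx <- which(cl %in% single)
  list(model = "pooled", N = length(y), C = length(mu), rssw = rssw,
       nF = as.numeric(n[iF]), nM = as.numeric(n[iM]),
       mF = as.numeric(mu[iF]), mM = as.numeric(mu[iM]),
       n1 = as.numeric(n[sidx]), m1 = as.numeric(mu[sidx]),
       isM = as.numeric(cs[sidx] == "M"), vary = var(y))
}

remlObjGrad <- function(theta, prep, want_grad = FALSE) {
  pooled <- prep$model == "pooled"
  if (pooled) { vL <- theta[1]; vS <- theta[2]; vE <- theta[3] }
  else        { vL <- theta[1]; vS <- 0;        vE <- theta[2] }
  NC <- prep$N - prep$C
  obj <- if (NC > 0) NC * log(vE) + prep$rssw / vE else 0

  if (pooled && length(prep$nF)) {
    a11 <- vL + vS + vE / prep$nF
    a22 <- vL + vS + vE / prep$nM
    a12 <- vL
    det <- a11 * a22 - a12^2
    i11 <- a22 / det; i22 <- a11 / det; i12 <- -a12 / det
  } else { det <- i11 <- i22 <- i12 <- numeric(0) }
  v1 <- vL + vS + vE / (prep$n1 %||% numeric(0))
  if (!length(prep$n1 %||% numeric(0))) v1 <- numeric(0)

  logdet <- sum(log(det)) + sum(log(v1))

  if (pooled) {
    isM <- prep$isM
    W11 <- sum(i11 + 2 * i12 + i22) + sum(1 / v1)
    W12 <- sum(i12 + i22) + sum(isM / v1)
    W22 <- sum(i22) + sum(isM / v1)
    U1 <- sum((i11 + i12) * prep$mF + (i12 + i22) * prep$mM) +
      sum(prep$m1 / v1)
    U2 <- sum(i12 * prep$mF + i22 * prep$mM) + sum(isM * prep$m1 / v1)
    quad <- sum(prep$mF * (i11 * prep$mF + i12 * prep$mM) +
                prep$mM * (i12 * prep$mF + i22 * prep$mM)) +
      sum(prep$m1^2 / v1)
    dW <- W11 * W22 - W12^2
    b2 <- (W11 * U2 - W12 * U1) / dW
    b1 <- (U1 - W12 * b2) / W11
    rq <- quad - (b1 * U1 + b2 * U2)
    obj <- obj + logdet + log(dW) + rq
    if (!want_grad) return(obj)

    rF <- prep$mF - b1; rM <- prep$mM - b1 - b2
    r1 <- prep$m1 - b1 - isM * b2
    gF <- i11 * rF + i12 * rM; gM <- i12 * rF + i22 * rM
    g1 <- r1 / v1
    # traces tr(V^-1 A_k)
    t1L <- sum(i11 + 2 * i12 + i22) + sum(1 / v1)
    t1S <- sum(i11 + i22) + sum(1 / v1)
    t1E <- sum(i11 / prep$nF + i22 / prep$nM) + sum(1 / (v1 * prep$n1))
    # M_k = sum X' V^-1 A_k V^-1 X
    p <- i11 + i12; q <- i12 + i22
    ML <- c(sum(p^2 + 2 * p * q + q^2), sum(p * q + q^2), sum(q^2))
    BS11 <- i11^2 + i12^2; BS12 <- i12 * (i11 + i22); BS22 <- i12^2 + i22^2
    MS_ <- c(sum(BS11 + 2 * BS12 + BS22), sum(BS12 + BS22), sum(BS22))
    BE11 <- i11^2 / prep$nF + i12^2 / prep$nM
    BE12 <- i11 * i12 / prep$nF + i12 * i22 / prep$nM
    BE22 <- i12^2 / prep$nF + i22^2 / prep$nM
    ME <- c(sum(BE11 + 2 * BE12 + BE22), sum(BE12 + BE22), sum(BE22))
    s2 <- 1 / v1^2
    ML <- ML + c(sum(s2), sum(isM * s2), sum(isM * s2))
    MS_ <- MS_ + c(sum(s2), sum(isM * s2), sum(isM * s2))
    ME <- ME + c(sum(s2 / prep$n1), sum(isM * s2 / prep$n1),
                 sum(isM * s2 / prep$n1))
    Winv <- matrix(c(W22, -W12, -W12, W11), 2) / dW
    trW <- function(M) sum(Winv * matrix(c(M[1], M[2], M[2], M[3]), 2))
    t3L <- sum((gF + gM)^2) + sum(g1^2)
    t3S <- sum(gF^2 + gM^2) + sum(g1^2)
    t3E <- sum(gF^2 / prep$nF + gM^2 / prep$nM) + sum(g1^2 / prep$n1)
    gr <- c(t1L - trW(ML) - t3L,
            t1S - trW(MS_) - t3S,
            t1E - trW(ME) - t3E +
              (if (NC > 0) NC / vE - prep$rssw / vE^2 else 0))
    return(list(objective = obj, gradient = gr))
  }

  # one-way: scalar blocks only
  iv <- 1 / v1
  W <- sum(iv); U <- sum(prep$m1 * iv); quad <- sum(prep$m1^2 * iv)
  b <- U / W
  rq <- quad - b * U
  obj <- obj + logdet + log(W) + rq
  if (!want_grad) return(obj)
  r <- prep$m1 - b
  g <- r * iv
  t1L <- sum(iv); t1E <- sum(iv / prep$n1)
  ML <- sum(iv^2); ME <- sum(iv^2 / prep$n1)
  t3L <- sum(g^2); t3E <- sum(g^2 / prep$n1)
  gr <- c(t1L - ML / W - t3L,
          t1E - ME / W - t3E +
            (if (NC > 0) NC / vE - prep$rssw / vE^2 else 0))
  list(objective = obj, gradient = gr)
}

remlSolve <- function(prep) {
  pooled <- prep$model == "pooled"
  npar <- if (pooled) 3L else 2L
  vy <- prep$vary
  if (!is.finite(vy) || vy < 1e-14) {
    theta <- rep(0, npar)
    return(list(theta = theta, se = rep(NA_real_, npar), convergence = TRUE,
                iterations = 0L, grad_norm = 0,
                obj_start = NA_real_, obj_final = NA_real_,
                boundary = rep(TRUE, npar)))
  }
  NC <- prep$N - prep$C
  vE0 <- if (NC > 0) max(prep$rssw / NC, vy * 1e-6) else vy / 2
  if (vE0 <= 0) vE0 <- vy * 1e-6
  mcell <- c(prep$mF %||% numeric(0), prep$mM %||% numeric(0), prep$m1)
  s2cell <- if (length(mcell) > 1) var(mcell) else vy
  start <- if (pooled) c(max(s2cell / 2, vy * 1e-4),
                         max(s2cell / 4, vy * 1e-4), vE0)
           else c(max(s2cell / 2, vy * 1e-4), vE0)
  lower <- c(rep(0, npar - 1), vy * 1e-10)
  obj <- function(th) remlObjGrad(th, prep, FALSE)
  grd <- function(th) remlObjGrad(th, prep, TRUE)$gradient
  obj0 <- obj(start)
  fit <- nlminb(start, obj, gradient = grd, lower = lower,
                control = list(iter.max = 500, eval.max = 1000,
                               rel.tol = 1e-14, x.tol = 1e-15))
  theta <- fit$par
  # Newton polish on interior coordinates for tight oracle agreement
  for (it in seq_len(8)) {
    gg <- grd(theta)
    free <- theta > lower + 1e-9 * max(vy, 1)
    if (!any(free) || sqrt(sum(gg[free]^2)) < 1e-10) break
    H <- tryCatch(optimHess(theta, obj, grd), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H[free, free, drop = FALSE], gg[free]),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta
    cand[free] <- cand[free] - step
    if (any(cand < lower)) {
      lam <- suppressWarnings(min(1, 0.95 * min(
        ((theta - lower) / pmax(step, 0))[free][step > 0])))
      if (!is.finite(lam) || lam <= 0) break
      cand <- theta
      cand[free] <- cand[free] - lam * step
    }
    if (obj(cand) <= obj(theta) + 1e-10) theta <- cand else break
  }
  theta <- pmax(theta, lower)
  objf <- obj(theta)
  gg <- grd(theta)
  free <- theta > lower + 1e-9 * max(vy, 1)
  gnorm <- if (any(free)) sqrt(sum(gg[free]^2)) else 0
  se <- rep(NA_real_, npar)
  H <- tryCatch(optimHess(theta, obj, grd), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      d <- diag(V)
      pos <- is.finite(d) & d > 0
      se[pos] <- sqrt(d[pos])
    }
  }
  se[!free] <- NA_real_
  list(theta = theta, se = se,
       convergence = (fit$convergence == 0 || gnorm < 1e-6) &&
                     objf <= obj0 + 1e-8,
       iterations = fit$iterations, grad_norm = gnorm,
       obj_start = obj0, obj_final = objf, boundary = !free)
}

checkValueCol <- function(vials, value) {
  stopifnot_cols(vials, c("line", "sex", value), "vial table")
  y <- vials[[value]]
  if (!is.numeric(y) || anyNA(y)) stop("value column must be numeric, no NAs")
  y
}

#' REML fit of the two-way line-by-sex mixed model
#'
#' Fits `Y = mu + Sex + Line + Sex:Line + E` with Sex fixed and Line and
#' Sex:Line random, by exact restricted maximum likelihood on the cell-mean
#' reduction (handles arbitrary unbalanced replicate counts and lines
#' measured in a single sex).  Standard errors come from the observed
#' information; variance components are constrained non-negative.
#' Optionally computes the Type III ANOVA table via [car::Anova] (sum
#' contrasts), with Sex and Line tested against the Sex:Line mean square
#' and Sex:Line against the error mean square.
#'
#' @param vials data.frame with columns `line`, `sex` (`F`/`M`) and the
#'   value column.
#' @param value name of the per-fly intake column.
#' @param anova logical; compute the Type III ANOVA table (slower).
#' @return object of class `cafeVarComp`: `components` (named
#'   `sigma2_line`, `sigma2_sexline`, `sigma2_error`), `se`, `model`
#'   (`"pooled"`), `convergence` diagnostics and `anova` table.
#' @examples
#' cfg <- simulationConfig(n_lines = 30, n_reps = 4, seed = 3)
#' sim <- simulatePhenotypes(cfg)
#' adj <- adjustConsumption(sim$vials, sim$controls)
#' fitTwoWayMixed(adj, anova = FALSE)
#' @export
fitTwoWayMixed <- function(vials, value = "adjusted_ul", anova = TRUE) {
  y <- checkValueCol(vials, value)
  sexes <- unique(vials$sex)
  if (!all(c("F", "M") %in% sexes))
    stop("two-way model needs both sexes; got: ",
         paste(sexes, collapse = ", "), ". Use fitOneWayRandom for one sex.")
  if (length(unique(vials$line)) < 2) stop("need >= 2 lines")
  prep <- remlPrepPooled(vials$line, vials$sex, y)
  if (!length(prep$nF))
    stop("no line is measured in both sexes; line and sex-by-line variance are confounded")
  if (prep$N == prep$C)
    stop("no cell has >= 2 replicate vials; error variance is not identifiable")
  sol <- remlSolve(prep)
  comp <- setNames(sol$theta, c("sigma2_line", "sigma2_sexline",
                                "sigma2_error"))
  se <- setNames(sol$se, names(comp))
  if (!sol$convergence)
    stop("REML did not converge (gradient norm ",
         format(sol$grad_norm), " after ", sol$iterations, " iterations)")
  at <- if (anova) anovaTwoWay(vials$line, vials$sex, y) else NULL
  structure(list(components = comp, se = se, model = "pooled",
                 convergence = sol[c("convergence", "iterations",
                                     "grad_norm", "obj_start", "obj_final",
                                     "boundary")],
                 anova = at, n_lines = length(unique(vials$line)),
                 n_obs = prep$N, minus2_restricted_ll = sol$obj_final),
            class = "cafeVarComp")
}

#' REML fit of the one-way random-line model for one sex
#'
#' Fits `Y = mu + Line + E` on one sex's vials.  For balanced data the
#' REML solution coincides with the ANOVA moment estimator
#' `((MS_Line - MS_Error)/n, MS_Error)` truncated at zero.
#'
#' @inheritParams fitTwoWayMixed
#' @param sex `"F"` or `"M"`; which sex's records to use.
#' @return `cafeVarComp` with components `sigma2_line`, `sigma2_error` and
#'   model tag `"female"` or `"male"`.
#' @export
fitOneWayRandom <- function(vials, sex, value = "adjusted_ul",
                            anova = TRUE) {
  stopifnot(sex %in% c("F", "M"))
  y <- checkValueCol(vials, value)
  keep <- vials$sex == sex
  if (!any(keep)) stop("no records for sex ", sex)
  line <- vials$line[keep]; y <- y[keep]
  if (length(unique(line)) < 2) stop("need >= 2 lines")
  prep <- remlPrepOneWay(line, y)
  if (prep$N == prep$C)
    stop("no line has >= 2 replicate vials; error variance is not identifiable")
  sol <- remlSolve(prep)
  comp <- setNames(sol$theta, c("sigma2_line", "sigma2_error"))
  if (!sol$convergence)
    stop("REML did not converge (gradient norm ",
         format(sol$grad_norm), ")")
  at <- if (anova) anovaOneWay(line, y) else NULL
  structure(list(components = comp,
                 se = setNames(sol$se, names(comp)),
                 model = if (sex == "F") "female" else "male",
                 convergence = sol[c("convergence", "iterations",
                                     "grad_norm", "obj_start", "obj_final",
                                     "boundary")],
                 anova = at, n_lines = length(unique(line)),
                 n_obs = prep$N, minus2_restricted_ll = sol$obj_final),
            class = "cafeVarComp")
}

anovaTwoWay <- function(line, sex, y) {
  df <- data.frame(y = y, sex = factor(sex), line = factor(line))
  mod <- lm(y ~ sex * line, data = df,
            contrasts = list(sex = "contr.sum", line = "contr.sum"))
  a3 <- car::Anova(mod, type = 3, singular.ok = TRUE)
  pick <- function(nm) {
    i <- match(nm, rownames(a3))
    c(df = a3$Df[i], ss = a3$`Sum Sq`[i])
  }
  s <- pick("sex"); l <- pick("line"); sl <- pick("sex:line")
  e <- pick("Residuals")
  ms <- c(s["ss"] / s["df"], l["ss"] / l["df"], sl["ss"] / sl["df"],
          e["ss"] / e["df"])
  Fv <- c(ms[1] / ms[3], ms[2] / ms[3], ms[3] / ms[4], NA)
  dfs <- c(s["df"], l["df"], sl["df"], e["df"])
  den_df <- c(sl["df"], sl["df"], e["df"], NA)
  P <- c(pf(Fv[1], dfs[1], den_df[1], lower.tail = FALSE),
         pf(Fv[2], dfs[2], den_df[2], lower.tail = FALSE),
         pf(Fv[3], dfs[3], den_df[3], lower.tail = FALSE), NA)
  data.frame(source = c("Sex", "Line", "Sex x Line", "Error"),
             df = unname(dfs), MS = unname(ms), F = unname(Fv),
             P = unname(P), stringsAsFactors = FALSE)
}

anovaOneWay <- function(line, y) {
  ow <- onewayF(y, line)
  data.frame(source = c("Line", "Error"),
             df = c(ow$df1, ow$df2), MS = c(ow$msb, ow$msw),
             F = c(ow$F, NA), P = c(ow$P, NA), stringsAsFactors = FALSE)
}

#' @export
print.cafeVarComp <- function(x, ...) {
  cat(sprintf("REML variance components (%s model; %d lines, %d vials)\n",
              x$model, x$n_lines, x$n_obs))
  tab <- data.frame(component = names(x$components),
                    estimate = round(unname(x$components), 4),
                    se = round(unname(x$se), 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$anova)) {
    cat("Type III ANOVA:\n")
    print(x$anova, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Broad-sense heritability from variance components
#'
#' Pooled across sexes: `H2 = (s2_L + s2_SL) / (s2_L + s2_SL + s2_E)`.
#' Per sex: `H2 = s2_L / (s2_L + s2_E)`.
#'
#' @param components a `cafeVarComp` fit or a named numeric vector with
#'   `sigma2_line`, `sigma2_error` and (pooled mode) `sigma2_sexline`.
#' @param mode `"pooled"` or `"per_sex"`; default inferred from the input.
#' @return heritability in `[0, 1]`.
#' @examples
#' broadSenseHeritability(c(sigma2_line = 8.21, sigma2_sexline = 1.92,
#'                          sigma2_error = 12.66))
#' @export
broadSenseHeritability <- function(components, mode = NULL) {
  if (inherits(components, "cafeVarComp")) {
    mode <- mode %||% if (components$model == "pooled") "pooled" else "per_sex"
    components <- components$components
  }
  mode <- mode %||% if ("sigma2_sexline" %in% names(components)) "pooled"
                    else "per_sex"
  vL <- components[["sigma2_line"]]
  vE <- components[["sigma2_error"]]
  vS <- if (mode == "pooled") components[["sigma2_sexline"]] else 0
  if (any(!is.finite(c(vL, vS, vE))) || any(c(vL, vS, vE) < 0))
    stop("components must be finite and non-negative")
  tot <- vL + vS + vE
  if (tot == 0) stop("heritability undefined: all variance components are zero")
  if (mode == "pooled") (vL + vS) / tot else vL / (vL + vE)
}

#' Cross-sex genetic correlation of line means
#'
#' `r_GS = cov_MF / (sigma_LM * sigma_LF)`, where `cov_MF` is the sample
#' covariance of female and male line means over lines measured in both
#' sexes, and the denominators are, in the primary convention, square
#' roots of the per-sex REML among-line variance components (each per-sex
#' fit uses all lines measured in that sex).  The plain Pearson
#' correlation of line means is reported alongside.  Estimates outside
#' `[-1, 1]` (possible because numerator and denominators come from
#' different estimators) are reported raw with a clamped copy and a
#' warning.
#'
#' @inheritParams fitTwoWayMixed
#' @return list of class `cafeGenCorr`: `r_gs`, `r_gs_raw`, `r_pearson`,
#'   `cov_MF`, `sigma_LF`, `sigma_LM`, `n_lines_both`.
#' @export
crossSexGeneticCorrelation <- function(vials, value = "adjusted_ul") {
  y <- checkValueCol(vials, value)
  lt <- summarizeLines(vials, min_reps = 1L, value = value)
  wf <- lt[lt$sex == "F", c("line", "mean")]
  wm <- lt[lt$sex == "M", c("line", "mean")]
  mrg <- merge(wf, wm, by = "line", suffixes = c("_F", "_M"))
  if (nrow(mrg) < 3) stop("need >= 3 lines measured in both sexes")
  cov_MF <- cov(mrg$mean_F, mrg$mean_M)
  fF <- fitOneWayRandom(vials, "F", value = value, anova = FALSE)
  fM <- fitOneWayRandom(vials, "M", value = value, anova = FALSE)
  sLF <- sqrt(fF$components[["sigma2_line"]])
  sLM <- sqrt(fM$components[["sigma2_line"]])
  r_raw <- if (sLF > 0 && sLM > 0) cov_MF / (sLF * sLM) else NA_real_
  r <- r_raw
  if (is.finite(r) && abs(r) > 1) {
    warning(sprintf("r_GS = %.3f outside [-1, 1]; reporting clamped value",
                    r))
    r <- sign(r)
  }
  structure(list(r_gs = r, r_gs_raw = r_raw,
                 r_pearson = cor(mrg$mean_F, mrg$mean_M),
                 cov_MF = cov_MF, sigma_LF = sLF, sigma_LM = sLM,
                 n_lines_both = nrow(mrg)), class = "cafeGenCorr")
}

#' @export
print.cafeGenCorr <- function(x, ...) {
  cat(sprintf(paste0("cross-sex genetic correlation: r_GS = %.3f ",
                     "(REML denominators; Pearson of line means = %.3f)\n"),
              x$r_gs, x$r_pearson))
  cat(sprintf("  cov_MF = %.3f, sigma_LF = %.3f, sigma_LM = %.3f, %d lines\n",
              x$cov_MF, x$sigma_LF, x$sigma_LM, x$n_lines_both))
  invisible(x)
}
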