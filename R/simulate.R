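#' Configuration for the synthetic line-panel feeding study
#'
#' Bundles every parameter of the synthetic-data generator.  The defaults
#' describe a panel of 182 inbred lines assayed in both sexes with six
#' replicate vials of eight flies, with among-line, sex-by-line and
#' within-line variance components on the scale observed for food intake in
#' large inbred panels, a heritable within-line standard deviation (drawn
#' log-normally per line and sex), biallelic homozygous genotypes with a
#' uniform minor-allele-frequency spectrum, and a Wolbachia infection
#' covariate.
#'
#' The within-line SD of line `l` in sex `s` is
#' `exp(mu0 + b_l + w_ls)` with `Var(b) = cve_heritability * cve_logsd_sd^2`
#' and `Var(w) = (1 - cve_heritability) * cve_logsd_sd^2`; `mu0` is chosen
#' so that the expected within-line *variance* equals `var_error_mean`.
#' Setting `cve_logsd_sd = 0` gives strictly equal within-line variances.
#'
#' @param n_lines number of inbred lines.
#' @param n_reps replicate vials per line and sex.
#' @param grand_mean grand mean per-fly intake (uL/fly over 24 h).
#' @param sex_effect fixed sex difference, female minus male (uL/fly).
#' @param var_line among-line variance component (uL^2/fly^2).
#' @param var_sexline sex-by-line variance component.
#' @param var_error_mean expected within-line (vial-to-vial) variance.
#' @param cve_heritability fraction of log within-line-SD variance that is
#'   among lines (0..1); makes micro-environmental variance heritable.
#' @param cve_logsd_sd total SD of log within-line SD across line x sex
#'   cells.
#' @param n_variants number of simulated biallelic variants.
#' @param maf_range length-2 numeric in (0, 0.5]; minor allele frequencies
#'   are drawn uniformly in this range and realized exactly (the minor
#'   allele is assigned to `round(maf * n_lines)` lines).
#' @param causal_mean_effects list of `list(variant=, effect=, sex=)`
#'   entries: `effect` is the per-allele (allele-substitution) effect in
#'   uL/fly, so homozygous classes differ by `2 * effect`; `sex` is one of
#'   `"both"`, `"F"`, `"M"`.
#' @param causal_var_effects list of `list(variant=, factor=)` entries:
#'   lines homozygous for the coded allele have their within-line SD
#'   multiplied by `factor`.
#' @param wolbachia_freq fraction of infected lines.
#' @param wolbachia_effect additive shift of infected line means (uL/fly).
#' @param flies_per_vial flies placed in each vial.
#' @param n_batches number of evaporation batches (humid chambers).
#' @param n_controls fly-free control vials per batch.
#' @param evap_mean mean evaporation per vial over the assay (uL).
#' @param evap_batch_sd SD of the shared per-batch evaporation constant.
#' @param evap_sd SD of vial-level evaporation noise.
#' @param seed integer; fully determines all generator output.
#' @return An object of class `CafeSimConfig` (validated list).
#' @examples
#' cfg <- simulationConfig(n_lines = 12, n_reps = 4, seed = 7)
#' sim <- simulatePhenotypes(cfg)
#' head(sim$vials)
#' @export
simulationConfig <- function(n_lines = 182L,
                             n_reps = 6L,
                             grand_mean = 12,
                             sex_effect = 0.88,
                             var_line = 8.21,
                             var_sexline = 1.92,
                             var_error_mean = 12.66,
                             cve_heritability = 0.3,
                             cve_logsd_sd = 0.2,
                             n_variants = 1000L,
                             maf_range = c(0.05, 0.5),
                             causal_mean_effects = list(),
                             causal_var_effects = list(),
                             wolbachia_freq = 0.53,
                             wolbachia_effect = 0,
                             flies_per_vial = 8L,
                             n_batches = 1L,
                             n_controls = 4L,
                             evap_mean = 1.5,
                             evap_batch_sd = 0.2,
                             evap_sd = 0.1,
                             seed = 1L) {
  if (n_lines < 1 || n_reps < 1) stop("n_lines and n_reps must be positive")
  for (v in c(var_line, var_sexline, var_error_mean))
    if (!is.finite(v) || v < 0) stop("variance parameters must be >= 0")
  if (cve_heritability < 0 || cve_heritability > 1)
    stop("cve_heritability must be in [0, 1]")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be within (0, 0.5]")
  if (wolbachia_freq < 0 || wolbachia_freq > 1)
    stop("wolbachia_freq must be in [0, 1]")
  chkCausal <- function(lst, fields) {
    for (ce in lst) {
      if (!all(fields %in% names(ce)))
        stop("causal effect entries need fields: ",
             paste(fields, collapse = ", "))
      if (ce$variant < 1 || ce$variant > n_variants)
        stop("causal variant index out of range: ", ce$variant)
    }
  }
  chkCausal(causal_mean_effects, c("variant", "effect"))
  chkCausal(causal_var_effects, c("variant", "factor"))
  cfg <- list(n_lines = as.integer(n_lines), n_reps = as.integer(n_reps),
              grand_mean = grand_mean, sex_effect = sex_effect,
              var_line = var_line, var_sexline = var_sexline,
              var_error_mean = var_error_mean,
              cve_heritability = cve_heritability,
              cve_logsd_sd = cve_logsd_sd,
              n_variants = as.integer(n_variants), maf_range = maf_range,
              causal_mean_effects = causal_mean_effects,
              causal_var_effects = causal_var_effects,
              wolbachia_freq = wolbachia_freq,
              wolbachia_effect = wolbachia_effect,
              flies_per_vial = as.integer(flies_per_vial),
              n_batches = as.integer(n_batches),
              n_controls = as.integer(n_controls),
              evap_mean = evap_mean, evap_batch_sd = evap_batch_sd,
              evap_sd = evap_sd, seed = as.integer(seed))
  class(cfg) <- "CafeSimConfig"
  cfg
}

#' @export
print.CafeSimConfig <- function(x, ...) {
  cat(sprintf(paste0("CafeSimConfig: %d lines x 2 sexes x %d vials ",
                     "(%d flies/vial), %d variants, seed %d\n"),
              x$n_lines, x$n_reps, x$flies_per_vial, x$n_variants, x$seed))
  cat(sprintf("  mean %.2f uL/fly, sex effect (F-M) %.2f; var components L=%.2f SL=%.2f E=%.2f\n",
              x$grand_mean, x$sex_effect, x$var_line, x$var_sexline,
              x$var_error_mean))
  cat(sprintf("  CV_E heritability %.2f (log-SD dispersion %.2f); causal: %d mean, %d variance\n",
              x$cve_heritability, x$cve_logsd_sd,
              length(x$causal_mean_effects), length(x$causal_var_effects)))
  invisible(x)
}

lineIdsFor <- function(n) sprintf("line_%03d", seq_len(n))

drawWolbachia <- function(config) {
  set.seed(subSeed(config$seed, "covariates"))
  stats::rbinom(config$n_lines, 1, config$wolbachia_freq) == 1
}

#' Simulate vial-level feeding-assay phenotypes
#'
#' Generates vial records by inverting the analysis model: per-fly vial
#' intake is `grand_mean +/- sex_effect/2 + L_l + (LS)_ls + QTL + e`, with
#' `L ~ N(0, var_line)`, `LS ~ N(0, var_sexline)` and vial error drawn with
#' a line-and-sex-specific SD (heritable micro-environmental variance).
#' Recorded vial totals are per-fly intake times flies per vial plus a
#' simulated evaporation loss, so the evaporation/survivor adjustment of
#' [adjustConsumption()] is exercised end to end.  Random streams are split
#' per component (line effects, covariates, genotypes, noise,
#' evaporation), so e.g. changing `n_variants` does not perturb phenotypes.
#'
#' @param config a [simulationConfig()].
#' @param panel optional [GenotypePanel-class] (normally from
#'   [simulateGenotypes()] with the same config); required for causal
#'   variant effects, and supplies the Wolbachia assignment.
#' @return list with `vials` (data.frame: line, sex, replicate, total_ul,
#'   flies_alive, batch), `controls` (batch, evap_ul), `truth` (per-line
#'   effects, within-line SDs, causal effects, covariates) and `config`.
#' @export
simulatePhenotypes <- function(config, panel = NULL) {
  stopifnot(inherits(config, "CafeSimConfig"))
  nl <- config$n_lines; nr <- config$n_reps
  lines <- lineIdsFor(nl)
  if (!is.null(panel)) {
    stopifnot(methods::is(panel, "GenotypePanel"))
    if (ncol(genoMatrix(panel)) != nl)
      stop("panel line count does not match config")
    lines <- lineIds(panel)
    wolb <- lineData(panel)$wolbachia
  } else {
    wolb <- drawWolbachia(config)
  }

  set.seed(subSeed(config$seed, "line_effects"))
  L <- rnorm(nl, 0, sqrt(config$var_line))
  SL <- matrix(rnorm(2 * nl, 0, sqrt(config$var_sexline)), nl, 2,
               dimnames = list(lines, c("F", "M")))
  tau <- config$cve_logsd_sd
  b <- rnorm(nl, 0, sqrt(config$cve_heritability) * tau)
  w <- matrix(rnorm(2 * nl, 0, sqrt(1 - config$cve_heritability) * tau),
              nl, 2, dimnames = list(lines, c("F", "M")))

  if (config$var_error_mean > 0) {
    mu0 <- 0.5 * (log(config$var_error_mean)) - tau^2
    sdm <- exp(mu0 + b + w)           # lines x 2, E[sd^2] = var_error_mean
  } else {
    sdm <- matrix(0, nl, 2, dimnames = list(lines, c("F", "M")))
  }

  sexmu <- c(F = config$grand_mean + config$sex_effect / 2,
             M = config$grand_mean - config$sex_effect / 2)
  cellmu <- cbind(F = sexmu["F"] + L + SL[, "F"],
                  M = sexmu["M"] + L + SL[, "M"])
  rownames(cellmu) <- lines
  cellmu <- cellmu + config$wolbachia_effect * wolb

  if (!is.null(panel)) {
    g <- genoMatrix(panel)
    for (ce in config$causal_mean_effects) {
      gv <- g[ce$variant, ]
      gv[is.na(gv)] <- 0
      sx <- ce$sex %||% "both"
      add <- gv * ce$effect
      if (sx %in% c("both", "F")) cellmu[, "F"] <- cellmu[, "F"] + add
      if (sx %in% c("both", "M")) cellmu[, "M"] <- cellmu[, "M"] + add
    }
    for (ce in config$causal_var_effects) {
      gv <- g[ce$variant, ]
      gv[is.na(gv)] <- 0
      sdm <- sdm * ce$factor^(gv / 2)
    }
  } else if (length(config$causal_mean_effects) ||
             length(config$causal_var_effects)) {
    stop("causal variant effects require a genotype panel")
  }

  # vial layout: lines x sexes x replicates, batches assigned by vial
  vials <- expand.grid(replicate = seq_len(nr), sex = c("F", "M"),
                       line = lines, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  vials <- vials[, c("line", "sex", "replicate")]
  nv <- nrow(vials)
  li <- match(vials$line, lines)
  si <- match(vials$sex, c("F", "M"))

  set.seed(subSeed(config$seed, "noise"))
  perfly <- cellmu[cbind(li, si)] + rnorm(nv) * sdm[cbind(li, si)]

  set.seed(subSeed(config$seed, "evaporation"))
  batches <- sprintf("batch_%02d", seq_len(config$n_batches))
  bconst <- config$evap_mean + rnorm(config$n_batches, 0, config$evap_batch_sd)
  vb <- rep(seq_len(config$n_batches), length.out = nv)
  evap_vial <- bconst[vb] + rnorm(nv, 0, config$evap_sd)
  controls <- data.frame(
    batch = rep(batches, each = config$n_controls),
    evap_ul = pmax(0, rep(bconst, each = config$n_controls) +
                     rnorm(config$n_batches * config$n_controls, 0,
                           config$evap_sd)),
    stringsAsFactors = FALSE)

  vials$total_ul <- perfly * config$flies_per_vial + evap_vial
  vials$flies_alive <- config$flies_per_vial
  vials$batch <- batches[vb]

  truth <- list(lines = lines, line_effects = setNames(L, lines),
                sexline_effects = SL, within_sd = sdm, cell_means = cellmu,
                wolbachia = setNames(wolb, lines),
                causal_mean_effects = config$causal_mean_effects,
                causal_var_effects = config$causal_var_effects,
                batch_evaporation = setNames(bconst, batches))
  structure(list(vials = vials, controls = controls, truth = truth,
                 config = config), class = "CafeSimulation")
}

#' Simulate a homozygous line-by-variant genotype panel
#'
#' Each variant is biallelic; a target minor allele frequency is drawn
#' uniformly in `maf_range` and realized exactly by assigning the minor
#' allele to `round(maf * n_lines)` lines sampled without replacement
#' (so `maf_range = c(0.5, 0.5)` with an even line count gives exactly
#' balanced allele classes).  Which allele is coded 2 is randomized per
#' variant, as in real ref/alt-coded panels.  Per-line covariates
#' (Wolbachia, common inversion karyotypes) are drawn from their own
#' random stream.
#'
#' @inheritParams simulatePhenotypes
#' @return a [GenotypePanel-class].
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "CafeSimConfig"))
  nl <- config$n_lines; nv <- config$n_variants
  lines <- lineIdsFor(nl)
  wolb <- drawWolbachia(config)
  set.seed(subSeed(config$seed, "covariates") + 1L)
  inv <- data.frame(
    In2Lt  = ifelse(rbinom(nl, 1, 0.20) == 1, "INV", "ST"),
    In2RNS = ifelse(rbinom(nl, 1, 0.15) == 1, "INV", "ST"),
    In3RP  = ifelse(rbinom(nl, 1, 0.10) == 1, "INV", "ST"),
    In3RK  = ifelse(rbinom(nl, 1, 0.08) == 1, "INV", "ST"),
    In3RMo = ifelse(rbinom(nl, 1, 0.10) == 1, "INV", "ST"),
    stringsAsFactors = FALSE)

  set.seed(subSeed(config$seed, "genotypes"))
  maf <- runif(nv, config$maf_range[1], config$maf_range[2])
  nminor <- pmin(pmax(round(maf * nl), 1L), floor(nl / 2))
  flip <- rbinom(nv, 1, 0.5) == 1     # coded allele is the major one
  geno <- matrix(0, nv, nl)
  for (v in seq_len(nv)) {
    carriers <- sample.int(nl, nminor[v])
    geno[v, carriers] <- 2
    if (flip[v]) geno[v, ] <- 2 - geno[v, ]
  }
  chrom <- sample(c("2L", "2R", "3L", "3R", "X"), nv, replace = TRUE,
                  prob = c(0.22, 0.22, 0.22, 0.24, 0.10))
  pos <- sample.int(23000000L, nv)    # unique positions => unique ids
  type <- sample(c("SNP", "INS", "DEL"), nv, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  ids <- paste(chrom, pos, type, sep = "_")
  variants <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
                                     id = ids, type = type)
  dimnames(geno) <- list(ids, lines)
  ld <- S4Vectors::DataFrame(wolbachia = wolb, inv, row.names = lines)
  GenotypePanel(geno, variants, ld)
}

#' Simulate a complete study: genotypes plus genotype-aware phenotypes
#'
#' Runs [simulateGenotypes()] and [simulatePhenotypes()] jointly so that
#' configured causal variants shift line means (mean-QTL) or scale
#' within-line SDs (variance-QTL) before vial noise is drawn.
#'
#' @inheritParams simulatePhenotypes
#' @return list with `vials`, `controls`, `panel`, `truth`, `config`.
#' @export
simulateCafePanel <- function(config) {
  panel <- simulateGenotypes(config)
  ph <- simulatePhenotypes(config, panel)
  structure(list(vials = ph$vials, controls = ph$controls, panel = panel,
                 truth = ph$truth, config = config),
            class = "CafeSimulation")
}

#' Write simulated (or real) assay tables to delimited text
#'
#' @param vials vial-level data.frame as produced by the generator or
#'   [readAssayTable()].
#' @param controls evaporation-control data.frame (batch, evap_ul).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written (`assay.tsv`, `controls.tsv`).
#' @export
writeAssayTable <- function(vials, controls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "assay.tsv")
  pc <- file.path(dir, "controls.tsv")
  utils::write.table(vials, pa, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(controls, pc, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(assay = pa, controls = pc))
}

#' Write a genotype panel as delimited text
#'
#' Writes `genotypes.tsv` (variant x line matrix with a `variant_id` first
#' column), `variants.tsv` (id, chrom, pos, type) and `lines.tsv`
#' (line covariates).
#'
#' @param panel a [GenotypePanel-class].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeGenotypePanel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- data.frame(variant_id = variantIds(panel), genoMatrix(panel),
                  check.names = FALSE)
  vr <- variantRanges(panel)
  v <- data.frame(id = vr$id,
                  chrom = as.character(GenomicRanges::seqnames(vr)),
                  pos = GenomicRanges::start(vr), type = vr$type)
  l <- data.frame(line = lineIds(panel),
                  as.data.frame(lineData(panel)), check.names = FALSE)
  paths <- file.path(dir, c("genotypes.tsv", "variants.tsv", "lines.tsv"))
  utils::write.table(g, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(v, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(l, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write the generator's ground truth as structured YAML
#'
#' Stores the per-line effects, within-line SDs, causal variant effects
#' and covariate assignments alongside a generated dataset, so recovery
#' tests can compare estimates against the generating values.
#'
#' @param sim a `CafeSimulation` (from [simulatePhenotypes()] or
#'   [simulateCafePanel()]).
#' @param path output YAML file.
#' @return invisibly, `path`.
#' @export
writeSimulationTruth <- function(sim, path) {
  stopifnot(inherits(sim, "CafeSimulation"))
  tr <- sim$truth
  out <- list(
    lines = as.list(setNames(as.numeric(tr$line_effects), tr$lines)),
    sexline_F = as.list(setNames(tr$sexline_effects[, "F"], tr$lines)),
    sexline_M = as.list(setNames(tr$sexline_effects[, "M"], tr$lines)),
    within_sd_F = as.list(setNames(tr$within_sd[, "F"], tr$lines)),
    within_sd_M = as.list(setNames(tr$within_sd[, "M"], tr$lines)),
    wolbachia = as.list(setNames(as.logical(tr$wolbachia), tr$lines)),
    causal_mean_effects = tr$causal_mean_effects,
    causal_var_effects = tr$causal_var_effects,
    batch_evaporation = as.list(tr$batch_evaporation),
    seed = sim$config$seed)
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Read a genotype panel written by [writeGenotypePanel()]
#'
#' @param dir directory containing `genotypes.tsv`, `variants.tsv`,
#'   `lines.tsv`.
#' @return a [GenotypePanel-class].
#' @export
readGenotypePanel <- function(dir) {
  g <- utils::read.delim(file.path(dir, "genotypes.tsv"),
                         check.names = FALSE)
  v <- utils::read.delim(file.path(dir, "variants.tsv"))
  l <- utils::read.delim(file.path(dir, "lines.tsv"), check.names = FALSE)
  geno <- as.matrix(g[, -1, drop = FALSE])
  rownames(geno) <- g$variant_id
  variants <- GenomicRanges::GRanges(v$chrom,
                                     IRanges::IRanges(v$pos, width = 1),
                                     id = v$id, type = v$type)
  ld <- S4Vectors::DataFrame(l[, setdiff(names(l), "line"), drop = FALSE],
                             row.names = l$line)
  ld$wolbachia <- as.logical(ld$wolbachia)
  GenotypePanel(geno, variants, ld)
}
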