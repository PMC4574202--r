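#' Default pipeline configuration
#'
#' @param out_dir directory for stage artifacts (created when needed).
#' @param stages character subset of
#'   `c("simulate", "reduce", "varcomp", "microvar", "gwas")` to run.
#' @param sim a [simulationConfig()]; used when `assay_path` is `NULL`.
#' @param assay_path,controls_path optional paths to real vial/control
#'   tables (skips the simulate stage).
#' @param genotype_dir optional directory readable by
#'   [readGenotypePanel()]; otherwise the simulated panel is used.
#' @param gff_path optional GFF3 of gene models for annotation.
#' @param maf_min,top_p,bonferroni_alpha,min_reps_for_cve analysis
#'   thresholds (panel MAF filter, nominal reporting threshold,
#'   family-wise alpha, replicate floor for CV_E).
#' @return a validated config list of class `CafePipelineConfig`.
#' @export
pipelineConfig <- function(out_dir = NULL,
                           stages = c("simulate", "reduce", "varcomp",
                                      "microvar", "gwas"),
                           sim = simulationConfig(),
                           assay_path = NULL, controls_path = NULL,
                           genotype_dir = NULL, gff_path = NULL,
                           maf_min = 0.05, top_p = 1e-5,
                           bonferroni_alpha = 0.05,
                           min_reps_for_cve = 3L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (maf_min <= 0 || maf_min > 0.5) stop("maf_min must be in (0, 0.5]")
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]")
  for (p in c(assay_path, controls_path, genotype_dir, gff_path))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  structure(list(out_dir = out_dir, stages = stages, sim = sim,
                 assay_path = assay_path, controls_path = controls_path,
                 genotype_dir = genotype_dir, gff_path = gff_path,
                 maf_min = maf_min, top_p = top_p,
                 bonferroni_alpha = bonferroni_alpha,
                 min_reps_for_cve = as.integer(min_reps_for_cve)),
            class = "CafePipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()]; the `sim`
#' key holds [simulationConfig()] arguments.
#'
#' @param path YAML file.
#' @return a `CafePipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simargs <- y$sim %||% list()
  if (!is.null(simargs$causal_mean_effects))
    simargs$causal_mean_effects <- lapply(simargs$causal_mean_effects,
                                          as.list)
  if (!is.null(simargs$causal_var_effects))
    simargs$causal_var_effects <- lapply(simargs$causal_var_effects,
                                         as.list)
  y$sim <- do.call(simulationConfig, simargs)
  do.call(pipelineConfig, y)
}

stageStep <- function(report, name, fun) {
  res <- tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  report$stages_run <- c(report$stages_run, name)
  report[[name]] <- res
  report
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the enabled stages in dependency order -- simulate (or load),
#' reduce, variance components, micro-environmental variance, genome-wide
#' association -- writing per-stage artifacts under `out_dir` (when set)
#' and returning a consolidated report.  With fixed seeds the report body
#' is fully reproducible; the run timestamp is stored separately in
#' `report$timestamp` so reports can be compared net of it.
#'
#' @param config a `CafePipelineConfig` (or path to a YAML file).
#' @return list of class `CafeReport` with elements per stage:
#'   `reduce` (line phenotype table), `varcomp` (fits + heritability +
#'   r_GS), `microvar` (variance-heterogeneity tests + correlations),
#'   `gwas` (per-coding association tables), plus `params`, `stages_run`,
#'   `timestamp`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "CafePipelineConfig"))
  report <- list(params = config[setdiff(names(config), "sim")],
                 seed = config$sim$seed, stages_run = character())
  odir <- config$out_dir
  save_tsv <- function(df, name) {
    if (!is.null(odir)) {
      dir.create(odir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(df, file.path(odir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }

  # -- input stage: simulate or load ---------------------------------
  panel <- NULL
  if (!is.null(config$assay_path)) {
    vials <- readAssayTable(config$assay_path)
    controls <- if (!is.null(config$controls_path))
      readEvaporationControls(config$controls_path)
    else data.frame(batch = unique(vials$batch), evap_ul = 0)
    if (!is.null(config$genotype_dir))
      panel <- readGenotypePanel(config$genotype_dir)
  } else {
    if (!"simulate" %in% config$stages)
      stop("stage 'simulate' disabled but no assay_path given")
    sim <- simulateCafePanel(config$sim)
    vials <- sim$vials; controls <- sim$controls; panel <- sim$panel
    report$truth <- sim$truth
    report$stages_run <- c(report$stages_run, "simulate")
  }

  # -- reduce --------------------------------------------------------
  adj <- line_table <- NULL
  if ("reduce" %in% config$stages) {
    report <- stageStep(report, "reduce", function() {
      adj <<- adjustConsumption(vials, controls)
      line_table <<- summarizeLines(adj,
                                    min_reps = config$min_reps_for_cve)
      save_tsv(line_table, "line_summaries.tsv")
      line_table
    })
  }
  if (is.null(adj)) return(structure(report, class = "CafeReport"))

  # -- variance components -------------------------------------------
  if ("varcomp" %in% config$stages) {
    report <- stageStep(report, "varcomp", function() {
      pooled <- fitTwoWayMixed(adj)
      fem <- fitOneWayRandom(adj, "F")
      mal <- fitOneWayRandom(adj, "M")
      list(pooled = pooled, female = fem, male = mal,
           heritability = list(
             H2_pooled = broadSenseHeritability(pooled),
             H2_female = broadSenseHeritability(fem),
             H2_male = broadSenseHeritability(mal)),
           gen_corr = crossSexGeneticCorrelation(adj))
    })
  }

  # -- micro-environmental variance ----------------------------------
  if ("microvar" %in% config$stages) {
    report <- stageStep(report, "microvar", function() {
      tests <- list()
      for (s in c("F", "M")) for (ctr in c("median", "mean")) {
        nm <- paste0(if (ctr == "median") "brown_forsythe" else "levene",
                     "_", if (s == "F") "female" else "male")
        tests[[nm]] <- varianceHeterogeneityTest(adj, sex = s,
                                                 center = ctr)
      }
      list(tests = tests,
           mean_variance = meanVarianceAssociation(
             line_table, min_reps = config$min_reps_for_cve))
    })
  }

  # -- genome-wide association ---------------------------------------
  if ("gwas" %in% config$stages && !is.null(panel)) {
    report <- stageStep(report, "gwas", function() {
      fp <- filterVariants(panel, maf_min = config$maf_min)
      grm <- computeGRM(fp)
      genes <- if (!is.null(config$gff_path))
        readGeneModels(config$gff_path)
      scans <- list()
      for (trait in c("mean", "cv_e")) {
        tvs <- traitVectors(line_table, trait,
                            min_reps = config$min_reps_for_cve)
        for (coding in c("avg", "diff", "female", "male")) {
          tv <- setNames(tvs[[coding]], rownames(tvs))
          ca <- covariateAdjust(tv, fp)
          assoc <- lmmAssociation(ca$adjusted, fp, grm,
                                  top_p = config$top_p,
                                  bonferroni_alpha =
                                    config$bonferroni_alpha)
          if (!is.null(genes)) assoc <- annotateVariants(assoc, genes)
          nm <- paste(trait, coding, sep = "_")
          scans[[nm]] <- assoc
          save_tsv(assoc, paste0("assoc_", nm, ".tsv"))
        }
      }
      top <- do.call(rbind, lapply(names(scans), function(nm) {
        s <- scans[[nm]]
        s <- s[s$top, , drop = FALSE]
        if (nrow(s)) cbind(scan = nm, s) else NULL
      }))
      list(scans = scans, top = top,
           n_variants_tested = nrow(scans[[1]]))
    })
  }

  report$timestamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  structure(report, class = "CafeReport")
}

#' @export
print.CafeReport <- function(x, ...) {
  cat("CAFE line-panel analysis report\n")
  cat("  stages:", paste(x$stages_run, collapse = " -> "), "\n")
  if (!is.null(x$varcomp)) {
    h <- x$varcomp$heritability
    cat(sprintf("  H2 pooled %.3f (F %.3f, M %.3f); r_GS %.3f\n",
                h$H2_pooled, h$H2_female, h$H2_male,
                x$varcomp$gen_corr$r_gs))
  }
  if (!is.null(x$microvar)) {
    lv <- x$microvar$tests$levene_female
    cat(sprintf("  Levene (F): F(%d,%d) = %.3f, P = %.3g\n",
                lv$df1, lv$df2, lv$F, lv$P))
  }
  if (!is.null(x$gwas))
    cat(sprintf("  GWAS: %d variants tested; %d top records\n",
                x$gwas$n_variants_tested,
                if (is.null(x$gwas$top)) 0L else nrow(x$gwas$top)))
  invisible(x)
}

#' Serialize a report to JSON (numbers only, timestamps excluded)
#'
#' @param report a `CafeReport`.
#' @param path optional output file.
#' @return the JSON string, invisibly when written to a file.
#' @export
reportJSON <- function(report, path = NULL) {
  body <- report[setdiff(names(report), c("timestamp", "truth"))]
  scrub <- function(x) {
    if (inherits(x, "cafeVarComp"))
      return(list(components = as.list(x$components),
                  se = as.list(x$se), model = x$model))
    if (inherits(x, "cafeVarHet"))
      return(x[c("test", "sex", "F", "df1", "df2", "P")])
    if (inherits(x, "cafeCorr"))
      return(x[c("labels", "n", "r", "P", "ci")])
    if (inherits(x, "cafeGenCorr"))
      return(x[c("r_gs", "r_pearson", "cov_MF", "n_lines_both")])
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), scrub))
    x
  }
  js <- jsonlite::toJSON(scrub(body), auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
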