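#' GenotypePanel: homozygous line-by-variant genotypes with covariates
#'
#' Container for the genotype side of an inbred line panel: a variants x
#' lines matrix of homozygous genotype codes (0 or 2 copies of the coded
#' allele, `NA` for missing calls), variant coordinates as a
#' [GenomicRanges::GRanges] (with `id` of the form `<chrom>_<pos>_<type>`
#' and `type` in SNP/INS/DEL/MNP), and per-line covariates (Wolbachia
#' infection status and inversion karyotypes) as a [S4Vectors::DataFrame].
#'
#' @slot geno numeric matrix, variants in rows (rownames = variant ids),
#'   lines in columns; values in \{0, 2, NA\}.
#' @slot variants `GRanges`, one range of width 1 per variant, metadata
#'   columns `id` and `type`.
#' @slot lineData `DataFrame` with one row per line (rownames = line ids);
#'   must contain a logical `wolbachia` column, plus any inversion columns.
#'
#' @examples
#' cfg <- simulationConfig(n_lines = 20, n_variants = 50, seed = 1)
#' gp <- simulateGenotypes(cfg)
#' gp
#' head(variantMAF(gp))
#'
#' @aliases GenotypePanel
#' @export
setClass("GenotypePanel",
  representation(geno = "matrix",
                 variants = "GRanges",
                 lineData = "DataFrame"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  g <- object@geno
  if (!all(g[!is.na(g)] %in% c(0, 2)))
    msg <- c(msg, "genotypes must be coded 0/2 (homozygous) or NA")
  if (nrow(g) != length(object@variants))
    msg <- c(msg, "nrow(geno) must equal length(variants)")
  if (ncol(g) != nrow(object@lineData))
    msg <- c(msg, "ncol(geno) must equal nrow(lineData)")
  ids <- object@variants$id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "variants must carry unique 'id' metadata")
  if (!"wolbachia" %in% colnames(object@lineData))
    msg <- c(msg, "lineData must contain a 'wolbachia' column")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param geno variants x lines matrix of 0/2/NA genotype codes.
#' @param variants `GRanges` of variant positions with `id` and `type`
#'   metadata columns (one per row of `geno`).
#' @param lineData `DataFrame` or data.frame of per-line covariates with a
#'   logical `wolbachia` column; rownames are line ids.
#' @return A [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(geno, variants, lineData) {
  if (is.data.frame(lineData)) lineData <- S4Vectors::DataFrame(lineData)
  if (is.null(rownames(geno))) rownames(geno) <- variants$id
  methods::new("GenotypePanel", geno = geno, variants = variants,
               lineData = lineData)
}

#' @describeIn GenotypePanel-class genotype matrix (variants x lines)
#' @param object,x a `GenotypePanel`
#' @export
setGeneric("genoMatrix", function(object) standardGeneric("genoMatrix"))

#' @rdname GenotypePanel-class
#' @export
setMethod("genoMatrix", "GenotypePanel", function(object) object@geno)

#' @describeIn GenotypePanel-class variant coordinates as `GRanges`
#' @export
setGeneric("variantRanges", function(object) standardGeneric("variantRanges"))

#' @rdname GenotypePanel-class
#' @export
setMethod("variantRanges", "GenotypePanel", function(object) object@variants)

#' @describeIn GenotypePanel-class per-line covariate `DataFrame`
#' @export
setGeneric("lineData", function(object) standardGeneric("lineData"))

#' @rdname GenotypePanel-class
#' @export
setMethod("lineData", "GenotypePanel", function(object) object@lineData)

#' @describeIn GenotypePanel-class line identifiers
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))

#' @rdname GenotypePanel-class
#' @export
setMethod("lineIds", "GenotypePanel", function(object) colnames(object@geno))

#' @describeIn GenotypePanel-class variant identifiers
#' @export
setGeneric("variantIds", function(object) standardGeneric("variantIds"))

#' @rdname GenotypePanel-class
#' @export
setMethod("variantIds", "GenotypePanel",
          function(object) object@variants$id)

#' @describeIn GenotypePanel-class minor allele frequency per variant,
#'   computed from non-missing lines (frequency of the rarer allele, in
#'   (0, 0.5]; 0 for monomorphic variants)
#' @export
setGeneric("variantMAF", function(object) standardGeneric("variantMAF"))

#' @rdname GenotypePanel-class
#' @export
setMethod("variantMAF", "GenotypePanel", function(object) {
  f <- rowMeans(object@geno, na.rm = TRUE) / 2
  setNames(pmin(f, 1 - f), variantIds(object))
})

#' @describeIn GenotypePanel-class fraction of missing calls per variant
#' @export
setGeneric("variantMissingness",
           function(object) standardGeneric("variantMissingness"))

#' @rdname GenotypePanel-class
#' @export
setMethod("variantMissingness", "GenotypePanel",
          function(object) setNames(rowMeans(is.na(object@geno)),
                                    variantIds(object)))

#' @rdname GenotypePanel-class
#' @param i,j variant and line subscripts
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  GenotypePanel(x@geno[i, j, drop = FALSE], x@variants[i],
                x@lineData[j, , drop = FALSE])
})

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d variants x %d lines\n",
              nrow(object@geno), ncol(object@geno)))
  maf <- variantMAF(object)
  cat(sprintf("  MAF: median %.3f, range [%.3f, %.3f]; missing calls: %.2f%%\n",
              median(maf), min(maf), max(maf),
              100 * mean(is.na(object@geno))))
  cat(sprintf("  line covariates: %s\n",
              paste(colnames(object@lineData), collapse = ", ")))
})
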