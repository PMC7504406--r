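#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Population labels: the progenitor population every contrast is computed
## against, and the three differentiated myeloid lineages.
.POPULATIONS <- c("progenitor", "erythrocyte", "dendritic", "neutrophil")

## Short lineage codes used in contrast names (each vs progenitor).
.LINEAGES <- c("E", "DC", "N")

.LINEAGE_POPULATION <- c(E = "erythrocyte", DC = "dendritic", N = "neutrophil")

## The nine pattern categories; order fixes the reporting order everywhere.
.CATEGORIES <- c("unique_E", "unique_DC", "unique_N",
                 "common_E_DC", "common_E_N", "common_DC_N",
                 "common_all", "relevant_unclassified", "not_relevant")

## Ground-truth categories a generator can plant (null = no effect).
.TRUTH_CATEGORIES <- c("unique_E", "unique_DC", "unique_N",
                       "common_E_DC", "common_E_N", "common_DC_N",
                       "common_all", "null")

#' ConcentrationMatrix: raw metabolite concentrations with LOD flags
#'
#' A \linkS4class{SummarizedExperiment} holding a metabolites x samples
#' matrix of non-negative concentrations (assay \code{"concentration"},
#' micromolar) together with a logical assay \code{"belowLOD"} flagging
#' measurements that fell below the analyte's limit of detection. Below-LOD
#' cells carry concentration 0 by convention, so the flag and the zero
#' entries always coincide. \code{colData} carries the \code{population}
#' label of each sample (one of \code{progenitor}, \code{erythrocyte},
#' \code{dendritic}, \code{neutrophil}).
#'
#' @seealso [ConcentrationMatrix()] for the constructor,
#'   [readConcentrationMatrix()] to build one from TSV files,
#'   [log2Transform()] for the preprocessing step.
#' @exportClass ConcentrationMatrix
setClass("ConcentrationMatrix", contains = "SummarizedExperiment")

setValidity("ConcentrationMatrix", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("concentration", "belowLOD") %in% an))
        return("assays 'concentration' and 'belowLOD' are required")
    conc <- SummarizedExperiment::assay(object, "concentration")
    lod <- SummarizedExperiment::assay(object, "belowLOD")
    if (!is.numeric(conc) || anyNA(conc) || any(!is.finite(conc)))
        msg <- c(msg, "concentrations must be finite and non-missing")
    else if (any(conc < 0))
        msg <- c(msg, "concentrations must be non-negative")
    if (!is.logical(lod) || anyNA(lod))
        msg <- c(msg, "'belowLOD' must be a logical matrix without NA")
    else if (is.numeric(conc) && !anyNA(conc) &&
             !identical(dim(conc), dim(lod)))
        msg <- c(msg, "'belowLOD' must have the same shape as 'concentration'")
    else if (is.numeric(conc) && !anyNA(conc) && !any(conc < 0) &&
             !all(lod == (conc == 0)))
        msg <- c(msg, "'belowLOD' flags must coincide exactly with zero concentrations")
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    else {
        pop <- SummarizedExperiment::colData(object)$population
        bad <- setdiff(unique(as.character(pop)), .POPULATIONS)
        if (length(bad))
            msg <- c(msg, sprintf("unknown population label(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ConcentrationMatrix
#'
#' @param concentration numeric metabolites x samples matrix of non-negative
#'   concentrations (micromolar); dimnames give metabolite and sample IDs.
#' @param population character vector (one entry per sample) with the
#'   population label of each sample.
#' @param belowLOD optional logical matrix of the same shape flagging
#'   below-LOD cells; defaults to \code{concentration == 0}. Any flagged cell
#'   is forced to concentration 0.
#'
#' @return A [ConcentrationMatrix-class] object.
#' @examples
#' conc <- matrix(c(4, 2, 0, 8), nrow = 2,
#'                dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' cm <- ConcentrationMatrix(conc, population = c("progenitor", "erythrocyte"))
#' belowLOD(cm)
#' @export
ConcentrationMatrix <- function(concentration, population, belowLOD = NULL) {
    concentration <- as.matrix(concentration)
    if (is.null(rownames(concentration)))
        rownames(concentration) <- sprintf("M%04d", seq_len(nrow(concentration)))
    if (is.null(colnames(concentration)))
        colnames(concentration) <- sprintf("S%02d", seq_len(ncol(concentration)))
    if (length(population) != ncol(concentration))
        stop("'population' must have one entry per sample (column)")
    if (is.null(belowLOD)) {
        belowLOD <- concentration == 0
    } else {
        belowLOD <- as.matrix(belowLOD)
        concentration[belowLOD] <- 0
    }
    dimnames(belowLOD) <- dimnames(concentration)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(concentration = concentration, belowLOD = belowLOD),
        colData = S4Vectors::DataFrame(
            population = as.character(population),
            row.names = colnames(concentration)))
    methods::new("ConcentrationMatrix", se)
}

#' LogAbundanceMatrix: log2 abundances with explicit missingness
#'
#' A \linkS4class{SummarizedExperiment} holding log2-transformed metabolite
#' abundances (assay \code{"log2Abundance"}; \code{NA} where the observation
#' was below the LOD and removed) and a per-cell \code{"provenance"} assay
#' (\code{"observed"} or \code{"removed_below_lod"}). No non-finite value is
#' ever left unmasked, so downstream linear-model code never sees a
#' \code{-Inf}.
#'
#' @seealso [log2Transform()], [eligibilityFilter()], [fitGroupMeans()].
#' @exportClass LogAbundanceMatrix
setClass("LogAbundanceMatrix", contains = "SummarizedExperiment")

setValidity("LogAbundanceMatrix", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("log2Abundance", "provenance") %in% an))
        return("assays 'log2Abundance' and 'provenance' are required")
    x <- SummarizedExperiment::assay(object, "log2Abundance")
    prov <- SummarizedExperiment::assay(object, "provenance")
    if (any(!is.na(x) & !is.finite(x)))
        msg <- c(msg, "non-finite log2 values must be masked as NA")
    if (!all(prov %in% c("observed", "removed_below_lod")))
        msg <- c(msg, "provenance must be 'observed' or 'removed_below_lod'")
    if (!all(is.na(x) == (prov == "removed_below_lod")))
        msg <- c(msg, "missing cells must match provenance 'removed_below_lod'")
    if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'population' column")
    if (length(msg)) msg else TRUE
})
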