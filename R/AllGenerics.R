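#' Accessors for the pipeline containers
#'
#' \code{concentrations()} returns the raw concentration matrix (metabolites
#' x samples, micromolar); \code{belowLOD()} the logical LOD mask;
#' \code{populations()} the per-sample population labels; \code{log2Values()}
#' the log2 abundances with \code{NA} at removed cells; \code{missingMask()}
#' the logical missingness mask; \code{provenance()} the per-cell provenance
#' flags.
#'
#' @param object a [ConcentrationMatrix-class] or
#'   [LogAbundanceMatrix-class] object.
#' @return A matrix (or character vector for \code{populations}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))

#' @rdname accessors
#' @export
setGeneric("belowLOD", function(object) standardGeneric("belowLOD"))

#' @rdname accessors
#' @export
setGeneric("populations", function(object) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("log2Values", function(object) standardGeneric("log2Values"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
setMethod("concentrations", "ConcentrationMatrix", function(object)
    SummarizedExperiment::assay(object, "concentration"))

#' @rdname accessors
setMethod("belowLOD", "ConcentrationMatrix", function(object)
    SummarizedExperiment::assay(object, "belowLOD"))

#' @rdname accessors
setMethod("populations", "ConcentrationMatrix", function(object)
    as.character(SummarizedExperiment::colData(object)$population))

#' @rdname accessors
setMethod("populations", "LogAbundanceMatrix", function(object)
    as.character(SummarizedExperiment::colData(object)$population))

#' @rdname accessors
setMethod("log2Values", "LogAbundanceMatrix", function(object)
    SummarizedExperiment::assay(object, "log2Abundance"))

#' @rdname accessors
setMethod("missingMask", "LogAbundanceMatrix", function(object)
    is.na(SummarizedExperiment::assay(object, "log2Abundance")))

#' @rdname accessors
setMethod("provenance", "LogAbundanceMatrix", function(object)
    SummarizedExperiment::assay(object, "provenance"))

setMethod("show", "ConcentrationMatrix", function(object) {
    cat("ConcentrationMatrix:", nrow(object), "metabolites x",
        ncol(object), "samples\n")
    pop <- table(populations(object))
    cat("populations:",
        paste(sprintf("%s (n=%d)", names(pop), as.integer(pop)),
              collapse = ", "), "\n")
    cat(sprintf("below-LOD cells: %d (%.1f%%)\n",
                sum(belowLOD(object)),
                100 * mean(belowLOD(object))))
})

setMethod("show", "LogAbundanceMatrix", function(object) {
    cat("LogAbundanceMatrix:", nrow(object), "metabolites x",
        ncol(object), "samples\n")
    cat(sprintf("missing (removed below LOD): %d cells (%.1f%%)\n",
                sum(missingMask(object)),
                100 * mean(missingMask(object))))
})
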