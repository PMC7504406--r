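#' Read a concentration matrix and sample metadata from TSV
#'
#' The matrix file is wide, one sample per row: columns \code{sample_id},
#' optionally \code{population}, then one column per metabolite. Metabolite
#' cells must be non-negative numbers; the sentinel token \code{"< LOD"}
#' (as exported by some panel software) is accepted and treated as a
#' below-LOD observation. The metadata file has columns \code{sample_id}
#' and \code{population}; every sample in the matrix must appear there.
#'
#' @param matrixPath path to the wide concentration TSV.
#' @param metadataPath path to the sample metadata TSV.
#' @return A validated [ConcentrationMatrix-class], with metabolite column
#'   order preserved and the below-LOD mask set from zero entries and
#'   sentinel cells.
#' @seealso [writeConcentrationMatrix()], [log2Transform()]
#' @export
readConcentrationMatrix <- function(matrixPath, metadataPath) {
    for (p in c(matrixPath, metadataPath))
        if (!file.exists(p)) stop("file not found: ", p)
    wide <- utils::read.delim(matrixPath, check.names = FALSE,
                              colClasses = "character")
    meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(wide))
        stop("matrix file must have a 'sample_id' column")
    if (!all(c("sample_id", "population") %in% names(meta)))
        stop("metadata file must have 'sample_id' and 'population' columns")
    missingSamples <- setdiff(wide$sample_id, meta$sample_id)
    if (length(missingSamples))
        stop("sample(s) absent from metadata: ",
             paste(missingSamples, collapse = ", "))
    pop <- meta$population[match(wide$sample_id, meta$sample_id)]
    badPop <- setdiff(unique(pop), .POPULATIONS)
    if (length(badPop))
        stop("unknown population label(s): ", paste(badPop, collapse = ", "))

    metCols <- setdiff(names(wide), c("sample_id", "population"))
    cells <- as.matrix(wide[, metCols, drop = FALSE])
    sentinel <- array(grepl("^\\s*<\\s*LOD\\s*$", cells, ignore.case = TRUE),
                      dim = dim(cells))
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    vals[sentinel] <- 0
    if (anyNA(vals))
        stop("non-numeric value(s) in metabolite column(s): ",
             paste(unique(metCols[which(is.na(vals), arr.ind = TRUE)[, 2]]),
                   collapse = ", "))
    if (any(vals < 0))
        stop("negative concentration(s) in metabolite column(s): ",
             paste(unique(metCols[which(vals < 0, arr.ind = TRUE)[, 2]]),
                   collapse = ", "))
    conc <- t(vals)                       # metabolites x samples
    dimnames(conc) <- list(metCols, wide$sample_id)
    ConcentrationMatrix(conc, population = pop,
                        belowLOD = conc == 0 | t(sentinel))
}

#' Log2-transform a concentration matrix, removing below-LOD values
#'
#' Concentrations are log2-transformed prior to statistical analysis.
#' Below-LOD observations would produce \code{-Inf}; they are removed,
#' i.e. masked as missing with provenance \code{"removed_below_lod"}, so no
#' non-finite value reaches the downstream model. With
#' \code{dropMode = "metabolite"}, any metabolite with at least one
#' below-LOD cell is instead dropped entirely (the alternative reading of
#' row-wise removal); the default is per-cell removal, which keeps
#' metabolites detectable in some populations.
#'
#' @param raw a [ConcentrationMatrix-class].
#' @param dropMode \code{"cell"} (default) masks individual below-LOD
#'   observations; \code{"metabolite"} drops whole rows containing any.
#' @return A [LogAbundanceMatrix-class].
#' @examples
#' cm <- ConcentrationMatrix(matrix(c(4, 1, 0, 8), nrow = 2,
#'         dimnames = list(c("m1", "m2"), c("s1", "s2"))),
#'         population = c("progenitor", "erythrocyte"))
#' log2Values(log2Transform(cm))
#' @export
log2Transform <- function(raw, dropMode = c("cell", "metabolite")) {
    stopifnot(is(raw, "ConcentrationMatrix"))
    dropMode <- match.arg(dropMode)
    conc <- concentrations(raw)
    mask <- belowLOD(raw)
    if (dropMode == "metabolite") {
        keep <- rowSums(mask) == 0
        conc <- conc[keep, , drop = FALSE]
        mask <- mask[keep, , drop = FALSE]
    }
    x <- matrix(NA_real_, nrow(conc), ncol(conc), dimnames = dimnames(conc))
    x[!mask] <- log2(conc[!mask])
    prov <- matrix("observed", nrow(conc), ncol(conc),
                   dimnames = dimnames(conc))
    prov[mask] <- "removed_below_lod"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2Abundance = x, provenance = prov),
        colData = S4Vectors::DataFrame(
            population = populations(raw),
            row.names = colnames(conc)))
    methods::new("LogAbundanceMatrix", se)
}

#' Per-contrast eligibility after below-LOD removal
#'
#' A metabolite enters a lineage-vs-progenitor contrast only if both groups
#' retain at least \code{minPerGroup} non-missing observations; otherwise
#' that (metabolite, contrast) pair is excluded and reported. Exclusion
#' never removes data: the full matrix is returned unchanged alongside the
#' eligibility call.
#'
#' @param logData a [LogAbundanceMatrix-class].
#' @param minPerGroup minimum non-missing observations required in each of
#'   the two groups of a contrast (>= 2 so a within-group variance is
#'   estimable; default 2).
#' @return A list with \code{data} (the input, unchanged), \code{eligible}
#'   (logical metabolites x 3 matrix, columns \code{E}, \code{DC},
#'   \code{N}) and \code{report} (data.frame of exclusions with columns
#'   \code{metabolite_id}, \code{contrast}, \code{reason}).
#' @export
eligibilityFilter <- function(logData, minPerGroup = 2L) {
    stopifnot(is(logData, "LogAbundanceMatrix"))
    if (!is.numeric(minPerGroup) || length(minPerGroup) != 1 ||
        minPerGroup < 2)
        stop("'minPerGroup' must be at least 2 (a variance needs 2 observations)")
    x <- log2Values(logData)
    pop <- populations(logData)
    nObs <- vapply(.POPULATIONS, function(p)
        rowSums(!is.na(x[, pop == p, drop = FALSE])), numeric(nrow(x)))
    if (nrow(x) == 1) nObs <- matrix(nObs, nrow = 1,
                                     dimnames = list(rownames(x), .POPULATIONS))
    eligible <- matrix(FALSE, nrow(x), length(.LINEAGES),
                       dimnames = list(rownames(x), .LINEAGES))
    report <- list()
    for (lin in .LINEAGES) {
        okProg <- nObs[, "progenitor"] >= minPerGroup
        okLin <- nObs[, .LINEAGE_POPULATION[lin]] >= minPerGroup
        eligible[, lin] <- okProg & okLin
        bad <- which(!(okProg & okLin))
        if (length(bad)) {
            reason <- ifelse(!okProg[bad] & !okLin[bad],
                             "too_few_in_progenitor_and_lineage",
                             ifelse(!okProg[bad], "too_few_in_progenitor",
                                    "too_few_in_lineage"))
            report[[lin]] <- data.frame(metabolite_id = rownames(x)[bad],
                                        contrast = lin, reason = reason,
                                        stringsAsFactors = FALSE)
        }
    }
    report <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE))
              else data.frame(metabolite_id = character(), contrast = character(),
                              reason = character(), stringsAsFactors = FALSE)
    list(data = logData, eligible = eligible, report = report)
}
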