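#' Configuration for the synthetic Biocrates-style panel generator
#'
#' Describes a simulated targeted-metabolomics experiment: four populations
#' (progenitor plus erythrocyte, dendritic-cell and neutrophil lineages) with
#' \code{nReplicates} biological replicates each, measured on a panel of
#' \code{nMetabolites} analytes. A configurable number of metabolites carry
#' planted log2 fold-change effects versus the progenitor (lineage-unique,
#' common to a pair, or common to all three); the remainder are null.
#'
#' Replicate noise is additive Gaussian on the log2 scale (log-normal
#' concentrations), matching the downstream linear model. Each analyte has
#' its own limit of detection, set at the \code{lodQuantile} of its
#' generating distribution; concentrations below it are emitted as 0 and
#' flagged, reproducing the "-Inf after log2" artifact the preprocessing
#' stage must handle.
#'
#' @param nMetabolites panel size (default 514).
#' @param nReplicates biological replicates per population (default 3).
#' @param counts named integer vector of planted-category counts; names from
#'   \code{unique_E}, \code{unique_DC}, \code{unique_N}, \code{common_E_DC},
#'   \code{common_E_N}, \code{common_DC_N}, \code{common_all}. Metabolites
#'   not covered by the counts are null. Defaults to
#'   \code{c(unique_E = 20, unique_DC = 15, unique_N = 40, common_E_DC = 25)}.
#' @param effectSize magnitude of planted log2 fold changes (must exceed 1
#'   so planted categories satisfy their defining inequalities; default 3).
#' @param baselineRange range (log2 micromolar) from which per-metabolite
#'   baseline means are drawn uniformly; default \code{c(-3, 7)} spans the
#'   concentration range of a typical targeted panel.
#' @param replicateSd replicate noise SD on the log2 scale (default 0.4).
#' @param lodQuantile quantile of each metabolite's generating distribution used
#'   as the per-metabolite LOD, in \code{[0, 1)}; 0 disables censoring
#'   (default 0.05).
#' @param seed integer seed; identical seeds give byte-identical output.
#'
#' @return A validated list of class \code{"SimulationConfig"}.
#' @seealso [simulateConcentrations()]
#' @export
simulationConfig <- function(nMetabolites = 514L,
                             nReplicates = 3L,
                             counts = c(unique_E = 20L, unique_DC = 15L,
                                        unique_N = 40L, common_E_DC = 25L),
                             effectSize = 3,
                             baselineRange = c(-3, 7),
                             replicateSd = 0.4,
                             lodQuantile = 0.05,
                             seed = 1L) {
    .checkScalarCount <- function(x, field, min = 1) {
        if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
            x != floor(x))
            stop(sprintf("invalid '%s': must be an integer >= %s", field, min),
                 call. = FALSE)
    }
    .checkScalarCount(nMetabolites, "nMetabolites")
    .checkScalarCount(nReplicates, "nReplicates")
    .checkScalarCount(seed, "seed", min = -2^31)
    if (length(counts)) {
        bad <- setdiff(names(counts), setdiff(.TRUTH_CATEGORIES, "null"))
        if (is.null(names(counts)) || length(bad))
            stop("invalid 'counts': names must be planted categories (",
                 paste(setdiff(.TRUTH_CATEGORIES, "null"), collapse = ", "),
                 ")", call. = FALSE)
        if (any(counts < 0) || any(counts != floor(counts)))
            stop("invalid 'counts': entries must be non-negative integers",
                 call. = FALSE)
        if (sum(counts) > nMetabolites)
            stop("invalid 'counts': sum exceeds 'nMetabolites'", call. = FALSE)
    }
    if (!is.numeric(effectSize) || length(effectSize) != 1 || effectSize <= 1)
        stop("invalid 'effectSize': must exceed 1 so planted categories ",
             "satisfy their defining inequalities", call. = FALSE)
    if (!is.numeric(baselineRange) || length(baselineRange) != 2 ||
        baselineRange[1] > baselineRange[2])
        stop("invalid 'baselineRange': must be an increasing interval",
             call. = FALSE)
    if (!is.numeric(replicateSd) || length(replicateSd) != 1 || replicateSd < 0)
        stop("invalid 'replicateSd': must be a non-negative standard deviation",
             call. = FALSE)
    if (!is.numeric(lodQuantile) || length(lodQuantile) != 1 ||
        lodQuantile < 0 || lodQuantile >= 1)
        stop("invalid 'lodQuantile': must lie in [0, 1)", call. = FALSE)
    full <- stats::setNames(integer(7), setdiff(.TRUTH_CATEGORIES, "null"))
    full[names(counts)] <- as.integer(counts)
    structure(list(nMetabolites = as.integer(nMetabolites),
                   nReplicates = as.integer(nReplicates),
                   counts = full,
                   effectSize = effectSize,
                   baselineRange = baselineRange,
                   replicateSd = replicateSd,
                   lodQuantile = lodQuantile,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simulationConfig()]; \code{counts} may be a
#' nested mapping of category to count. Missing keys take the defaults.
#'
#' @param path path to a YAML file.
#' @return A \code{"SimulationConfig"} object.
#' @export
readSimulationConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(raw), known)
    if (length(bad))
        stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    if (!is.null(raw$counts)) raw$counts <- unlist(raw$counts)
    if (!is.null(raw$baselineRange)) raw$baselineRange <- unlist(raw$baselineRange)
    do.call(simulationConfig, raw)
}

## Per-metabolite limit of detection on the log2 scale: the `q` quantile of
## the metabolite's generating distribution, i.e. the equal-weight normal
## mixture over its per-sample means. Solved by monotone root-finding on the
## mixture CDF; collapses to qnorm for null metabolites (all means equal).
## q = 0 disables censoring. With sd = 0 the quantile of the point-mass
## mixture is taken, so strict below-LOD comparison censors nothing at
## q <= 1/n_samples (the zero-noise limit stays exact).
.lodPerMetabolite <- function(mu, sd, q) {
    nm <- nrow(mu)
    if (q <= 0) return(rep(-Inf, nm))
    vapply(seq_len(nm), function(i) {
        m <- mu[i, ]
        if (sd == 0) return(unname(stats::quantile(m, q, type = 1)))
        if (all(m == m[1])) return(stats::qnorm(q, m[1], sd))
        f <- function(x) mean(stats::pnorm(x, m, sd)) - q
        stats::uniroot(f, lower = min(m) - 10 * sd, upper = max(m) + 10 * sd,
                       tol = 1e-10)$root
    }, numeric(1))
}

## Planted logFC triple (E, DC, N) for one metabolite of a given category.
## `sign` gives the direction shared by the co-regulated lineages.
.plantedTriple <- function(category, effect, sign) {
    e <- sign * effect
    switch(category,
           unique_E = c(e, 0, 0),
           unique_DC = c(0, e, 0),
           unique_N = c(0, 0, e),
           common_E_DC = c(e, e, 0),
           common_E_N = c(e, 0, e),
           common_DC_N = c(0, e, e),
           common_all = c(e, e, e),
           null = c(0, 0, 0))
}

#' Simulate a concentration matrix with known ground truth
#'
#' Generates a four-population design (progenitor + three lineages, with
#' \code{nReplicates} samples each). For metabolite \eqn{m} and sample
#' \eqn{i}, the log2 abundance is
#' \deqn{y_{mi} = b_m + \beta_{m,\ell(i)} + \epsilon_{mi},\quad
#'       \epsilon_{mi} \sim N(0, \sigma^2),}
#' where \eqn{b_m} is the metabolite baseline, \eqn{\beta} the planted
#' lineage effect (0 for progenitor samples and null metabolites) and
#' \eqn{\sigma} the replicate SD. The emitted concentration is
#' \eqn{2^{y_{mi}}}, except that values below the per-metabolite LOD
#' (the \code{lodQuantile} of the metabolite's generating mixture on the
#' log2 scale)
#' become 0 and are flagged below-LOD.
#'
#' The per-metabolite LOD is the \code{lodQuantile} of the metabolite's
#' generating mixture distribution (equal-weight over all samples), so a
#' planted depletion is only partially censored, as on a real panel where
#' the LOD is an assay property rather than a function of the cell state.
#'
#' @param config a \code{"SimulationConfig"} from [simulationConfig()].
#'
#' @return A list with components \code{data}
#'   (a [ConcentrationMatrix-class]) and \code{truth} (a data.frame with
#'   \code{metabolite_id}, \code{category} and the planted
#'   \code{logFC_E}, \code{logFC_DC}, \code{logFC_N}).
#' @examples
#' sim <- simulateConcentrations(simulationConfig(nMetabolites = 50,
#'   counts = c(unique_E = 6, unique_N = 6, common_all = 4), seed = 7))
#' sim$data
#' table(sim$truth$category)
#' @export
simulateConcentrations <- function(config) {
    if (!inherits(config, "SimulationConfig"))
        config <- do.call(simulationConfig, as.list(config))
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)

    nm <- config$nMetabolites
    nr <- config$nReplicates
    ids <- sprintf("M%04d", seq_len(nm))
    categories <- c(rep(names(config$counts), times = config$counts),
                    rep("null", nm - sum(config$counts)))
    signs <- sample(c(-1, 1), nm, replace = TRUE)
    eff <- t(vapply(seq_len(nm), function(i)
        .plantedTriple(categories[i], config$effectSize, signs[i]),
        numeric(3)))
    colnames(eff) <- .LINEAGES

    pops <- rep(.POPULATIONS, each = nr)
    sampleIds <- paste(pops, rep(seq_len(nr), times = 4), sep = "_")
    ## per-sample planted effect, per metabolite (progenitor column of 0s)
    effectBySample <- cbind(matrix(0, nm, nr),
                            matrix(eff[, "E"], nm, nr),
                            matrix(eff[, "DC"], nm, nr),
                            matrix(eff[, "N"], nm, nr))
    baseline <- stats::runif(nm, config$baselineRange[1], config$baselineRange[2])
    mu <- baseline + effectBySample
    y <- mu + stats::rnorm(length(mu), sd = config$replicateSd)
    dim(y) <- dim(mu)

    lod <- .lodPerMetabolite(mu, config$replicateSd, config$lodQuantile)
    censored <- y < lod          # recycles lod down columns (metabolite-wise)
    conc <- 2^y
    conc[censored] <- 0
    dimnames(conc) <- list(ids, sampleIds)

    truth <- data.frame(metabolite_id = ids,
                        category = categories,
                        logFC_E = eff[, "E"],
                        logFC_DC = eff[, "DC"],
                        logFC_N = eff[, "N"],
                        stringsAsFactors = FALSE)
    list(data = ConcentrationMatrix(conc, population = pops,
                                    belowLOD = censored),
         truth = truth)
}

#' Write a ConcentrationMatrix (and metadata) as TSV
#'
#' Writes the wide sample-per-row layout used for data exchange: first
#' columns \code{sample_id} and \code{population}, then one numeric column
#' per metabolite. Below-LOD cells are written as 0 (the reader restores the
#' flag from zeros). A companion two-column metadata table can be written
#' with \code{metadataPath}.
#'
#' @param object a [ConcentrationMatrix-class].
#' @param path output TSV path for the matrix.
#' @param metadataPath optional output TSV path for sample metadata
#'   (\code{sample_id}, \code{population}).
#' @return \code{path}, invisibly.
#' @seealso [readConcentrationMatrix()]
#' @export
writeConcentrationMatrix <- function(object, path, metadataPath = NULL) {
    wide <- data.frame(sample_id = colnames(object),
                       population = populations(object),
                       t(concentrations(object)),
                       check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(metadataPath))
        utils::write.table(wide[, c("sample_id", "population")], metadataPath,
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a ground-truth table as TSV
#'
#' @param truth the \code{truth} data.frame from [simulateConcentrations()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
    utils::write.table(truth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
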