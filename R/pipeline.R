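#' Pipeline configuration
#'
#' Exactly one input source must be given: a simulation block (a
#' \code{"SimulationConfig"}) or a pair of input TSV paths. Thresholds
#' default to the relevance rule (|logFC| > 1, FDR < 0.05).
#'
#' @param simulation optional \code{"SimulationConfig"} from
#'   [simulationConfig()].
#' @param matrixPath,metadataPath optional input TSV paths (see
#'   [readConcentrationMatrix()]).
#' @param logfcThreshold,fdrThreshold relevance thresholds (defaults 1 and
#'   0.05).
#' @param minPerGroup per-group eligibility minimum (default 2).
#' @param fdrFamily \code{"per_contrast"} (default) or \code{"global"}.
#' @param commonRule \code{"both_relevant"} (default) or
#'   \code{"any_relevant"}.
#' @param annotationsPath optional term-annotation TSV for per-lineage
#'   overrepresentation of the relevant sets.
#' @param outputDir directory for stage outputs (created if needed).
#' @param seed optional top-level seed; overrides the simulation block's.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL, matrixPath = NULL,
                           metadataPath = NULL,
                           logfcThreshold = 1, fdrThreshold = 0.05,
                           minPerGroup = 2L,
                           fdrFamily = c("per_contrast", "global"),
                           commonRule = c("both_relevant", "any_relevant"),
                           annotationsPath = NULL,
                           outputDir = tempfile("metaboPatterns_run_"),
                           seed = NULL) {
    haveSim <- !is.null(simulation)
    havePaths <- !is.null(matrixPath) || !is.null(metadataPath)
    if (haveSim == havePaths)
        stop("exactly one of a simulation block or input paths must be given")
    if (havePaths && (is.null(matrixPath) || is.null(metadataPath)))
        stop("both 'matrixPath' and 'metadataPath' are required for file input")
    if (haveSim && !inherits(simulation, "SimulationConfig"))
        simulation <- do.call(simulationConfig, as.list(simulation))
    if (logfcThreshold <= 0 || fdrThreshold <= 0 || fdrThreshold >= 1)
        stop("thresholds must be positive (and FDR threshold inside (0, 1))")
    if (!is.null(seed)) {
        seed <- as.integer(seed)
        if (haveSim) simulation$seed <- seed
    }
    structure(list(simulation = simulation, matrixPath = matrixPath,
                   metadataPath = metadataPath,
                   logfcThreshold = logfcThreshold,
                   fdrThreshold = fdrThreshold,
                   minPerGroup = as.integer(minPerGroup),
                   fdrFamily = match.arg(fdrFamily),
                   commonRule = match.arg(commonRule),
                   annotationsPath = annotationsPath,
                   outputDir = outputDir, seed = seed),
              class = "PipelineConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate-or-read, log2 preprocessing, differential statistics,
#' pattern classification (and per-lineage overrepresentation when
#' annotations are supplied), writing every stage table to
#' \code{outputDir} plus a \code{summary.json} and a \code{manifest.json}
#' recording the configuration, seed and content hashes of the outputs.
#' Identical configuration and seed give identical hashes.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results: \code{data},
#'   \code{contrasts}, \code{assignments}, \code{summary} (category
#'   counts), \code{hyper}, \code{report}, \code{truth} and
#'   \code{recovery} (simulation runs only), \code{enrichment} (if
#'   annotations were supplied) and \code{manifest}.
#' @examples
#' cfg <- pipelineConfig(simulation = simulationConfig(nMetabolites = 40,
#'                       counts = c(unique_E = 5, common_E_DC = 4)),
#'                       outputDir = tempfile(), seed = 7)
#' res <- runPipeline(cfg)
#' res$summary$counts
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outputDir, f)
    written <- character()

    truth <- NULL
    if (!is.null(config$simulation)) {
        sim <- .stage("simulate", simulateConcentrations(config$simulation))
        cm <- sim$data
        truth <- sim$truth
        writeConcentrationMatrix(cm, out("concentrations.tsv"),
                                 out("metadata.tsv"))
        writeGroundTruth(truth, out("ground_truth.tsv"))
        written <- c(written, "concentrations.tsv", "metadata.tsv",
                     "ground_truth.tsv")
    } else {
        cm <- .stage("read", readConcentrationMatrix(config$matrixPath,
                                                     config$metadataPath))
    }

    logData <- .stage("log2_transform", log2Transform(cm))
    stats <- .stage("differential_statistics",
                    contrastStatistics(logData,
                                       minPerGroup = config$minPerGroup,
                                       fdrFamily = config$fdrFamily))
    utils::write.table(stats$contrasts, out("contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(stats$report, out("exclusions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, "contrasts.tsv", "exclusions.tsv")

    rel <- .stage("relevance_filter",
                  relevanceFilter(stats$contrasts,
                                  logfcThreshold = config$logfcThreshold,
                                  fdrThreshold = config$fdrThreshold))
    assignments <- .stage("classify_patterns",
                          classifyPatterns(rel, commonRule = config$commonRule))
    summary <- patternSummary(assignments)
    utils::write.table(assignments, out("assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, "assignments.tsv")

    enrichment <- NULL
    if (!is.null(config$annotationsPath)) {
        enrichment <- .stage("enrichment", {
            ann <- readAnnotations(config$annotationsPath)
            bg <- assignments$metabolite_id
            res <- lapply(.LINEAGES, function(lin) {
                q <- rel$metabolite_id[rel[[paste0("relevant_", lin)]]]
                if (!length(q)) return(NULL)
                fisherOverrepresentation(q, ann, bg)
            })
            names(res) <- .LINEAGES
            res
        })
        for (lin in .LINEAGES) {
            if (is.null(enrichment[[lin]])) next
            f <- sprintf("enrichment_%s.tsv", lin)
            utils::write.table(enrichment[[lin]], out(f), sep = "\t",
                               quote = FALSE, row.names = FALSE)
            written <- c(written, f)
        }
    }

    recovery <- NULL
    if (!is.null(truth)) {
        recovery <- .stage("recovery_report",
                           recoveryReport(assignments, truth))
        utils::write.table(
            data.frame(category = names(recovery$sensitivity),
                       sensitivity = recovery$sensitivity,
                       precision = recovery$precision, row.names = NULL),
            out("recovery.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
        written <- c(written, "recovery.tsv")
    }

    summaryJson <- list(
        category_counts = as.list(summary$counts),
        hyperparameters = list(d0 = stats$hyper$d0, s0_sq = stats$hyper$s0sq),
        n_metabolites = nrow(assignments),
        n_exclusions = nrow(stats$report))
    jsonlite::write_json(summaryJson, out("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, "summary.json")

    manifest <- list(
        config = .configAsList(config),
        seed = config$seed,
        outputs = as.list(tools::md5sum(file.path(config$outputDir, written))))
    names(manifest$outputs) <- written
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(data = cm, contrasts = stats$contrasts,
                   assignments = assignments, summary = summary,
                   hyper = stats$hyper, report = stats$report,
                   truth = truth, recovery = recovery,
                   enrichment = enrichment, manifest = manifest))
}

.configAsList <- function(config) {
    cfg <- unclass(config)
    if (!is.null(cfg$simulation)) {
        sim <- unclass(cfg$simulation)
        sim$counts <- as.list(sim$counts)
        cfg$simulation <- sim
    }
    cfg[!vapply(cfg, is.null, logical(1))]
}

#' Recovery report: assigned categories versus planted ground truth
#'
#' Builds the confusion matrix of planted versus assigned pattern
#' categories (planted \code{null} metabolites map to the
#' \code{not_relevant} row) and per-category sensitivity and precision.
#'
#' @param assignments output of [classifyPatterns()].
#' @param truth ground-truth table from [simulateConcentrations()].
#' @return A list with \code{confusion} (9 x 9 matrix, rows = truth,
#'   columns = assigned), \code{sensitivity} and \code{precision} (named
#'   vectors over the categories; \code{NaN} where a category is empty).
#' @export
recoveryReport <- function(assignments, truth) {
    if (!setequal(assignments$metabolite_id, truth$metabolite_id))
        stop("metabolite IDs in assignments and ground truth do not match")
    truth <- truth[match(assignments$metabolite_id, truth$metabolite_id), ]
    truthCat <- ifelse(truth$category == "null", "not_relevant",
                       truth$category)
    truthCat <- factor(truthCat, levels = .CATEGORIES)
    assigned <- factor(as.character(assignments$category),
                       levels = .CATEGORIES)
    confusion <- table(truth = truthCat, assigned = assigned)
    confusion <- unclass(confusion)
    sens <- diag(confusion) / rowSums(confusion)
    prec <- diag(confusion) / colSums(confusion)
    list(confusion = confusion, sensitivity = sens, precision = prec)
}
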