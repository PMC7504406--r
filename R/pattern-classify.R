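#' Relevance filter: |logFC| > 1 and FDR < 0.05
#'
#' A metabolite is called relevant in a lineage when its contrast versus the
#' progenitor is eligible, its absolute log2 fold change strictly exceeds
#' \code{logfcThreshold} and its FDR-adjusted p-value is strictly below
#' \code{fdrThreshold}. Both inequalities are strict: a logFC of exactly 1
#' is not "above 1".
#'
#' @param contrasts a contrast table with \code{p_fdr} (see [addFDR()]).
#' @param logfcThreshold positive log2 fold-change threshold (default 1).
#' @param fdrThreshold FDR threshold in (0, 1) (default 0.05).
#' @return A per-metabolite \code{data.frame} with columns
#'   \code{metabolite_id}; \code{logFC_E/DC/N}; \code{eligible_E/DC/N};
#'   \code{relevant_E/DC/N} (logical, \code{FALSE} when ineligible).
#' @export
relevanceFilter <- function(contrasts, logfcThreshold = 1,
                            fdrThreshold = 0.05) {
    if (!is.numeric(logfcThreshold) || logfcThreshold <= 0)
        stop("'logfcThreshold' must be positive")
    if (!is.numeric(fdrThreshold) || fdrThreshold <= 0 || fdrThreshold >= 1)
        stop("'fdrThreshold' must lie strictly inside (0, 1)")
    need <- c("metabolite_id", "contrast", "logFC", "p_fdr", "eligible")
    if (!all(need %in% names(contrasts)))
        stop("contrast table must contain columns: ",
             paste(need, collapse = ", "))
    ids <- unique(contrasts$metabolite_id)
    out <- data.frame(metabolite_id = ids, stringsAsFactors = FALSE)
    for (lin in .LINEAGES) {
        sub <- contrasts[contrasts$contrast == lin, ]
        i <- match(ids, sub$metabolite_id)
        out[[paste0("logFC_", lin)]] <- sub$logFC[i]
        out[[paste0("eligible_", lin)]] <- !is.na(sub$eligible[i]) &
            sub$eligible[i]
        rel <- sub$eligible[i] & !is.na(sub$logFC[i]) & !is.na(sub$p_fdr[i]) &
            abs(sub$logFC[i]) > logfcThreshold & sub$p_fdr[i] < fdrThreshold
        out[[paste0("relevant_", lin)]] <- !is.na(rel) & rel
    }
    out
}

## Core rule engine on one metabolite: logfc and relevant are length-3
## vectors ordered (E, DC, N); eligible likewise. Returns the category.
## Precedence: common_all, then unique, then pairwise-common, then the
## relevant-but-unclassified / not-relevant fallbacks. A pairwise delta of
## exactly 1 satisfies neither the "> 1" nor the "< 1" rule.
.classifyOne <- function(logfc, relevant, eligible,
                         commonRule = "both_relevant") {
    logfc <- unname(logfc); relevant <- unname(relevant)
    eligible <- unname(eligible)
    if (!any(relevant)) return("not_relevant")
    if (!all(eligible)) return("relevant_unclassified")
    d <- c(E_DC = abs(logfc[1] - logfc[2]),
           E_N = abs(logfc[1] - logfc[3]),
           DC_N = abs(logfc[2] - logfc[3]))
    if (all(d < 1)) return("common_all")
    pairDelta <- function(i, j) {
        k <- sort(c(i, j))
        d[[paste(.LINEAGES[k[1]], .LINEAGES[k[2]], sep = "_")]]
    }
    uniqueOK <- vapply(1:3, function(i) {
        others <- setdiff(1:3, i)
        relevant[i] && pairDelta(i, others[1]) > 1 && pairDelta(i, others[2]) > 1
    }, logical(1))
    if (any(uniqueOK)) {
        ## several lineages can qualify when all three responses are mutually
        ## distant; take the most separated one (permutation-invariant
        ## tie-break by minimum delta to the others, then effect size)
        minDelta <- vapply(1:3, function(i) {
            others <- setdiff(1:3, i)
            min(pairDelta(i, others[1]), pairDelta(i, others[2]))
        }, numeric(1))
        score <- ifelse(uniqueOK, minDelta + 1e-9 * abs(logfc), -Inf)
        return(paste0("unique_", .LINEAGES[which.max(score)]))
    }
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (pr in pairs) {
        third <- setdiff(1:3, pr)
        relOK <- if (commonRule == "both_relevant") all(relevant[pr])
                 else any(relevant[pr])
        if (relOK && pairDelta(pr[1], pr[2]) < 1 &&
            pairDelta(pr[1], third) > 1 && pairDelta(pr[2], third) > 1)
            return(paste0("common_", .LINEAGES[pr[1]], "_", .LINEAGES[pr[2]]))
    }
    "relevant_unclassified"
}

#' Classify metabolites into unique and common patterns
#'
#' Applies the delta-logFC rules to the relevance-filtered metabolites.
#' Writing \eqn{\Delta\mathrm{logFC}(X, Y)} for the absolute difference of
#' two lineages' logFCs versus the progenitor, the categories are assigned
#' in a fixed precedence order:
#' \enumerate{
#'   \item \emph{common to all} - all three pairwise deltas < 1 (and the
#'     metabolite is relevant somewhere);
#'   \item \emph{unique to X} - X is relevant and its delta to both other
#'     lineages exceeds 1 (when several lineages qualify simultaneously,
#'     the most separated one - largest minimum delta, then largest
#'     absolute logFC - is chosen, a permutation-invariant tie-break);
#'   \item \emph{common to X and Y} - the pair's delta is < 1 while both
#'     deltas to the third lineage exceed 1, and (by default) both paired
#'     lineages are relevant;
#'   \item otherwise \emph{relevant_unclassified} when relevant anywhere,
#'     else \emph{not_relevant}.
#' }
#' A delta of exactly 1 satisfies neither strict rule. A metabolite
#' ineligible in any contrast has undefined deltas and is reported as
#' \code{relevant_unclassified} (if relevant where eligible) or
#' \code{not_relevant}.
#'
#' @param relevance output of [relevanceFilter()].
#' @param commonRule \code{"both_relevant"} (default): a pairwise-common
#'   call requires relevance in both paired lineages;
#'   \code{"any_relevant"}: one suffices.
#' @return A \code{data.frame} (the pattern assignment) with
#'   \code{metabolite_id}, \code{relevant_in} (semicolon-separated),
#'   \code{category} (factor over the nine categories), the three logFCs
#'   and the pairwise \code{delta_E_DC}, \code{delta_E_N},
#'   \code{delta_DC_N}.
#' @examples
#' rel <- data.frame(metabolite_id = "m1",
#'   logFC_E = 2, logFC_DC = 0.5, logFC_N = 0.3,
#'   eligible_E = TRUE, eligible_DC = TRUE, eligible_N = TRUE,
#'   relevant_E = TRUE, relevant_DC = FALSE, relevant_N = FALSE)
#' classifyPatterns(rel)$category
#' @export
classifyPatterns <- function(relevance,
                             commonRule = c("both_relevant", "any_relevant")) {
    commonRule <- match.arg(commonRule)
    lf <- as.matrix(relevance[, paste0("logFC_", .LINEAGES)])
    rel <- as.matrix(relevance[, paste0("relevant_", .LINEAGES)])
    elig <- as.matrix(relevance[, paste0("eligible_", .LINEAGES)])
    n <- nrow(relevance)
    category <- character(n)
    for (i in seq_len(n))
        category[i] <- .classifyOne(lf[i, ], rel[i, ], elig[i, ], commonRule)
    data.frame(metabolite_id = relevance$metabolite_id,
               relevant_in = apply(rel, 1, function(r)
                   paste(.LINEAGES[r], collapse = ";")),
               category = factor(category, levels = .CATEGORIES),
               logFC_E = lf[, 1], logFC_DC = lf[, 2], logFC_N = lf[, 3],
               delta_E_DC = abs(lf[, 1] - lf[, 2]),
               delta_E_N = abs(lf[, 1] - lf[, 3]),
               delta_DC_N = abs(lf[, 2] - lf[, 3]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarise a pattern assignment
#'
#' @param assignments output of [classifyPatterns()].
#' @return A list with \code{counts} (named integer vector over the nine
#'   categories, summing to the panel size), \code{members} (per-category
#'   metabolite ID lists) and \code{uniqueLogFC} (matrix of logFC triples
#'   restricted to the lineage-unique metabolites, for plotting).
#' @export
patternSummary <- function(assignments) {
    counts <- table(assignments$category)
    counts <- stats::setNames(as.integer(counts), names(counts))
    members <- split(assignments$metabolite_id, assignments$category)
    uniq <- assignments$category %in% c("unique_E", "unique_DC", "unique_N")
    uniqueLogFC <- as.matrix(assignments[uniq, paste0("logFC_", .LINEAGES)])
    rownames(uniqueLogFC) <- assignments$metabolite_id[uniq]
    list(counts = counts, members = members, uniqueLogFC = uniqueLogFC)
}
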