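#' Read term-to-feature annotations from TSV
#'
#' The annotation file is two-column TSV (\code{term_id}, \code{feature_id});
#' an optional term-name map is two-column TSV (\code{term_id},
#' \code{term_name}). Duplicate (term, feature) pairs are collapsed.
#'
#' @param path annotation TSV path.
#' @param namesPath optional term-name TSV path.
#' @return A named list of character vectors (term members), with a
#'   \code{"termNames"} attribute when names were supplied.
#' @export
readAnnotations <- function(path, namesPath = NULL) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("term_id", "feature_id") %in% names(ann)))
        stop("annotation file must have 'term_id' and 'feature_id' columns")
    sets <- lapply(split(ann$feature_id, ann$term_id), unique)
    if (!is.null(namesPath)) {
        nm <- utils::read.delim(namesPath, stringsAsFactors = FALSE)
        attr(sets, "termNames") <-
            stats::setNames(nm$term_name, nm$term_id)
    }
    sets
}

#' Fisher's exact overrepresentation test
#'
#' For each term, counts \eqn{k} (query features annotated to the term),
#' \eqn{n} (query size), \eqn{K} (term size in the background) and \eqn{N}
#' (background size) are formed after restricting the term to the
#' background. The one-sided p-value is the upper hypergeometric tail
#' \eqn{P(X \ge k)} and the fold enrichment is \eqn{(k/n)/(K/N)}. Holm
#' step-down adjustment is applied over all terms tested in the run.
#'
#' @param query character vector of feature IDs (must be contained in the
#'   background).
#' @param annotations named list of term member vectors (see
#'   [readAnnotations()]).
#' @param background character vector of background feature IDs.
#' @return A \code{data.frame} with one row per term
#'   (\code{term_id}, \code{term_name}, \code{k}, \code{n}, \code{K},
#'   \code{N}, \code{fold_enrichment}, \code{p_raw}, \code{p_holm}),
#'   sorted by \code{p_holm} then decreasing fold enrichment.
#' @examples
#' bg <- sprintf("g%03d", 1:100)
#' ann <- list(T1 = bg[1:20], T2 = bg[30:34])
#' fisherOverrepresentation(bg[1:10], ann, bg)
#' @export
fisherOverrepresentation <- function(query, annotations, background) {
    background <- unique(background)
    query <- unique(query)
    if (!length(background)) stop("background universe is empty")
    stray <- setdiff(query, background)
    if (length(stray))
        stop("query feature(s) not in background: ",
             paste(stray, collapse = ", "))
    if (is.null(names(annotations)) || !length(annotations))
        stop("'annotations' must be a non-empty named list of term members")
    N <- length(background)
    n <- length(query)
    termNames <- attr(annotations, "termNames")
    rows <- lapply(names(annotations), function(tid) {
        members <- intersect(unique(annotations[[tid]]), background)
        K <- length(members)
        k <- length(intersect(query, members))
        fold <- if (K > 0 && n > 0) (k / n) / (K / N) else 0
        ## upper tail P(X >= k) of Hypergeometric(N, K, n)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term_id = tid,
                   term_name = if (!is.null(termNames) && tid %in% names(termNames))
                       unname(termNames[tid]) else tid,
                   k = k, n = n, K = K, N = N,
                   fold_enrichment = fold, p_raw = p,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$p_holm <- holmAdjust(res$p_raw)
    res[order(res$p_holm, -res$fold_enrichment), , drop = FALSE]
}

#' Holm step-down adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "holm")}: sort
#' ascending, multiply the i-th smallest by \eqn{m - i + 1}, enforce a
#' running maximum, cap at 1, return in the original order.
#'
#' @param p raw p-values in \code{[0, 1]}.
#' @return Adjusted p-values (empty in, empty out).
#' @export
holmAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "holm")
}
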