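# Fixture builders shared across test files.

# A LogAbundanceMatrix straight from a metabolites x samples matrix (NA =
# removed below LOD), bypassing the concentration layer.
makeLogMatrix <- function(x, pop) {
    if (is.null(rownames(x))) rownames(x) <- sprintf("m%02d", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
    conc <- 2^x
    conc[is.na(x)] <- 0
    log2Transform(ConcentrationMatrix(conc, population = pop))
}

fourPops <- function(n = 3) rep(c("progenitor", "erythrocyte",
                                  "dendritic", "neutrophil"), each = n)

# A relevance-filter row in the shape classifyPatterns() expects.
relevanceRow <- function(id, logfc, relevant, eligible = c(TRUE, TRUE, TRUE)) {
    data.frame(metabolite_id = id,
               logFC_E = logfc[1], logFC_DC = logfc[2], logFC_N = logfc[3],
               eligible_E = eligible[1], eligible_DC = eligible[2],
               eligible_N = eligible[3],
               relevant_E = relevant[1], relevant_DC = relevant[2],
               relevant_N = relevant[3],
               stringsAsFactors = FALSE)
}
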