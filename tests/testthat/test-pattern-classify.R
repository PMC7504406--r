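test_that("relevance thresholds are strict and sign-symmetric", {
    ct <- data.frame(metabolite_id = rep(c("a", "b", "c", "d"), each = 3),
                     contrast = rep(c("E", "DC", "N"), 4),
                     logFC = c(1.5, 0, 0,   1.0, 0, 0,   -2.3, 0, 0,  1.4, 0, 0),
                     p_fdr = c(0.01, 1, 1,  0.001, 1, 1, 0.049, 1, 1, 0.05, 1, 1),
                     eligible = TRUE, stringsAsFactors = FALSE)
    rel <- relevanceFilter(ct)
    expect_true(rel$relevant_E[rel$metabolite_id == "a"])
    expect_false(rel$relevant_E[rel$metabolite_id == "b"])  # logFC exactly 1
    expect_true(rel$relevant_E[rel$metabolite_id == "c"])   # absolute value
    expect_false(rel$relevant_E[rel$metabolite_id == "d"])  # FDR exactly 0.05
    expect_error(relevanceFilter(ct, logfcThreshold = 0), "logfcThreshold")
    expect_error(relevanceFilter(ct, fdrThreshold = 1.2), "fdrThreshold")
})

test_that("hand-worked classification examples come out right", {
    # unique to E: relevant only in E, deltas 1.5 and 1.7 both above 1
    a <- classifyPatterns(relevanceRow("a", c(2.0, 0.5, 0.3),
                                       c(TRUE, FALSE, FALSE)))
    expect_equal(as.character(a$category), "unique_E")
    # common to E and DC: delta(E,DC) = 0.4, both deltas to N above 1
    b <- classifyPatterns(relevanceRow("b", c(1.8, 1.4, 0.1),
                                       c(TRUE, TRUE, FALSE)))
    expect_equal(as.character(b$category), "common_E_DC")
    # uniformly depleted: all pairwise deltas below 1
    c3 <- classifyPatterns(relevanceRow("c", c(-1.6, -1.5, -1.4),
                                        c(TRUE, TRUE, TRUE)))
    expect_equal(as.character(c3$category), "common_all")
    # relevant everywhere, deltas (0.5, 1.8, 2.3): the unique rule for N
    # takes precedence over the E/DC pair rule
    d <- classifyPatterns(relevanceRow("d", c(2.0, 2.5, 0.2),
                                       c(TRUE, TRUE, TRUE)))
    expect_equal(as.character(d$category), "unique_N")
    # same deltas but N not relevant: the close pair wins
    d2 <- classifyPatterns(relevanceRow("d2", c(2.0, 2.5, 0.2),
                                        c(TRUE, TRUE, FALSE)))
    expect_equal(as.character(d2$category), "common_E_DC")
})

test_that("boundary delta of exactly 1 satisfies neither strict rule", {
    r <- classifyPatterns(relevanceRow("x", c(2.0, 1.0, 1.0),
                                       c(TRUE, TRUE, TRUE)))
    expect_equal(as.character(r$category), "relevant_unclassified")
})

test_that("ineligible or irrelevant metabolites fall through correctly", {
    r1 <- classifyPatterns(relevanceRow("x", c(2.0, NA, 0.3),
                                        c(TRUE, FALSE, FALSE),
                                        eligible = c(TRUE, FALSE, TRUE)))
    expect_equal(as.character(r1$category), "relevant_unclassified")
    r2 <- classifyPatterns(relevanceRow("y", c(0.2, 0.1, 0),
                                        c(FALSE, FALSE, FALSE)))
    expect_equal(as.character(r2$category), "not_relevant")
    expect_equal(r2$relevant_in, "")
})

test_that("classifier agrees with the brute-force rule evaluator", {
    set.seed(42)
    n <- 1500
    lf <- matrix(runif(3 * n, -3, 3), ncol = 3)
    rel <- matrix(runif(3 * n) < 0.5, ncol = 3)
    relevance <- do.call(rbind, lapply(seq_len(n), function(i)
        relevanceRow(sprintf("m%04d", i), lf[i, ], rel[i, ])))
    got <- as.character(classifyPatterns(relevance)$category)
    want <- vapply(seq_len(n), function(i)
        bruteClassify(lf[i, ], rel[i, ], c(TRUE, TRUE, TRUE)), character(1))
    expect_identical(got, want)
})

test_that("the any_relevant switch relaxes the pairwise-common rule", {
    row <- relevanceRow("x", c(1.8, 1.4, 0.1), c(TRUE, FALSE, FALSE))
    both <- classifyPatterns(row, commonRule = "both_relevant")
    any_ <- classifyPatterns(row, commonRule = "any_relevant")
    expect_equal(as.character(both$category), "relevant_unclassified")
    expect_equal(as.character(any_$category), "common_E_DC")
})

test_that("classification is equivariant under lineage permutations", {
    # relabelling the lineages before classifying must equal classifying
    # first and relabelling the category afterwards
    lin <- c("E", "DC", "N")
    renameCategory <- function(cat, map) {   # map: old label -> new label
        if (grepl("^unique_", cat))
            return(paste0("unique_", map[sub("unique_", "", cat)]))
        if (grepl("^common_", cat) && cat != "common_all") {
            parts <- unname(map[strsplit(sub("common_", "", cat), "_")[[1]]])
            parts <- lin[sort(match(parts, lin))]   # canonical pair order
            return(paste0("common_", paste(parts, collapse = "_")))
        }
        cat
    }
    set.seed(8)
    n <- 100
    lf <- matrix(runif(3 * n, -3, 3), ncol = 3)
    rel <- matrix(runif(3 * n) < 0.5, ncol = 3)
    baseRelevance <- do.call(rbind, lapply(seq_len(n), function(i)
        relevanceRow(sprintf("m%03d", i), lf[i, ], rel[i, ])))
    base <- as.character(classifyPatterns(baseRelevance)$category)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    for (perm in perms) {
        # new lineage k carries old component perm[k]: old label lin[perm[k]]
        # becomes new label lin[k]
        map <- setNames(lin, lin[perm])
        relevance <- do.call(rbind, lapply(seq_len(n), function(i)
            relevanceRow(sprintf("m%03d", i), lf[i, perm], rel[i, perm])))
        got <- as.character(classifyPatterns(relevance)$category)
        want <- vapply(base, renameCategory, character(1), map = map)
        expect_identical(got, unname(want))
    }
})

test_that("pattern summary partitions the panel", {
    set.seed(3)
    n <- 200
    lf <- matrix(runif(3 * n, -3, 3), ncol = 3)
    rel <- matrix(runif(3 * n) < 0.4, ncol = 3)
    relevance <- do.call(rbind, lapply(seq_len(n), function(i)
        relevanceRow(sprintf("m%04d", i), lf[i, ], rel[i, ])))
    assign <- classifyPatterns(relevance)
    s <- patternSummary(assign)
    expect_equal(sum(s$counts), n)
    expect_equal(sort(unlist(s$members, use.names = FALSE)),
                 sort(relevance$metabolite_id))      # no duplicates, no gaps
    expect_equal(nrow(s$uniqueLogFC),
                 sum(s$counts[c("unique_E", "unique_DC", "unique_N")]))
})
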