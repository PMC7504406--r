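# Independent oracles, deliberately coded by different routes than the
# implementation they check.

# Ordinary pooled-variance t via R's lm(): one-way model with treatment
# coding relative to the progenitor, so each lineage coefficient is the
# lineage-vs-progenitor contrast with the pooled residual variance.
oracleLmContrasts <- function(x, pop) {
    pop <- factor(pop, levels = c("progenitor", "erythrocyte",
                                  "dendritic", "neutrophil"))
    out <- lapply(seq_len(nrow(x)), function(i) {
        y <- x[i, ]
        fit <- summary(lm(y ~ pop))$coefficients
        rn <- paste0("pop", c("erythrocyte", "dendritic", "neutrophil"))
        data.frame(contrast = c("E", "DC", "N"),
                   logFC = fit[rn, "Estimate"],
                   t = fit[rn, "t value"],
                   p = fit[rn, "Pr(>|t|)"],
                   row.names = NULL)
    })
    do.call(rbind, out)
}

# Benjamini-Hochberg step-up, straight from the definition:
# adj_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1.
bruteBH <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m))
        adj[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
    adj
}

# Holm step-down from the definition: adj_(i) = max_{j <= i} (m - j + 1) p_(j),
# capped at 1.
bruteHolm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    run <- 0
    for (i in seq_len(m)) {
        run <- max(run, (m - i + 1) * p[o][i])
        adj[o[i]] <- min(1, run)
    }
    adj
}

# Upper hypergeometric tail P(X >= k) by direct enumeration of the pmf.
bruteHyperTail <- function(k, K, N, n) {
    kk <- max(0, k):min(n, K)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# All permutations of 1:n as an (n! x n) matrix, built recursively.
allPermutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- allPermutations(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- setdiff(seq_len(n), k)
        cbind(k, matrix(rest[sub], nrow(sub), n - 1))
    }))
}

# Brute-force pattern classifier: evaluates each category definition as a
# predicate and applies the documented precedence. Inputs are unnamed
# length-3 vectors ordered (E, DC, N).
bruteClassify <- function(logfc, relevant, eligible,
                          commonRule = "both_relevant") {
    lin <- c("E", "DC", "N")
    if (sum(relevant) == 0) return("not_relevant")
    if (sum(eligible) < 3) return("relevant_unclassified")
    delta <- function(i, j) abs(logfc[i] - logfc[j])
    isCommonAll <- delta(1, 2) < 1 && delta(1, 3) < 1 && delta(2, 3) < 1
    if (isCommonAll) return("common_all")
    isUnique <- function(i) {
        o <- setdiff(1:3, i)
        relevant[i] && delta(i, o[1]) > 1 && delta(i, o[2]) > 1
    }
    uniq <- which(vapply(1:3, isUnique, logical(1)))
    if (length(uniq)) {
        # most separated qualifying lineage wins; effect size as tie-break
        sep <- vapply(uniq, function(i) {
            o <- setdiff(1:3, i)
            min(delta(i, o[1]), delta(i, o[2])) + 1e-9 * abs(logfc[i])
        }, numeric(1))
        return(paste0("unique_", lin[uniq[which.max(sep)]]))
    }
    isCommonPair <- function(i, j) {
        third <- setdiff(1:3, c(i, j))
        relOK <- if (commonRule == "both_relevant") relevant[i] && relevant[j]
                 else relevant[i] || relevant[j]
        relOK && delta(i, j) < 1 && delta(i, third) > 1 && delta(j, third) > 1
    }
    for (pr in list(c(1, 2), c(1, 3), c(2, 3)))
        if (isCommonPair(pr[1], pr[2]))
            return(paste0("common_", lin[pr[1]], "_", lin[pr[2]]))
    "relevant_unclassified"
}
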