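#' Per-metabolite group-means linear model
#'
#' Fits, for every metabolite, a one-way group-means model across the four
#' populations: each population has its own mean on the log2 scale and all
#' groups share one residual variance. Means are arithmetic means of the
#' non-missing log2 values; the pooled residual variance is
#' \deqn{s_g^2 = \frac{\sum_{j} \sum_{i} (y_{ij} - \bar y_j)^2}{d_g},\quad
#'       d_g = n_{obs} - \#\{\text{groups with} \ge 1\ \text{observation}\},}
#' with no imputation: missing (below-LOD) cells simply drop out, so the
#' residual degrees of freedom follow the actual unbalanced fit.
#' Metabolites with \eqn{d_g = 0} (no replication anywhere) are flagged and
#' excluded from shrinkage fitting, never an error.
#'
#' @param logData a [LogAbundanceMatrix-class].
#' @return A list of class \code{"GroupMeansFit"}: \code{means} and
#'   \code{nObs} (metabolites x 4 matrices, columns the populations),
#'   \code{s2} and \code{df} (per-metabolite pooled residual variance and
#'   residual df) and \code{noResidualDf} (IDs with \eqn{d_g = 0}).
#' @seealso [estimateHyperparams()], [moderatedStatistics()]
#' @export
fitGroupMeans <- function(logData) {
    stopifnot(is(logData, "LogAbundanceMatrix"))
    x <- log2Values(logData)
    pop <- populations(logData)
    nm <- nrow(x)
    means <- nObs <- matrix(NA_real_, nm, length(.POPULATIONS),
                            dimnames = list(rownames(x), .POPULATIONS))
    ss <- numeric(nm)
    for (p in .POPULATIONS) {
        xp <- x[, pop == p, drop = FALSE]
        n <- rowSums(!is.na(xp))
        m <- rowSums(xp, na.rm = TRUE) / n       # NaN when n == 0
        nObs[, p] <- n
        means[, p] <- m
        ss <- ss + rowSums((xp - m)^2, na.rm = TRUE)
    }
    means[nObs == 0] <- NA_real_
    df <- rowSums(nObs) - rowSums(nObs > 0)
    s2 <- ifelse(df > 0, ss / df, NA_real_)
    structure(list(means = means, nObs = nObs, s2 = s2, df = df,
                   noResidualDf = rownames(x)[df == 0]),
              class = "GroupMeansFit")
}

## Inverse of the trigamma function by bisection: solves trigamma(y) = x.
## trigamma is strictly decreasing on (0, Inf) with range (0, Inf), so the
## root is unique; the bracket is widened geometrically until it straddles
## the root and bisection runs to 1e-8 on the trigamma residual.
.trigammaInverse <- function(x, tol = 1e-8) {
    if (x <= 0) return(Inf)
    y <- 0.5 + 1 / x                       # rough starting point
    lo <- y; hi <- y
    while (trigamma(lo) < x) lo <- lo / 2  # trigamma(lo) must exceed x
    while (trigamma(hi) > x) hi <- hi * 2
    repeat {
        mid <- (lo + hi) / 2
        r <- trigamma(mid) - x
        if (abs(r) < tol || (hi - lo) < 1e-12 * mid) return(mid)
        if (r > 0) lo <- mid else hi <- mid
    }
}

#' Estimate the variance-shrinkage prior by moment matching
#'
#' The empirical-Bayes model places a scaled inverse-chi-square prior
#' \eqn{s_0^2 d_0 / \chi^2_{d_0}} on the true residual variances. Writing
#' \eqn{z_g = \log s_g^2}, the marginal moments of \eqn{z_g} involve the
#' digamma and trigamma functions:
#' \eqn{E[z_g] = \log s_0^2 + \psi(d_g/2) - \log(d_g/2) - \psi(d_0/2) +
#' \log(d_0/2)} (sign conventions folded into the estimator below) and
#' \eqn{Var[z_g] = \psi'(d_g/2) + \psi'(d_0/2)}. Matching the observed mean
#' and variance of the adjusted \eqn{z_g} yields \eqn{d_0} via the trigamma
#' inverse (monotone bisection) and then \eqn{s_0^2} in closed form. When
#' the observed dispersion of the log variances does not exceed what the
#' sampling distributions alone explain, \eqn{d_0 = \infty} and
#' \eqn{s_0^2} is the pooled (arithmetic mean) variance.
#'
#' @param s2 per-metabolite residual variances (from [fitGroupMeans()]).
#' @param df matching residual degrees of freedom.
#' @return A list of class \code{"ShrinkageHyperparams"} with elements
#'   \code{d0} (prior df, possibly \code{Inf}) and \code{s0sq} (prior
#'   variance, log2-squared units).
#' @export
estimateHyperparams <- function(s2, df) {
    usable <- which(!is.na(s2) & df > 0 & s2 > 0)
    if (length(usable) < 2) {
        ## degenerate panel (e.g. noise-free data): almost all variances are
        ## exactly zero, so the common variance is their mean
        withDf <- which(!is.na(s2) & df > 0)
        if (length(withDf) >= 2)
            return(structure(list(d0 = Inf, s0sq = mean(s2[withDf])),
                             class = "ShrinkageHyperparams"))
        stop("fewer than 2 usable residual variances; ",
             "skip shrinkage and use ordinary t-statistics (d0 = 0)")
    }
    s2 <- s2[usable]; df <- df[usable]
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.na(evar) || evar <= 0) {
        ## no excess dispersion: every s2 estimates one common variance,
        ## pooled by the arithmetic mean
        d0 <- Inf
        s0sq <- mean(s2)
    } else {
        d0 <- 2 * .trigammaInverse(evar)
        s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    }
    structure(list(d0 = d0, s0sq = s0sq), class = "ShrinkageHyperparams")
}

#' Moderated t-statistics for the lineage-vs-progenitor contrasts
#'
#' For each metabolite the posterior (shrunken) variance is
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}}
#' (equal to \eqn{s_0^2} in the \eqn{d_0 = \infty} limit and to
#' \eqn{s_g^2} when \eqn{d_0 = 0}, the ordinary-t limit). For each lineage
#' contrast, \eqn{\mathrm{logFC} = \bar y_{lineage} - \bar y_{progenitor}},
#' \deqn{\tilde t = \frac{\mathrm{logFC}}
#'      {\tilde s_g \sqrt{1/n_{lineage} + 1/n_{progenitor}}},}
#' and the two-sided p-value comes from a t distribution on
#' \eqn{d_g + d_0} degrees of freedom (standard normal when infinite).
#' Degenerate zero-variance fits are resolved by the limit: a zero logFC
#' gives \eqn{t = 0} (p = 1), a non-zero one \eqn{t = \pm\infty} (p = 0).
#'
#' @param fit a \code{"GroupMeansFit"} from [fitGroupMeans()].
#' @param eligible logical metabolites x 3 matrix from
#'   [eligibilityFilter()]; ineligible entries carry no statistics.
#' @param hyper a \code{"ShrinkageHyperparams"}, or \code{NULL} to set
#'   \code{d0 = 0} (no shrinkage).
#' @return A long-format \code{data.frame} (the contrast table) with
#'   columns \code{metabolite_id}, \code{contrast} (\code{E}, \code{DC},
#'   \code{N}), \code{logFC}, \code{residual_sd}, \code{posterior_sd},
#'   \code{moderated_t}, \code{df_total}, \code{p_raw} and \code{eligible}.
#' @export
moderatedStatistics <- function(fit, eligible, hyper = NULL) {
    stopifnot(inherits(fit, "GroupMeansFit"))
    if (is.null(hyper)) hyper <- structure(list(d0 = 0, s0sq = NA_real_),
                                           class = "ShrinkageHyperparams")
    d0 <- hyper$d0; s0sq <- hyper$s0sq
    ids <- rownames(fit$means)
    s2 <- fit$s2; dg <- fit$df
    s2tilde <- if (is.infinite(d0)) rep(s0sq, length(s2))
               else if (d0 == 0) s2
               else (d0 * s0sq + dg * s2) / (d0 + dg)
    dfTotal <- dg + d0
    out <- lapply(.LINEAGES, function(lin) {
        popL <- .LINEAGE_POPULATION[lin]
        elig <- eligible[ids, lin]
        logFC <- fit$means[, popL] - fit$means[, "progenitor"]
        se <- sqrt(s2tilde * (1 / fit$nObs[, popL] +
                              1 / fit$nObs[, "progenitor"]))
        t <- logFC / se
        ## zero-variance limit: 0/0 -> 0 (no evidence), x/0 -> signed Inf
        deg <- !is.na(se) & se == 0
        t[deg] <- sign(logFC[deg]) * Inf
        t[deg & logFC == 0] <- 0
        p <- ifelse(is.infinite(dfTotal),
                    2 * stats::pnorm(-abs(t)),
                    2 * stats::pt(-abs(t), df = dfTotal))
        df <- data.frame(metabolite_id = ids, contrast = lin,
                         logFC = logFC,
                         residual_sd = sqrt(s2),
                         posterior_sd = sqrt(s2tilde),
                         moderated_t = t, df_total = dfTotal,
                         p_raw = p, eligible = elig,
                         stringsAsFactors = FALSE, row.names = NULL)
        df[!elig, c("logFC", "residual_sd", "posterior_sd", "moderated_t",
                    "df_total", "p_raw")] <- NA_real_
        df
    })
    do.call(rbind, out)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}, the step-up
#' procedure: sort ascending, multiply the i-th by m/i, enforce a running
#' minimum from the top, cap at 1.
#'
#' @param p raw p-values in \code{[0, 1]}.
#' @return Adjusted p-values in the original order (empty in, empty out).
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Add FDR-adjusted p-values to a contrast table
#'
#' The adjustment family is, by default, the eligible metabolites within
#' one contrast (each lineage adjusted separately); \code{family =
#' "global"} adjusts across all eligible entries of all three contrasts
#' jointly.
#'
#' @param contrasts a contrast table from [moderatedStatistics()].
#' @param family \code{"per_contrast"} (default) or \code{"global"}.
#' @return The contrast table with a \code{p_fdr} column added.
#' @export
addFDR <- function(contrasts, family = c("per_contrast", "global")) {
    family <- match.arg(family)
    contrasts$p_fdr <- NA_real_
    ok <- contrasts$eligible & !is.na(contrasts$p_raw)
    if (family == "global") {
        contrasts$p_fdr[ok] <- bhAdjust(contrasts$p_raw[ok])
    } else {
        for (lin in .LINEAGES) {
            sel <- ok & contrasts$contrast == lin
            contrasts$p_fdr[sel] <- bhAdjust(contrasts$p_raw[sel])
        }
    }
    contrasts
}

#' One-call differential statistics
#'
#' Convenience wrapper chaining [eligibilityFilter()], [fitGroupMeans()],
#' [estimateHyperparams()], [moderatedStatistics()] and [addFDR()].
#'
#' @param logData a [LogAbundanceMatrix-class].
#' @param minPerGroup minimum non-missing observations per group and
#'   contrast (default 2).
#' @param fdrFamily \code{"per_contrast"} (default) or \code{"global"}.
#' @param shrink use empirical-Bayes shrinkage (default \code{TRUE});
#'   \code{FALSE} gives ordinary pooled-variance t-statistics.
#' @return A list with \code{contrasts} (the contrast table including
#'   \code{p_fdr}), \code{fit}, \code{hyper}, \code{eligible} and the
#'   exclusion \code{report}.
#' @examples
#' sim <- simulateConcentrations(simulationConfig(nMetabolites = 60,
#'   counts = c(unique_DC = 8, common_E_DC = 6), seed = 3))
#' res <- contrastStatistics(log2Transform(sim$data))
#' head(res$contrasts)
#' res$hyper$d0
#' @export
contrastStatistics <- function(logData, minPerGroup = 2L,
                               fdrFamily = c("per_contrast", "global"),
                               shrink = TRUE) {
    fdrFamily <- match.arg(fdrFamily)
    elig <- eligibilityFilter(logData, minPerGroup)
    fit <- fitGroupMeans(logData)
    hyper <- if (shrink) estimateHyperparams(fit$s2, fit$df) else NULL
    ct <- moderatedStatistics(fit, elig$eligible, hyper)
    ct <- addFDR(ct, fdrFamily)
    list(contrasts = ct, fit = fit, hyper = hyper,
         eligible = elig$eligible, report = elig$report)
}
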