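#' Likelihood of occurrence: condition enrichment over dyad-containing genes
#'
#' The fold-enrichment statistic L = X / Y with X = |A intersect B| / |B|
#' and Y = |A| / |universe|, where A is the set of genes regulated (up or
#' down) by a condition and B the set of genes whose promoter carries a
#' dyad. L is computed per spacer length (B = B(N)) and overall
#' (B = union of B(N) over all N, i.e. genes with at least one dyad at any
#' spacer length). L = 1 is the value expected when regulation and dyad
#' content are independent; conditions with overall L above a cutoff
#' (default 1.30) are forwarded to the Grubbs screen.
#'
#' @param genes Character vector: the regulated gene set A (must be a
#'   subset of \code{universe}).
#' @param dyadGenesByN List indexed "0".."maxSpacer" of gene-id vectors
#'   (the B(N) sets), as produced by [dyadGeneSets()] (element \code{byN}).
#' @param universe Character vector of all genes with scanned promoters.
#' @param condition,direction Labels stored in the result.
#' @param motifLabel Motif label stored in the result.
#' @return A \linkS4class{LikelihoodResult}; L(N) is NA where |B(N)| = 0.
#' @examples
#' u <- sprintf("g%03d", 1:100)
#' likelihood(u[1:20], list(`5` = u[c(1:4, 30:35)]), u)
#' @export
likelihood <- function(genes, dyadGenesByN, universe,
                       condition = "condition", direction = "up",
                       motifLabel = "ACGT") {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    A <- unique(as.character(genes))
    if (!all(A %in% universe))
        stop("regulated gene set must be a subset of the universe")
    if (!length(A)) stop("empty regulated gene set: P(A) = 0")
    Y <- length(A) / length(universe)

    perN <- vapply(dyadGenesByN, function(B) {
        B <- intersect(unique(as.character(B)), universe)
        if (!length(B)) return(NA_real_)
        (length(intersect(A, B)) / length(B)) / Y
    }, numeric(1))

    Bany <- intersect(unique(unlist(dyadGenesByN, use.names = FALSE)),
                      universe)
    overall <- if (length(Bany))
        (length(intersect(A, Bany)) / length(Bany)) / Y else NA_real_

    nBperN <- vapply(dyadGenesByN, function(B)
        length(intersect(unique(as.character(B)), universe)), integer(1))
    nABperN <- vapply(dyadGenesByN, function(B)
        length(intersect(A, B)), integer(1))

    methods::new("LikelihoodResult",
                 condition = condition, direction = direction,
                 motif = motifLabel, perN = perN, overall = overall,
                 counts = list(nA = length(A),
                               nUniverse = length(universe),
                               nBperN = nBperN, nABperN = nABperN,
                               nBany = length(Bany),
                               nABany = length(intersect(A, Bany))))
}

#' Grubbs statistic for a single outlier
#'
#' G = max_i |x_i - mean| / sd with the sample standard deviation (n - 1
#' denominator). Ties are broken toward the lowest index.
#'
#' @param values Numeric vector, length >= 3, sd > 0.
#' @return List with \code{G}, \code{extreme_index}, \code{mean}, \code{sd}.
#' @export
grubbsStatistic <- function(values) {
    if (length(values) < 3L) stop("need at least 3 values")
    m <- mean(values)
    s <- stats::sd(values)
    if (s == 0) stop("zero standard deviation: no outlier definable")
    dev <- abs(values - m) / s
    i <- which.max(dev)
    list(G = dev[[i]], extreme_index = i, mean = m, sd = s)
}

#' Grubbs critical value
#'
#' \deqn{G_{crit} = \frac{n-1}{\sqrt{n}}
#'   \sqrt{\frac{t^2}{n - 2 + t^2}}}
#' with t the upper critical value of the t distribution on n - 2 df at
#' alpha / (2n) (two-sided) or alpha / n (one-sided). For n = 9 at
#' alpha = 0.05 the two-sided value is 2.215.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level (default 0.05).
#' @param sidedness "two_sided" (default) or "one_sided".
#' @return The critical value.
#' @examples
#' grubbsCritical(9)  # 2.215
#' @export
grubbsCritical <- function(n, alpha = 0.05,
                           sidedness = c("two_sided", "one_sided")) {
    sidedness <- match.arg(sidedness)
    if (n < 3) stop("need n >= 3")
    div <- if (sidedness == "two_sided") 2 * n else n
    t <- stats::qt(1 - alpha / div, df = n - 2)
    (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs outlier screen of a test motif against controls
#'
#' Tests whether the test motif's likelihood is the single outlier among the
#' panel values. The screen is significant only when (a) the extreme point
#' is the test motif itself and (b) G exceeds the critical value — a control
#' motif being the outlier never flags the condition.
#'
#' @param values Named numeric vector of overall likelihoods (one per
#'   motif; names must include \code{testMotif}).
#' @param testMotif Motif being screened (default "ACGT").
#' @param alpha Significance level.
#' @param sidedness Passed to [grubbsCritical()].
#' @return A \linkS4class{GrubbsResult}.
#' @export
grubbsScreen <- function(values, testMotif = "ACGT", alpha = 0.05,
                         sidedness = c("two_sided", "one_sided")) {
    sidedness <- match.arg(sidedness)
    if (is.null(names(values)) || !testMotif %in% names(values))
        stop("values must be named and include the test motif")
    st <- grubbsStatistic(values)
    crit <- grubbsCritical(length(values), alpha, sidedness)
    methods::new("GrubbsResult",
                 values = values, testMotif = testMotif,
                 G = st$G, extremeIndex = as.integer(st$extreme_index),
                 critical = crit, alpha = alpha, sidedness = sidedness,
                 significant = (names(values)[st$extreme_index] ==
                                testMotif) && st$G > crit,
                 center = st$mean, scale = st$sd)
}

#' Screen conditions for motif-specific enrichment
#'
#' For every condition, computes the overall likelihood of occurrence for
#' the test motif and each control motif; conditions whose test-motif
#' likelihood exceeds \code{cutoff} (default 1.30) are subjected to the
#' Grubbs outlier screen across the panel.
#'
#' @param conditions List of condition sets, each a list with elements
#'   \code{condition}, \code{direction} and \code{genes} (see
#'   [generateConditionSets()] or [readConditionManifest()]).
#' @param panel Result of [dyadGeneSets()]: per motif, the B(N) gene sets.
#'   Must contain \code{testMotif} and at least 2 other motifs.
#' @param universe All genes with scanned promoters.
#' @param testMotif The motif under test (default "ACGT").
#' @param alpha Grubbs significance level (default 0.05).
#' @param cutoff Likelihood gate for the Grubbs stage (default 1.30).
#' @param sidedness Grubbs sidedness.
#' @return data.frame: one row per condition with the likelihood per motif
#'   (columns \code{L_<motif>}), \code{gate_passed}, and for gated
#'   conditions \code{G}, \code{critical} and \code{significant}.
#' @export
conditionScreen <- function(conditions, panel, universe,
                            testMotif = "ACGT", alpha = 0.05,
                            cutoff = 1.30,
                            sidedness = c("two_sided", "one_sided")) {
    sidedness <- match.arg(sidedness)
    if (!testMotif %in% names(panel))
        stop("panel must contain the test motif")
    if (length(panel) < 3L)
        stop("panel must contain the test motif and at least 2 controls")
    rows <- lapply(conditions, function(cs) {
        L <- vapply(names(panel), function(mm)
            overallLikelihood(likelihood(
                cs$genes, panel[[mm]]$byN, universe,
                condition = cs$condition, direction = cs$direction,
                motifLabel = mm)), numeric(1))
        gate <- !is.na(L[[testMotif]]) && L[[testMotif]] > cutoff
        G <- crit <- NA_real_
        sig <- FALSE
        if (gate) {
            gr <- grubbsScreen(L, testMotif = testMotif, alpha = alpha,
                               sidedness = sidedness)
            G <- gr@G; crit <- gr@critical; sig <- gr@significant
        }
        out <- data.frame(condition = cs$condition,
                          direction = cs$direction,
                          stringsAsFactors = FALSE)
        for (mm in names(panel)) out[[paste0("L_", mm)]] <- L[[mm]]
        out$gate_passed <- gate
        out$G <- G
        out$critical <- crit
        out$significant <- sig
        out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Read a condition manifest and its gene lists
#'
#' The manifest is a TSV with columns \code{condition}, \code{direction},
#' \code{path}; each path points to a plain-text gene list, one id per line.
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return List of condition sets suitable for [conditionScreen()].
#' @export
readConditionManifest <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    man <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("condition", "direction", "path")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    base <- dirname(path)
    lapply(seq_len(nrow(man)), function(i) {
        p <- man$path[i]
        if (!file.exists(p)) p <- file.path(base, man$path[i])
        if (!file.exists(p)) stop("gene list not found: ", man$path[i])
        ids <- readLines(p)
        ids <- trimws(ids[nzchar(trimws(ids))])
        list(condition = man$condition[i], direction = man$direction[i],
             genes = unique(ids))
    })
}
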