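#' Percentile-whisker peak and dip calling on a spacer profile
#'
#' Mirrors a 10--90% box-and-whiskers reading of the 31-value profile:
#' spacer lengths whose count lies strictly above the 90th-percentile
#' whisker are potential peaks; strictly below the 10th, potential dips.
#' Percentiles use linear interpolation between order statistics
#' (\code{stats::quantile} type 7).
#'
#' @param counts Numeric vector of dyad counts indexed by spacer length
#'   (names taken as N when present, otherwise 0..length-1), or a
#'   \linkS4class{SpacerProfile}.
#' @param low,high Whisker percentiles, defaults 10 and 90.
#' @return A \linkS4class{PercentileOutliers}.
#' @examples
#' percentileOutliers(c(100, rep(2, 30)))
#' @export
percentileOutliers <- function(counts, low = 10, high = 90) {
    if (methods::is(counts, "SpacerProfile")) counts <- dyadCounts(counts)
    if (length(counts) < 5L) stop("need at least 5 values")
    if (low >= high) stop("low percentile must be below high")
    N <- if (!is.null(names(counts))) as.integer(names(counts))
         else seq_along(counts) - 1L
    q <- stats::quantile(counts, probs = c(low, high) / 100,
                         type = 7, names = FALSE)
    methods::new("PercentileOutliers",
                 lowPct = low, highPct = high,
                 lowWhisker = q[1L], highWhisker = q[2L],
                 peaks = N[counts > q[2L]], dips = N[counts < q[1L]])
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient r.
#' @export
pearsonR <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("need at least 3 points")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("correlation undefined for a zero-variance vector")
    stats::cor(x, y, method = "pearson")
}

#' t statistic for a Pearson correlation
#'
#' \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} on n - 2 degrees of freedom.
#'
#' @param r Correlation coefficient, |r| <= 1.
#' @param n Number of paired observations (>= 3).
#' @return The t statistic (signed; +/-Inf with a warning when |r| = 1).
#' @examples
#' tFromR(0.974, 6)  # 8.599
#' @export
tFromR <- function(r, n) {
    if (n < 3) stop("need n >= 3")
    if (abs(r) > 1) stop("|r| must be <= 1")
    if (abs(r) == 1) {
        warning("|r| = 1: t statistic is infinite")
        return(sign(r) * Inf)
    }
    r * sqrt((n - 2) / (1 - r^2))
}

#' Two-sided p-value for a t statistic
#'
#' @param t The t statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Two-sided tail probability.
#' @examples
#' pFromT(8.599, 4)  # 0.0010
#' @export
pFromT <- function(t, df) {
    if (df < 1) stop("df must be >= 1")
    2 * stats::pt(-abs(t), df)
}

#' Sliding-window Pearson correlation between two spacer profiles
#'
#' Enumerates every window of consecutive spacer lengths of width
#' \code{minWidth} up to the full profile length, correlates the two
#' profiles within each window and attaches t and two-sided p
#' (df = width - 2). The full-length window is the whole-profile
#' correlation. Windows where either profile is constant are skipped with a
#' warning. Correlation is invariant to per-1000 scaling, so raw counts and
#' normalised profiles give identical r.
#'
#' @param a,b Numeric vectors indexed by the same spacer lengths, or
#'   \linkS4class{SpacerProfile}s of equal maxSpacer.
#' @param minWidth Minimum window width (default 6).
#' @return data.frame with columns \code{start_N}, \code{width}, \code{r},
#'   \code{t}, \code{p}.
#' @export
windowCorrelations <- function(a, b, minWidth = 6) {
    if (methods::is(a, "SpacerProfile")) a <- dyadCounts(a)
    if (methods::is(b, "SpacerProfile")) b <- dyadCounts(b)
    if (length(a) != length(b)) stop("profiles must have equal length")
    L <- length(a)
    if (minWidth < 3L) stop("minWidth must be >= 3")
    if (minWidth > L) stop("minWidth exceeds profile length")
    Ns <- if (!is.null(names(a))) as.integer(names(a)) else 0:(L - 1L)
    rows <- list(); skipped <- 0L
    for (w in minWidth:L) {
        for (s in 1:(L - w + 1L)) {
            xs <- a[s:(s + w - 1L)]; ys <- b[s:(s + w - 1L)]
            if (stats::var(xs) == 0 || stats::var(ys) == 0) {
                skipped <- skipped + 1L
                next
            }
            r <- stats::cor(xs, ys)
            t <- if (abs(r) >= 1) sign(r) * Inf else tFromR(r, w)
            rows[[length(rows) + 1L]] <- data.frame(
                start_N = Ns[s], width = w, r = r, t = t,
                p = pFromT(t, w - 2L))
        }
    }
    if (skipped)
        warning(sprintf("%d zero-variance window(s) skipped", skipped))
    if (!length(rows))
        return(data.frame(start_N = integer(0), width = integer(0),
                          r = numeric(0), t = numeric(0), p = numeric(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Best window per width
#'
#' From a [windowCorrelations()] table, the window with the highest r at
#' each width — the "most conserved run of spacer lengths" summary.
#'
#' @param windows data.frame from [windowCorrelations()].
#' @return One row per width, ordered by width.
#' @export
bestWindows <- function(windows) {
    if (!nrow(windows)) return(windows)
    picked <- do.call(rbind, lapply(split(windows, windows$width),
                                    function(d) d[which.max(d$r), ]))
    rownames(picked) <- NULL
    picked[order(picked$width), ]
}

#' Restrict a scan to a gene subset (ortholog group or condition set)
#'
#' Rebuilds the spacer-frequency profile over a subset of the scanned genes,
#' e.g. the members of an ortholog group in one species, or a
#' condition-regulated gene list. Gene ids not present in the scanned
#' universe are skipped with a warning reporting how many. The per-gene
#' average frequency at each N is counts / nPromoters (i.e. perThousand /
#' 1000).
#'
#' @param scan Result of [scanSet()] (needs \code{hits} and
#'   \code{universe}).
#' @param geneIds Character vector of gene ids to keep.
#' @return A \linkS4class{SpacerProfile} over the subset (nPromoters = number
#'   of retained gene ids).
#' @export
subsetProfile <- function(scan, geneIds) {
    if (!all(c("hits", "universe", "profile") %in% names(scan)))
        stop("scan must be the result of scanSet()")
    geneIds <- unique(as.character(geneIds))
    unknown <- setdiff(geneIds, scan$universe)
    if (length(unknown)) {
        warning(sprintf("%d gene id(s) not in the scanned set; skipped",
                        length(unknown)))
        geneIds <- setdiff(geneIds, unknown)
    }
    if (!length(geneIds)) stop("no known gene ids in subset")
    maxN <- maxSpacer(scan$profile)
    hits <- scan$hits[scan$hits$gene_id %in% geneIds, , drop = FALSE]
    nm <- as.character(0:maxN)
    counts <- stats::setNames(integer(maxN + 1L), nm)
    geneCounts <- counts
    if (nrow(hits)) {
        counts[] <- as.integer(table(factor(hits$N, levels = 0:maxN)))
        geneCounts[] <- as.integer(table(factor(
            hits$N[!duplicated(paste(hits$gene_id, hits$N))],
            levels = 0:maxN)))
    }
    methods::new("SpacerProfile", motif = motif(scan$profile),
                 counts = counts, geneCounts = geneCounts,
                 nPromoters = length(geneIds),
                 speciesLabel = speciesLabel(scan$profile))
}
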