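## Deterministic per-promoter substream seed, kept within 32-bit range so
## subsets of a generated set are reproducible independently of order.
.subSeed <- function(seed, i, salt = 0L) {
    as.integer((as.double(seed) * 48271 + i * 10007 + salt) %% 2147483629)
}

#' Generate background promoter sequences
#'
#' i.i.d. bases with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2. The
#' default GC fraction of 0.36 emulates the Arabidopsis genome-wide GC
#' content. Deterministic under a fixed seed; each promoter uses its own
#' derived substream, so any subset of the set is reproducible.
#'
#' @param nPromoters Number of promoters.
#' @param promoterLength Length of each promoter in nt (default 1000).
#' @param gcFraction Background GC fraction in (0, 1) — 1.0 and values
#'   arbitrarily close to 0/1 are permitted for degenerate fixtures.
#' @param seed Integer seed (mandatory).
#' @param speciesLabel Label stored in the result.
#' @return A \linkS4class{PromoterSet} with gene ids g00001, g00002, ...
#' @export
generateBackground <- function(nPromoters, promoterLength = 1000,
                               gcFraction = 0.36, seed,
                               speciesLabel = "synthetic") {
    if (missing(seed)) stop("seed is mandatory")
    if (gcFraction <= 0 || gcFraction > 1)
        stop("gcFraction must be in (0, 1]")
    probs <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
               G = gcFraction / 2, T = (1 - gcFraction) / 2)
    seqs <- vapply(seq_len(nPromoters), function(i) {
        set.seed(.subSeed(seed, i))
        paste(sample(names(probs), promoterLength, replace = TRUE,
                     prob = probs), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("g%05d", seq_len(nPromoters))
    PromoterSet(seqs, speciesLabel = speciesLabel,
                requestedLength = promoterLength)
}

#' Plant motif dyads into a promoter set
#'
#' For each promoter and each requested spacer length N, draws a number of
#' dyad constructs (Poisson with mean \code{plantRates[N]}, or exactly
#' \code{round(plantRates[N])} when \code{fixedCounts = TRUE}), places them
#' at uniformly chosen non-overlapping offsets and overwrites the bases with
#' motif + random spacer + motif. The authoritative ground truth is the
#' post-rescan profile — the scanner's own output on the final sequences —
#' because background sequence can contribute incidental occurrences and
#' adjacent constructs can pair with each other.
#'
#' @param x A \linkS4class{PromoterSet}.
#' @param plantRates Named numeric vector: names are spacer lengths N,
#'   values are expected dyads per promoter.
#' @param motif Motif to plant (default "ACGT").
#' @param seed Integer seed (mandatory).
#' @param maxSpacer Spacer range used for the post-rescan profile.
#' @param gcFraction GC fraction for the random spacer fill (default 0.36).
#' @param fixedCounts Plant exactly round(rate) constructs per promoter
#'   instead of Poisson draws.
#' @return List with \code{promoters} (the modified
#'   \linkS4class{PromoterSet}), \code{planted} (data.frame gene_id, N,
#'   start, spacer) and \code{postScan} (the [scanSet()] result on the final
#'   sequences, whose \code{profile} is the testing oracle).
#' @export
plantDyads <- function(x, plantRates, motif = "ACGT", seed,
                       maxSpacer = 30, gcFraction = 0.36,
                       fixedCounts = FALSE) {
    stopifnot(methods::is(x, "PromoterSet"))
    if (missing(seed)) stop("seed is mandatory")
    checkMotif(motif)
    Ns <- as.integer(names(plantRates))
    if (anyNA(Ns) || any(Ns < 0))
        stop("plantRates must be named by non-negative spacer lengths")
    m <- nchar(motif)
    probs <- c(A = (1 - gcFraction) / 2, C = gcFraction / 2,
               G = gcFraction / 2, T = (1 - gcFraction) / 2)
    seqs <- as.character(x@sequences)
    ids <- names(x@sequences)
    planted <- list()

    for (i in seq_along(seqs)) {
        set.seed(.subSeed(seed, i, salt = 500009L))
        L <- nchar(seqs[i])
        occupied <- logical(L)
        chars <- strsplit(seqs[i], "")[[1L]]
        for (k in seq_along(Ns)) {
            N <- Ns[k]
            len <- 2L * m + N
            if (len > L)
                stop("promoter ", ids[i], " too short for a construct of ",
                     "total length ", len)
            cnt <- if (fixedCounts) as.integer(round(plantRates[k]))
                   else stats::rpois(1L, plantRates[k])
            for (rep in seq_len(cnt)) {
                cs <- cumsum(occupied)
                cand <- seq_len(L - len + 1L)
                free <- (cs[cand + len - 1L] -
                         c(0, cs)[cand]) == 0L
                cand <- cand[free]
                if (!length(cand))
                    stop("cannot place construct without overlap in ",
                         "promoter ", ids[i])
                s <- if (length(cand) == 1L) cand else sample(cand, 1L)
                spacer <- if (N > 0L)
                    paste(sample(names(probs), N, replace = TRUE,
                                 prob = probs), collapse = "") else ""
                chars[s:(s + len - 1L)] <-
                    strsplit(paste0(motif, spacer, motif), "")[[1L]]
                occupied[s:(s + len - 1L)] <- TRUE
                planted[[length(planted) + 1L]] <- data.frame(
                    gene_id = ids[i], N = N, start = s, spacer = spacer,
                    stringsAsFactors = FALSE)
            }
        }
        seqs[i] <- paste(chars, collapse = "")
    }
    out <- PromoterSet(seqs, speciesLabel = x@speciesLabel,
                       requestedLength = x@requestedLength)
    plantedDf <- if (length(planted)) do.call(rbind, planted)
                 else data.frame(gene_id = character(0), N = integer(0),
                                 start = integer(0), spacer = character(0),
                                 stringsAsFactors = FALSE)
    list(promoters = out, planted = plantedDf,
         postScan = scanSet(out, motif, maxSpacer = maxSpacer))
}

#' Generate a condition gene set with a known true enrichment
#'
#' Each dyad-carrying gene is regulated with probability fold * p; the
#' regulation probability of the remaining genes is chosen so the marginal
#' regulation rate equals p. The true overall likelihood of occurrence of
#' the construction is therefore fold (up to sampling noise).
#'
#' @param universe All gene ids.
#' @param dyadGenes Gene ids carrying at least one dyad (the B set).
#' @param pRegulated Marginal probability that a gene is regulated.
#' @param fold True enrichment factor (fold * pRegulated must be <= 1 and
#'   the implied off-set probability must lie in [0, 1]).
#' @param seed Integer seed (mandatory).
#' @param condition,direction Labels for the resulting set.
#' @return Condition set: list(condition, direction, genes).
#' @export
generateConditionSets <- function(universe, dyadGenes, pRegulated, fold,
                                  seed, condition = "synthetic",
                                  direction = "up") {
    if (missing(seed)) stop("seed is mandatory")
    universe <- unique(as.character(universe))
    dyadGenes <- intersect(unique(as.character(dyadGenes)), universe)
    pB <- length(dyadGenes) / length(universe)
    pIn <- fold * pRegulated
    if (pIn > 1) stop("fold * pRegulated exceeds 1: infeasible")
    q <- if (pB < 1) pRegulated * (1 - fold * pB) / (1 - pB) else pIn
    if (q < 0 || q > 1)
        stop("implied regulation probability for non-dyad genes is ",
             "outside [0, 1]: infeasible fold/pRegulated/|B| combination")
    set.seed(seed)
    inB <- universe %in% dyadGenes
    p <- ifelse(inB, pIn, q)
    keep <- stats::runif(length(universe)) < p
    list(condition = condition, direction = direction,
         genes = universe[keep])
}

#' Generate a family of "species" with correlated planted spacer profiles
#'
#' All species share a base planting-rate vector, perturbed per species by
#' independent multiplicative lognormal noise (unit mean); the expected
#' cross-species correlation of the resulting spacer profiles decreases as
#' \code{profileNoise} grows. Gene ids are aligned 1:1 across species, so
#' the identity map serves as a trivial ortholog table.
#'
#' @param kSpecies Number of species (>= 2).
#' @param nPromoters Promoters per species.
#' @param plantRates Named base rate vector (names = spacer lengths).
#' @param profileNoise Standard deviation of the log-normal perturbation
#'   (0 = identical expected profiles).
#' @param seed Integer seed (mandatory).
#' @param promoterLength,gcFraction,motif,maxSpacer Passed to the
#'   generators.
#' @return Named list (species1, species2, ...), each element the
#'   [plantDyads()] result for that species plus its perturbed \code{rates}.
#' @export
generateSpeciesFamily <- function(kSpecies, nPromoters, plantRates,
                                  profileNoise = 0, seed,
                                  promoterLength = 1000,
                                  gcFraction = 0.36, motif = "ACGT",
                                  maxSpacer = 30) {
    if (missing(seed)) stop("seed is mandatory")
    if (kSpecies < 2) stop("need at least 2 species")
    out <- vector("list", kSpecies)
    for (s in seq_len(kSpecies)) {
        set.seed(.subSeed(seed, s, salt = 900001L))
        noise <- if (profileNoise > 0)
            exp(stats::rnorm(length(plantRates), 0, profileNoise) -
                profileNoise^2 / 2) else rep(1, length(plantRates))
        rates <- plantRates * noise
        bg <- generateBackground(nPromoters, promoterLength, gcFraction,
                                 seed = .subSeed(seed, s, salt = 910001L),
                                 speciesLabel = sprintf("species%d", s))
        pl <- plantDyads(bg, rates, motif = motif,
                         seed = .subSeed(seed, s, salt = 920001L),
                         maxSpacer = maxSpacer, gcFraction = gcFraction)
        pl$rates <- rates
        out[[s]] <- pl
    }
    names(out) <- sprintf("species%d", seq_len(kSpecies))
    out
}
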