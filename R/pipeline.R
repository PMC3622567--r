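#' Read a pipeline configuration file
#'
#' YAML with flat keys; anything omitted falls back to the package defaults
#' (motif ACGT, the eight control motifs, max_spacer 30, all_pairs mode,
#' thresholds 25/40, whiskers 10/90, min window width 6, cutoff 1.30,
#' alpha 0.05, requested_length 1000). The \code{species} key is a list of
#' entries with \code{label} and either \code{promoters} (a promoter FASTA
#' written by [writePromoters()]) or \code{fasta} + \code{annotation} +
#' \code{format}.
#'
#' @param path YAML file path.
#' @return A config list with all defaults filled in.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    cfg <- yaml::read_yaml(path)
    fillPipelineDefaults(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg A (possibly partial) config list.
#' @export
fillPipelineDefaults <- function(cfg) {
    defaults <- list(
        motif = "ACGT", controls = controlMotifs(), max_spacer = 30L,
        mode = "all_pairs", pct_gc = 25, pct_at = 40,
        whisker_low = 10, whisker_high = 90, min_width = 6L,
        cutoff = 1.30, alpha = 0.05, requested_length = 1000L,
        seed = 1L, output_dir = "dyadspacer_out",
        ortholog_table = NULL, conditions = NULL)
    for (k in names(defaults))
        if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
    if (is.null(cfg$species) || !length(cfg$species))
        stop("config must list at least one species")
    cfg
}

## short deterministic fingerprint of the effective configuration,
## embedded in every output header so tables are traceable to their run
.configHash <- function(cfg) {
    cfg$output_dir <- NULL  # content-irrelevant: same config, any location
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(yaml::as.yaml(cfg[order(names(cfg))]), f)
    unname(tools::md5sum(f))
}

.writeTsv <- function(df, path, meta) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (k in names(meta))
        writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.loadSpecies <- function(sp, cfg) {
    if (!is.null(sp$promoters)) return(readPromoters(sp$promoters))
    store <- loadGenome(sp$fasta)
    genes <- loadAnnotation(sp$annotation,
                            format = if (is.null(sp$format)) "tsv"
                                     else sp$format)
    extractUpstream(store, genes, requestedLength = cfg$requested_length,
                    speciesLabel = sp$label)
}

#' Run the full dyad analysis pipeline
#'
#' Loads (or extracts) promoters per species, scans the full motif panel,
#' and writes: per-species spacer-frequency profile tables, percentile
#' peak/dip tables, pairwise window-correlation tables with the best window
#' per width, spacer composition and consensus tables for the test motif,
#' ortholog-restricted profile correlations (when an ortholog table is
#' supplied) and the condition enrichment/Grubbs table (when a condition
#' manifest is supplied). Every table carries `# key=value` provenance
#' comments including a hash of the effective configuration. A failing
#' stage aborts with the stage name and removes files written so far.
#'
#' @param config A config list (see [fillPipelineDefaults()]) or the path to
#'   a YAML config.
#' @return A \code{ReportBundle}: list with \code{files} (named output
#'   paths), the in-memory result objects, and \code{config}.
#' @export
runPipeline <- function(config) {
    cfg <- if (is.character(config)) readPipelineConfig(config)
           else fillPipelineDefaults(config)
    outDir <- cfg$output_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    written <- character(0)
    meta <- list(tool = "dyadSpacer",
                 version = as.character(utils::packageVersion("dyadSpacer")),
                 config_hash = .configHash(cfg))
    stage <- function(name, expr) {
        tryCatch(force(expr), error = function(e) {
            unlink(written)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
    }
    emit <- function(df, file) {
        p <- .writeTsv(df, file.path(outDir, file), meta)
        written <<- c(written, p)
        p
    }
    panelMotifs <- unique(c(cfg$motif, cfg$controls))

    promoters <- stage("load_promoters", {
        out <- lapply(cfg$species, .loadSpecies, cfg = cfg)
        names(out) <- vapply(cfg$species, `[[`, character(1), "label")
        out
    })
    message(sprintf("loaded %d species: %s",
                    length(promoters),
                    paste(sprintf("%s (%d promoters)", names(promoters),
                                  vapply(promoters, length, integer(1))),
                          collapse = ", ")))

    scans <- stage("scan", {
        lapply(promoters, scanSet, motif = cfg$motif,
               maxSpacer = cfg$max_spacer, mode = cfg$mode)
    })
    files <- list()
    profileFiles <- stage("profiles", lapply(names(promoters), function(lab) {
        panel <- controlPanel(promoters[[lab]], motifs = panelMotifs,
                              maxSpacer = cfg$max_spacer, mode = cfg$mode)
        tab <- do.call(rbind, lapply(names(panel), function(mm) {
            pr <- panel[[mm]]
            data.frame(motif = mm, N = 0:maxSpacer(pr),
                       count = unname(dyadCounts(pr)),
                       gene_count = unname(geneDyadCounts(pr)),
                       per_thousand = unname(perThousand(pr)),
                       stringsAsFactors = FALSE)
        }))
        emit(tab, sprintf("profiles_%s.tsv", lab))
    }))
    files[paste0("profiles_", names(promoters))] <- profileFiles

    outlierObjs <- stage("outliers", {
        lapply(scans, function(sc)
            percentileOutliers(sc$profile, low = cfg$whisker_low,
                               high = cfg$whisker_high))
    })
    files$outliers <- stage("outliers_table", {
        tab <- do.call(rbind, lapply(names(outlierObjs), function(lab) {
            o <- outlierObjs[[lab]]
            data.frame(species = lab,
                       low_whisker = o@lowWhisker,
                       high_whisker = o@highWhisker,
                       peaks = paste(o@peaks, collapse = ","),
                       dips = paste(o@dips, collapse = ","),
                       stringsAsFactors = FALSE)
        }))
        emit(tab, "outliers.tsv")
    })

    windows <- stage("window_correlations", {
        labs <- names(scans)
        rows <- list()
        if (length(labs) >= 2) for (i in seq_len(length(labs) - 1L))
            for (j in (i + 1L):length(labs)) {
                w <- windowCorrelations(scans[[i]]$profile,
                                        scans[[j]]$profile,
                                        minWidth = cfg$min_width)
                if (nrow(w)) {
                    w$species_a <- labs[i]; w$species_b <- labs[j]
                    rows[[length(rows) + 1L]] <- w
                }
            }
        if (length(rows)) do.call(rbind, rows) else NULL
    })
    if (!is.null(windows)) {
        files$windows <- emit(windows, "window_correlations.tsv")
        best <- do.call(rbind, lapply(
            split(windows, paste(windows$species_a, windows$species_b)),
            bestWindows))
        rownames(best) <- NULL
        files$best_windows <- emit(best, "best_windows.tsv")
    }

    consFiles <- stage("consensus", lapply(names(scans), function(lab) {
        pool <- scans[[lab]]$pool
        cons <- suppressWarnings(
            consensusAll(pool, pctGC = cfg$pct_gc, pctAT = cfg$pct_at))
        out <- list()
        out[[paste0("consensus_", lab)]] <-
            emit(cons, sprintf("consensus_%s.tsv", lab))
        comp <- do.call(rbind, lapply(
            as.integer(names(pool@pools)), function(n) {
                sp <- spacers(pool, n)
                if (n == 0L || !length(sp)) return(NULL)
                pct <- positionComposition(sp)
                data.frame(N = n,
                           position = rep(seq_len(ncol(pct)), each = 4L),
                           base = rep(rownames(pct), ncol(pct)),
                           pct = as.vector(pct))
            }))
        if (!is.null(comp))
            out[[paste0("composition_", lab)]] <-
                emit(comp, sprintf("composition_%s.tsv", lab))
        out
    }))
    for (fl in consFiles) files[names(fl)] <- fl

    orthoTab <- NULL
    if (!is.null(cfg$ortholog_table)) {
        orthoTab <- stage("orthologs", {
            og <- utils::read.delim(cfg$ortholog_table,
                                    stringsAsFactors = FALSE)
            labs <- intersect(names(og), names(scans))
            if (length(labs) < 2)
                stop("ortholog table must share >= 2 species labels ",
                     "with the config")
            sub <- lapply(labs, function(lab)
                subsetProfile(scans[[lab]], og[[lab]]))
            names(sub) <- labs
            rows <- list()
            for (i in seq_len(length(labs) - 1L))
                for (j in (i + 1L):length(labs)) {
                    ci <- dyadCounts(sub[[i]]); cj <- dyadCounts(sub[[j]])
                    r <- pearsonR(ci, cj)
                    t <- tFromR(r, length(ci))
                    rows[[length(rows) + 1L]] <- data.frame(
                        species_a = labs[i], species_b = labs[j],
                        n = length(ci), r = r, t = t,
                        p = pFromT(t, length(ci) - 2L),
                        stringsAsFactors = FALSE)
                }
            do.call(rbind, rows)
        })
        files$ortholog_correlations <-
            emit(orthoTab, "ortholog_correlations.tsv")
    }

    screen <- NULL
    if (!is.null(cfg$conditions)) {
        screen <- stage("enrichment", {
            conds <- readConditionManifest(cfg$conditions)
            lab <- names(promoters)[1L]
            panel <- dyadGeneSets(promoters[[lab]], motifs = panelMotifs,
                                  maxSpacer = cfg$max_spacer,
                                  mode = cfg$mode)
            conditionScreen(conds, panel, universe = geneIds(promoters[[lab]]),
                            testMotif = cfg$motif, alpha = cfg$alpha,
                            cutoff = cfg$cutoff)
        })
        files$enrichment <- emit(screen, "enrichment.tsv")
    }

    bundle <- structure(list(
        files = files, config = cfg, promoters = promoters,
        scans = scans, outliers = outlierObjs, windows = windows,
        orthologCorrelations = orthoTab, enrichment = screen),
        class = "ReportBundle")
    files$report <- file.path(outDir, "report.txt")
    writeLines(makeReport(bundle), files$report)
    bundle$files <- files
    bundle
}

#' Plain-text summary of a pipeline run
#'
#' Names the per-species peaks and dips, the common peaks across species,
#' the best correlation window per species pair, the ortholog correlations
#' and any Grubbs-significant conditions.
#'
#' @param bundle A \code{ReportBundle} from [runPipeline()].
#' @return Character vector of report lines (invisibly written by
#'   [runPipeline()] to \code{report.txt}).
#' @export
makeReport <- function(bundle) {
    stopifnot(inherits(bundle, "ReportBundle"))
    lines <- c(sprintf("dyadSpacer report (motif %s, max spacer %d)",
                       bundle$config$motif, bundle$config$max_spacer), "")
    for (lab in names(bundle$outliers)) {
        o <- bundle$outliers[[lab]]
        lines <- c(lines, sprintf(
            "%s: %d promoters; peaks N = {%s}; dips N = {%s}",
            lab, length(bundle$promoters[[lab]]),
            paste(o@peaks, collapse = ", "),
            paste(o@dips, collapse = ", ")))
    }
    common <- Reduce(intersect, lapply(bundle$outliers, peaks))
    lines <- c(lines, sprintf("common peaks across species: {%s}",
                              paste(common, collapse = ", ")), "")
    if (!is.null(bundle$windows)) {
        best <- bestWindows(bundle$windows)
        for (i in seq_len(nrow(best)))
            lines <- c(lines, sprintf(
                "%s vs %s: best width-%d window starts N = %d (r = %.3f, t = %.3f, p = %.2g)",
                best$species_a[i], best$species_b[i], best$width[i],
                best$start_N[i], best$r[i], best$t[i], best$p[i]))
        lines <- c(lines, "")
    }
    if (!is.null(bundle$orthologCorrelations)) {
        oc <- bundle$orthologCorrelations
        for (i in seq_len(nrow(oc)))
            lines <- c(lines, sprintf(
                "orthologs %s vs %s: r = %.4f (n = %d, p = %.3g)",
                oc$species_a[i], oc$species_b[i], oc$r[i], oc$n[i],
                oc$p[i]))
        lines <- c(lines, "")
    }
    if (!is.null(bundle$enrichment)) {
        sig <- bundle$enrichment[bundle$enrichment$significant, ]
        lines <- c(lines, sprintf(
            "conditions screened: %d; gate (L > %.2f) passed: %d; Grubbs-significant: %s",
            nrow(bundle$enrichment), bundle$config$cutoff,
            sum(bundle$enrichment$gate_passed),
            if (nrow(sig)) paste(sig$condition, collapse = ", ")
            else "none"))
    }
    lines
}

#' @export
print.ReportBundle <- function(x, ...) {
    cat("ReportBundle with outputs:\n")
    for (f in unlist(x$files)) cat("  ", f, "\n")
    invisible(x)
}
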