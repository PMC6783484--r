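#' Read a plain-text key=value run configuration
#'
#' Lines of the form \code{key = value}; blank lines and \code{#}
#' comments ignored.  Recognised keys mirror the arguments of
#' [runAll()]; unknown keys are kept verbatim.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    bad <- lengths(kv) != 3L
    if (any(bad)) stop("unparseable config line: ", lines[bad][1L])
    out <- lapply(kv, function(x) trimws(x[3L]))
    names(out) <- vapply(kv, function(x) trimws(x[2L]), character(1L))
    out
}

#' Run the full plastome diversity analysis
#'
#' Orchestrates the pipeline on one alignment: site classification,
#' private/shared SNP partition, sliding-window profile, hotspot and
#' high-deletion regions, percent-identity profile, p-distance matrix,
#' relative rate tests and (per annotated genome) quadripartite
#' structure summaries.  All tables are written under \code{outDir}
#' together with a run log recording package version, seed and
#' parameters.  When no outgroup is given the relative-rate stage is
#' skipped with a warning; everything else still runs.
#'
#' @param alignment A \linkS4class{PlastomeAlignment} or path to an
#'   aligned FASTA file.
#' @param outDir Output directory (created if missing).
#' @param reference Reference taxon for identity profile and annotation
#'   overlay (default: first taxon).
#' @param outgroup Outgroup taxon for the relative rate tests, or NULL.
#' @param annotations Named list of GenBank flatfile paths (names =
#'   taxa) for structure summaries, or NULL.
#' @param L,s Window length and step, bp.
#' @param hotspotMode,hotspotParam Hotspot criterion passed to
#'   [detectHotspots()].
#' @param deletionFraction Threshold for [highDeletionWindows()].
#' @param minIrLength Passed to [summarizePlastome()].
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with all in-memory results (sites,
#'   partition, profile, hotspots, highDeletion, identity, pdist, rrt,
#'   structures) plus the output paths.
#' @export
runAll <- function(alignment, outDir,
                   reference = NULL, outgroup = NULL,
                   annotations = NULL,
                   L = 500L, s = 250L,
                   hotspotMode = "top_k", hotspotParam = 4L,
                   deletionFraction = 0.70,
                   minIrLength = 10000L,
                   seed = NULL) {
    if (is.character(alignment)) alignment <- readAlignment(alignment)
    stopifnot(is(alignment, "PlastomeAlignment"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tx <- taxa(alignment)
    if (is.null(reference)) reference <- tx[1L]
    if (!reference %in% tx)
        stop("stage config: reference taxon '", reference,
             "' not in alignment")
    paths <- list()
    out <- list()

    withStage <- function(stage, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", stage, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    out$sites <- withStage("classify", classifyColumns(alignment))
    paths$sites <- file.path(outDir, "site_table.tsv")
    writeSiteTable(out$sites, paths$sites)

    out$partition <- withStage("venn", snpPartition(out$sites))
    paths$partition <- file.path(outDir, "snp_partition.json")
    writeSnpPartition(out$partition, paths$partition)

    out$profile <- withStage("windows", windowProfile(out$sites, L, s))
    if (!is.null(annotations) && reference %in% names(annotations)) {
        feats <- withStage("windows",
                           readGenBankFeatures(annotations[[reference]]))
        out$profile <- withStage("windows",
            annotateWindows(out$profile, feats$features, alignment,
                            reference))
    }
    paths$profile <- file.path(outDir, "window_profile.tsv")
    writeWindowProfile(out$profile, paths$profile)

    out$hotspots <- withStage("hotspots",
        detectHotspots(out$profile, out$sites, hotspotMode, hotspotParam))
    paths$hotspots <- file.path(outDir, "hotspots.bed")
    writeBed(out$hotspots, paths$hotspots,
             name = sprintf("hotspot_%d_snps_%d",
                            seq_len(nrow(out$hotspots)),
                            out$hotspots$snpTotal))

    out$highDeletion <- withStage("high_deletion",
        highDeletionWindows(alignment, L, s, deletionFraction))
    paths$highDeletion <- file.path(outDir, "high_deletion.bed")
    writeBed(out$highDeletion, paths$highDeletion)

    out$identity <- withStage("identity",
        identityProfile(alignment, reference, L, s))
    paths$identity <- file.path(outDir, "identity_profile.tsv")
    idt <- out$identity
    idt$start <- idt$start + 1L
    write.table(idt, paths$identity, sep = "\t", quote = FALSE,
                row.names = FALSE)

    out$pdist <- withStage("pdist", pDistance(alignment))
    paths$pdist <- file.path(outDir, "p_distance.tsv")
    writeDistanceMatrix(out$pdist, paths$pdist)

    if (is.null(outgroup)) {
        warning("no outgroup configured; relative-rate stage skipped")
    } else {
        if (!outgroup %in% tx)
            stop("stage 'rrt' failed: outgroup '", outgroup,
                 "' not in alignment")
        out$rrt <- withStage("rrt",
            rrtAllPairs(alignment, setdiff(tx, outgroup), outgroup))
        paths$rrt <- file.path(outDir, "rrt.tsv")
        writeRrtTable(out$rrt, paths$rrt)
    }

    if (!is.null(annotations)) {
        out$structures <- list()
        for (nm in names(annotations)) {
            gb <- withStage("structure", readGenBankFeatures(annotations[[nm]]))
            st <- withStage("structure",
                summarizePlastome(gb$sequence, gb$features, minIrLength))
            out$structures[[nm]] <- st
            p <- file.path(outDir, sprintf("structure_%s.json", nm))
            writeStructureReport(st, p)
            paths[[paste0("structure_", nm)]] <- p
        }
    }

    paths$log <- file.path(outDir, "run_log.txt")
    writeLines(c(
        sprintf("plastomics version: %s",
                as.character(utils::packageVersion("plastomics"))),
        sprintf("taxa: %s", paste(tx, collapse = ", ")),
        sprintf("alignment_length: %d", alignmentLength(alignment)),
        sprintf("reference: %s", reference),
        sprintf("outgroup: %s", if (is.null(outgroup)) "none" else outgroup),
        sprintf("window_length: %d", as.integer(L)),
        sprintf("step: %d", as.integer(s)),
        sprintf("hotspot_mode: %s", hotspotMode),
        sprintf("hotspot_param: %s", hotspotParam),
        sprintf("deletion_fraction: %s", deletionFraction),
        sprintf("seed: %s", if (is.null(seed)) "none" else seed)),
        paths$log)
    out$paths <- paths
    invisible(out)
}

#' Write a simulated reference as a GenBank-like flatfile
#'
#' Emits a minimal flatfile (LOCUS / FEATURES / ORIGIN) for the toy
#' annotated genome produced by [simulateReference()], readable by
#' [readGenBankFeatures()].
#'
#' @param reference Output of [simulateReference()].
#' @param path Output path.
#' @param name Locus name (default "synthetic_plastome").
#' @return Invisibly, \code{path}.
#' @export
writeGenBankLike <- function(reference, path, name = "synthetic_plastome") {
    seqstr <- tolower(reference$sequence)
    n <- nchar(seqstr)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("LOCUS       %s %d bp    DNA     circular SYN",
                       name, n), con)
    writeLines(sprintf("DEFINITION  synthetic plastome (seed %s).",
                       if (is.null(reference$config$seed)) "none"
                       else reference$config$seed), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    f <- reference$features
    keyOf <- c(coding = "CDS", tRNA = "tRNA", rRNA = "rRNA",
               other = "misc_feature")
    for (i in seq_len(nrow(f))) {
        loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
        if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
        writeLines(sprintf("     %-15s %s", keyOf[[f$kind[i]]], loc), con)
        writeLines(sprintf("                     /gene=\"%s\"", f$name[i]),
                   con)
    }
    writeLines("ORIGIN", con)
    for (off in seq.int(1L, n, by = 60L)) {
        chunkEnd <- min(off + 59L, n)
        chunk <- substr(seqstr, off, chunkEnd)
        parts <- substring(chunk, seq(1, nchar(chunk), 10),
                           pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
        writeLines(sprintf("%9d %s", off, paste(parts, collapse = " ")), con)
    }
    writeLines("//", con)
    invisible(path)
}
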