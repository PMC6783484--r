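#' Sliding-window SNP/indel profile
#'
#' Emits fixed-width windows of length \code{L} starting at 0, s, 2s, ...
#' while \code{start + L <=} alignment length (a trailing partial window
#' is dropped unless \code{keepPartial}).  Per window: the number of
#' distinct columns flagged SNP, the number of indel positions, and the
#' indel density per kb (indel positions / L x 1000).  The window
#' midpoint (start + L/2) is the canonical x-coordinate for plotting.
#'
#' @param sites A \linkS4class{SiteClassification}.
#' @param L Window length, bp (default 500).
#' @param s Step size, bp (default 250); must satisfy 1 <= s <= L.
#' @param keepPartial Also emit a final truncated window? Default FALSE.
#' @return A \linkS4class{WindowProfile}.
#' @examples
#' aln <- plastomeAlignment(c(a = strrep("A", 1000), b = strrep("A", 1000)))
#' windowProfile(classifyColumns(aln), L = 500, s = 250)
#' @export
windowProfile <- function(sites, L = 500L, s = 250L, keepPartial = FALSE) {
    stopifnot(is(sites, "SiteClassification"))
    L <- as.integer(L); s <- as.integer(s)
    if (L < 1L) stop("window length L must be >= 1")
    if (s < 1L || s > L) stop("step s must satisfy 1 <= s <= L")
    n <- alignmentLength(sites)
    if (n < L)
        stop("alignment (", n, " bp) shorter than window (", L,
             " bp); use a smaller L")
    starts <- seq.int(0L, n - L, by = s)
    csSnp <- c(0L, cumsum(sites@isSnp))
    csIndel <- c(0L, cumsum(sites@isIndel))
    ends <- starts + L
    win <- data.frame(
        start = starts, end = ends, midpoint = starts + L / 2,
        snpCount = csSnp[ends + 1L] - csSnp[starts + 1L],
        indelCount = csIndel[ends + 1L] - csIndel[starts + 1L])
    if (keepPartial && max(ends) < n) {
        st <- max(starts) + s
        win <- rbind(win, data.frame(
            start = st, end = n, midpoint = st + (n - st) / 2,
            snpCount = csSnp[n + 1L] - csSnp[st + 1L],
            indelCount = csIndel[n + 1L] - csIndel[st + 1L]))
    }
    win$indelPerKb <- win$indelCount / (win$end - win$start) * 1000
    new("WindowProfile", windowLength = L, step = s, windows = win)
}

#' Detect SNP hotspot regions
#'
#' Selects windows by a criterion (\code{min_count}: SNP count >= param;
#' \code{top_k}: the param highest-count windows, ties broken by count
#' descending then start ascending), merges overlapping or adjacent
#' selected windows into regions, and recounts the distinct SNP columns
#' in each merged region so overlapping windows are not double counted.
#'
#' @param profile A \linkS4class{WindowProfile}.
#' @param sites The \linkS4class{SiteClassification} the profile was
#'   computed from.
#' @param mode \code{"min_count"} or \code{"top_k"}.
#' @param param Threshold (min_count) or number of windows (top_k); > 0.
#' @return data.frame of disjoint regions: start, end (0-based
#'   half-open), mergedWindowCount, snpTotal; ordered by snpTotal
#'   descending then start ascending.
#' @export
detectHotspots <- function(profile, sites,
                           mode = c("min_count", "top_k"), param) {
    stopifnot(is(profile, "WindowProfile"), is(sites, "SiteClassification"))
    mode <- match.arg(mode)
    if (param <= 0) stop("param must be > 0")
    w <- profile@windows
    if (nrow(w) == 0L) stop("empty window profile")
    sel <- if (mode == "min_count") {
        which(w$snpCount >= param)
    } else {
        ord <- order(-w$snpCount, w$start)
        sort(ord[seq_len(min(param, nrow(w)))])
    }
    if (!length(sel))
        return(data.frame(start = integer(), end = integer(),
                          mergedWindowCount = integer(),
                          snpTotal = integer()))
    regions <- .mergeIntervals(w$start[sel], w$end[sel])
    csSnp <- c(0L, cumsum(sites@isSnp))
    out <- data.frame(
        start = regions$start, end = regions$end,
        mergedWindowCount = regions$n,
        snpTotal = csSnp[regions$end + 1L] - csSnp[regions$start + 1L])
    out[order(-out$snpTotal, out$start), , drop = FALSE]
}

# merge overlapping/adjacent half-open intervals; returns start, end, n
.mergeIntervals <- function(start, end) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    rs <- start[1L]; re <- end[1L]; rn <- 1L
    outS <- integer(); outE <- integer(); outN <- integer()
    for (i in seq_along(start)[-1L]) {
        if (start[i] <= re) {            # overlap or touching
            re <- max(re, end[i]); rn <- rn + 1L
        } else {
            outS <- c(outS, rs); outE <- c(outE, re); outN <- c(outN, rn)
            rs <- start[i]; re <- end[i]; rn <- 1L
        }
    }
    data.frame(start = c(outS, rs), end = c(outE, re), n = c(outN, rn))
}

#' Windows with a high per-taxon deletion fraction
#'
#' Flags windows in which any single taxon's gap proportion exceeds
#' \code{fraction} (the screen behind large species-specific deletions).
#'
#' @param alignment A \linkS4class{PlastomeAlignment}.
#' @param L,s Window length and step, bp.
#' @param fraction Gap-proportion threshold in (0, 1); default 0.70.
#' @return data.frame: start, end, taxon, gapFraction — one row per
#'   (window, offending taxon).
#' @export
highDeletionWindows <- function(alignment, L = 500L, s = 250L,
                                fraction = 0.70) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must lie in (0, 1)")
    m <- alignmentMatrix(alignment)
    n <- ncol(m)
    L <- as.integer(L); s <- as.integer(s)
    if (n < L) stop("alignment shorter than window")
    starts <- seq.int(0L, n - L, by = s)
    hits <- list()
    for (tx in rownames(m)) {
        cs <- c(0L, cumsum(m[tx, ] == "-"))
        gaps <- cs[starts + L + 1L] - cs[starts + 1L]
        f <- gaps / L
        sel <- which(f > fraction)
        if (length(sel))
            hits[[tx]] <- data.frame(start = starts[sel],
                                     end = starts[sel] + L,
                                     taxon = tx, gapFraction = f[sel])
    }
    if (!length(hits))
        return(data.frame(start = integer(), end = integer(),
                          taxon = character(), gapFraction = numeric()))
    out <- do.call(rbind, hits)
    rownames(out) <- NULL
    out[order(out$start, out$taxon), , drop = FALSE]
}

#' Windowed percent identity against a reference taxon
#'
#' For each non-reference taxon and window, identity = matching columns /
#' comparable columns x 100, where a column is comparable when neither
#' the reference nor the taxon carries N and the two are not both gapped
#' (gap vs base counts as a mismatch; gap vs gap is excluded).  A window
#' with zero comparable columns yields NA, not 0.
#'
#' @param alignment A \linkS4class{PlastomeAlignment}.
#' @param reference Reference taxon label.
#' @param L,s Window length and step, bp.
#' @return data.frame: start, end, midpoint, then one identity column per
#'   non-reference taxon (percentages in [0, 100]).
#' @export
identityProfile <- function(alignment, reference, L = 500L, s = 250L) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    m <- alignmentMatrix(alignment)
    if (!reference %in% rownames(m))
        stop("reference taxon '", reference, "' not in alignment")
    n <- ncol(m)
    L <- as.integer(L); s <- as.integer(s)
    if (n < L) stop("alignment shorter than window")
    starts <- seq.int(0L, n - L, by = s)
    ref <- m[reference, ]
    out <- data.frame(start = starts, end = starts + L,
                      midpoint = starts + L / 2)
    for (tx in setdiff(rownames(m), reference)) {
        row <- m[tx, ]
        comparable <- ref != "N" & row != "N" & !(ref == "-" & row == "-")
        matchc <- comparable & ref == row
        csC <- c(0L, cumsum(comparable))
        csM <- c(0L, cumsum(matchc))
        nC <- csC[starts + L + 1L] - csC[starts + 1L]
        nM <- csM[starts + L + 1L] - csM[starts + 1L]
        out[[tx]] <- ifelse(nC == 0L, NA_real_, 100 * nM / nC)
    }
    out
}

#' Label windows with overlapping genes and intergenic spacers
#'
#' Features (given on the reference taxon's ungapped coordinates) are
#' lifted onto alignment columns via the gap-aware coordinate map;
#' spacers between consecutive features are named
#' \code{"geneA-geneB spacer"}.  A window straddling a gene boundary
#' receives both the gene and the spacer label.
#'
#' @param profile A \linkS4class{WindowProfile}.
#' @param features Feature data.frame (name, kind, start, end, strand;
#'   0-based half-open on the reference's ungapped sequence).
#' @param alignment The underlying \linkS4class{PlastomeAlignment}.
#' @param reference Reference taxon carrying the annotation.
#' @return The profile with a \code{label} column added to its windows
#'   (\code{";"}-separated labels, \code{""} when nothing overlaps).
#' @export
annotateWindows <- function(profile, features, alignment, reference) {
    stopifnot(is(profile, "WindowProfile"))
    if (!reference %in% taxa(alignment))
        stop("reference taxon '", reference, "' not in alignment")
    ivs <- .featureIntervalsOnAlignment(features, alignment, reference)
    w <- profile@windows
    w$label <- vapply(seq_len(nrow(w)), function(i) {
        hit <- ivs$start < w$end[i] & ivs$end > w$start[i]
        paste(unique(ivs$label[hit]), collapse = ";")
    }, character(1L))
    profile@windows <- w
    profile
}

# features on ungapped reference coords -> alignment-column intervals,
# plus named spacer intervals between consecutive features
.featureIntervalsOnAlignment <- function(features, alignment, reference) {
    f <- features[order(features$start), , drop = FALSE]
    ungappedLen <- sum(.alignedRow(alignment, reference) != "-")
    if (nrow(f) && any(f$end > ungappedLen))
        stop("feature interval beyond reference ungapped length")
    toCol <- function(p) mapUngappedToAlignment(alignment, reference, p)
    res <- list()
    if (nrow(f))
        res[[1L]] <- data.frame(
            start = toCol(f$start),
            end = toCol(f$end - 1L) + 1L,
            label = f$name)
    if (nrow(f) > 1L) {
        gapFrom <- f$end[-nrow(f)]
        gapTo <- f$start[-1L]
        keep <- gapTo > gapFrom
        if (any(keep))
            res[[length(res) + 1L]] <- data.frame(
                start = toCol(gapFrom[keep]),
                end = toCol(gapTo[keep] - 1L) + 1L,
                label = paste0(f$name[-nrow(f)][keep], "-",
                               f$name[-1L][keep], " spacer"))
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          label = character()))
    do.call(rbind, res)
}

#' Write a window profile to TSV
#'
#' Coordinates are written 1-based inclusive; a \code{#}-prefixed header
#' records the window parameters.
#'
#' @param profile A \linkS4class{WindowProfile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeWindowProfile <- function(profile, path) {
    w <- profile@windows
    out <- data.frame(start = w$start + 1L, end = w$end,
                      midpoint = w$midpoint + 0.5,
                      snp = w$snpCount, indel = w$indelCount,
                      indel_per_kb = round(w$indelPerKb, 3))
    if (!is.null(w$label)) out$label <- w$label
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# window_length=%d step=%d coordinates=1-based",
                       profile@windowLength, profile@step), con)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write regions as BED
#'
#' Standard BED: 0-based half-open, tab-separated chrom/start/end plus a
#' name column.
#'
#' @param regions data.frame with start and end columns (0-based
#'   half-open) and optionally a name-like column.
#' @param path Output path.
#' @param chrom Chromosome/contig label for column 1 (default
#'   "alignment").
#' @param name Optional character vector of region names.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(regions, path, chrom = "alignment", name = NULL) {
    if (is.null(name))
        name <- if (!is.null(regions$taxon)) as.character(regions$taxon)
                else sprintf("region_%d", seq_len(nrow(regions)))
    out <- data.frame(chrom = chrom, start = regions$start,
                      end = regions$end, name = name)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
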