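#' Detect the inverted repeat pair of a plastome
#'
#' Finds the longest pair of disjoint spans such that one equals the
#' reverse complement of the other, by seed-and-extend over exact k-mer
#' matches between the sequence and its reverse complement.  The
#' sequence is treated as circular (scanned doubled); reported
#' coordinates are normalized so starts lie in \code{[0, length)}; an
#' arm whose end exceeds the sequence length wraps the origin.  Matching
#' is exact (no mismatches tolerated).  Ties in length are broken by the
#' leftmost start.
#'
#' @param sequence A \code{DNAString} or single character string
#'   (A/C/G/T/N).
#' @param minLength Minimum acceptable repeat length, bp (default 10000,
#'   the scale of plastome IRs).
#' @param seedLength Seed k-mer size (default \code{min(24, minLength)}).
#' @param maxSeedHits Seeds whose k-mer occurs more often than this in
#'   the reverse complement are skipped (repeat masking; default 20).
#' @return List with elements \code{ira} and \code{irb}, each
#'   \code{c(start, end)} 0-based half-open (\code{ira} has the smaller
#'   start), and \code{length}.  The returned spans satisfy exact
#'   reverse-complement equality by construction and are re-verified
#'   before returning.
#' @examples
#' set.seed(1)
#' arm <- paste(sample(c("A","C","G","T"), 300, TRUE), collapse = "")
#' lsc <- paste(sample(c("A","C","G","T"), 1000, TRUE), collapse = "")
#' ssc <- paste(sample(c("A","C","G","T"), 200, TRUE), collapse = "")
#' genome <- paste0(lsc, arm, ssc, revComp(arm))
#' detectInvertedRepeat(genome, minLength = 100)
#' @export
detectInvertedRepeat <- function(sequence, minLength = 10000L,
                                 seedLength = NULL, maxSeedHits = 20L) {
    s <- .asSequenceString(sequence)
    n <- nchar(s)
    if (minLength < 1L) stop("minLength must be >= 1")
    if (n < 2L * minLength)
        stop("no IR found: sequence (", n,
             " bp) cannot hold two disjoint repeats of ", minLength, " bp")
    k <- if (is.null(seedLength)) min(24L, minLength) else as.integer(seedLength)
    D <- paste0(s, s)
    RCD <- revComp(D)
    lenD <- nchar(D)
    Dv <- strsplit(D, "")[[1L]]
    Rv <- strsplit(RCD, "")[[1L]]

    rcStarts <- seq_len(lenD - k + 1L)
    rcK <- substring(RCD, rcStarts, rcStarts + k - 1L)
    stride <- max(1L, k %/% 2L)
    dStarts <- seq.int(1L, lenD - k + 1L, by = stride)
    dK <- substring(D, dStarts, dStarts + k - 1L)

    rcIndex <- split(rcStarts, rcK)
    hits <- rcIndex[dK]
    covered <- new.env(parent = emptyenv())   # per anti-diagonal coverage
    cand <- list()
    for (u in seq_along(dStarts)) {
        js <- hits[[u]]
        if (is.null(js) || length(js) > maxSeedHits) next
        i <- dStarts[u]
        for (j in js) {
            dg <- as.character(i - j)   # constant along one repeat match
            cov <- covered[[dg]]
            if (!is.null(cov) && i >= cov[1L] && i <= cov[2L]) next
            # extend exact match left and right
            il <- i; jl <- j
            while (il > 1L && jl > 1L && Dv[il - 1L] == Rv[jl - 1L]) {
                il <- il - 1L; jl <- jl - 1L
            }
            ir <- i + k - 1L; jr <- j + k - 1L
            while (ir < lenD && jr < lenD && Dv[ir + 1L] == Rv[jr + 1L]) {
                ir <- ir + 1L; jr <- jr + 1L
            }
            covered[[dg]] <- c(il, ir)
            L <- ir - il + 1L
            if (L > n) next                       # degenerate full wrap
            sA <- (il - 1L) %% n
            sB <- (lenD - jr) %% n                # counterpart arm start
            if (.circOverlap(sA, L, sB, L, n)) next
            lo <- min(sA, sB); hi <- max(sA, sB)
            cand[[paste(lo, hi, L)]] <- c(lo, hi, L)
        }
    }
    if (!length(cand)) {
        stop("no IR found: no reverse-complement repeat >= ", minLength,
             " bp (longest candidate: 0 bp)")
    }
    cm <- do.call(rbind, cand)
    best <- cm[order(-cm[, 3L], cm[, 1L], cm[, 2L]), , drop = FALSE][1L, ]
    if (best[3L] < minLength)
        stop("no IR found: no reverse-complement repeat >= ", minLength,
             " bp (longest candidate: ", best[3L], " bp)")
    ira <- c(best[1L], best[1L] + best[3L])
    irb <- c(best[2L], best[2L] + best[3L])
    armA <- .circSubstr(s, ira[1L], best[3L])
    armB <- .circSubstr(s, irb[1L], best[3L])
    stopifnot(armA == revComp(armB))              # self-checking postcondition
    list(ira = unname(ira), irb = unname(irb), length = unname(best[3L]))
}

# do circular intervals [s1, s1+l1) and [s2, s2+l2) mod n overlap?
.circOverlap <- function(s1, l1, s2, l2, n) {
    d <- (s2 - s1) %% n
    d < l1 || (n - d) < l2
}

.circSubstr <- function(s, start0, len) {
    n <- nchar(s)
    start <- start0 %% n + 1L
    if (start + len - 1L <= n)
        substr(s, start, start + len - 1L)
    else
        paste0(substr(s, start, n), substr(s, 1L, len - (n - start + 1L)))
}

.asSequenceString <- function(sequence) {
    if (is(sequence, "DNAString") || is(sequence, "BString"))
        sequence <- as.character(sequence)
    stopifnot(is.character(sequence), length(sequence) == 1L)
    toupper(sequence)
}

#' Reverse complement of a sequence string
#'
#' @param x Single character string over A/C/G/T/N (case-insensitive).
#' @return Reverse-complemented uppercase string.
#' @export
revComp <- function(x) {
    as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(toupper(x))))
}

#' Partition a circular plastome into LSC / IRa / SSC / IRb
#'
#' Given the two IR spans, the two inter-IR arcs of the circle are
#' assigned LSC (the longer) and SSC (the shorter); on a tie the arc
#' following the first IR is named LSC with a warning.  IRa is the IR
#' that follows the LSC going clockwise.  Region lengths always sum to
#' the total length.
#'
#' @param sequence \code{DNAString} or character string.
#' @param ira,irb IR spans \code{c(start, end)}, 0-based half-open
#'   (end may exceed the length for a wrapping arm); must be disjoint.
#' @return data.frame with rows LSC, IRa, SSC, IRb: region, start, end,
#'   length (start in \code{[0, n)}; end = start + length, wrapping when
#'   end > n).
#' @export
partitionRegions <- function(sequence, ira, irb) {
    s <- .asSequenceString(sequence)
    n <- nchar(s)
    l1 <- ira[2L] - ira[1L]; l2 <- irb[2L] - irb[1L]
    s1 <- ira[1L] %% n; s2 <- irb[1L] %% n
    if (l1 < 1L || l2 < 1L) stop("empty IR span")
    if (.circOverlap(s1, l1, s2, l2, n)) stop("overlapping IR spans")
    arcAstart <- (s1 + l1) %% n                  # arc after first IR
    arcAlen <- (s2 - arcAstart) %% n
    arcBstart <- (s2 + l2) %% n
    arcBlen <- (s1 - arcBstart) %% n
    if (arcAlen == 0L || arcBlen == 0L)
        warning("IRs are adjacent; a single-copy region has zero length")
    if (arcAlen == arcBlen)
        warning("single-copy arcs have equal length; naming the first LSC")
    if (arcAlen >= arcBlen) {
        lsc <- c(arcAstart, arcAlen); ssc <- c(arcBstart, arcBlen)
        iraOut <- c(s2, l2); irbOut <- c(s1, l1)  # IRa follows LSC
    } else {
        lsc <- c(arcBstart, arcBlen); ssc <- c(arcAstart, arcAlen)
        iraOut <- c(s1, l1); irbOut <- c(s2, l2)
    }
    data.frame(
        region = c("LSC", "IRa", "SSC", "IRb"),
        start = c(lsc[1L], iraOut[1L], ssc[1L], irbOut[1L]),
        end = c(lsc[1L] + lsc[2L], iraOut[1L] + iraOut[2L],
                ssc[1L] + ssc[2L], irbOut[1L] + irbOut[2L]),
        length = c(lsc[2L], iraOut[2L], ssc[2L], irbOut[2L]),
        stringsAsFactors = FALSE)
}

#' GC content of a sequence
#'
#' (G + C) / (A + C + G + T) x 100; N and gaps are excluded from the
#' denominator.  A region containing no unambiguous base yields NA.
#'
#' @param sequence \code{DNAString} or character string.
#' @return Percentage in \code{[0, 100]}, or NA.
#' @examples
#' gcContent("ATNGC")  # 50
#' @export
gcContent <- function(sequence) {
    s <- .asSequenceString(sequence)
    v <- strsplit(s, "")[[1L]]
    denom <- sum(v %in% BASES)
    if (denom == 0L) return(NA_real_)
    sum(v %in% c("G", "C")) / denom * 100
}

#' Base composition of a sequence
#'
#' @param sequence \code{DNAString} or character string.
#' @return Named numeric vector of A/C/G/T percentages over all
#'   positions including N (unresolved positions dilute the four
#'   percentages, matching how mapping-based base frequencies are
#'   reported).
#' @export
baseComposition <- function(sequence) {
    s <- .asSequenceString(sequence)
    v <- strsplit(s, "")[[1L]]
    n <- length(v)
    vapply(setNames(BASES, BASES), function(b) sum(v == b) / n * 100,
           numeric(1L))
}

#' Quadripartite summary of a plastome
#'
#' Detects the inverted repeats, partitions the circle into LSC / IRa /
#' SSC / IRb, computes total and per-region GC content, and (when an
#' annotation is supplied) the gene census by kind.  IR-duplicated
#' features count once per annotated occurrence, so a plastome with 4
#' rRNA genes duplicated in the IRs reports 8 rRNA features.
#'
#' @param sequence \code{DNAString} or character string (the circular
#'   genome, linearized anywhere).
#' @param features Optional feature data.frame (name, kind, start, end,
#'   strand) as from [readGenBankFeatures()].
#' @param minIrLength Passed to [detectInvertedRepeat()].
#' @return A \linkS4class{PlastomeStructure}.
#' @export
summarizePlastome <- function(sequence, features = NULL,
                              minIrLength = 10000L) {
    s <- .asSequenceString(sequence)
    n <- nchar(s)
    ir <- detectInvertedRepeat(s, minLength = minIrLength)
    regions <- partitionRegions(s, ir$ira, ir$irb)
    regions$gc <- vapply(seq_len(nrow(regions)), function(i)
        gcContent(.circSubstr(s, regions$start[i], regions$length[i])),
        numeric(1L))
    census <- c(coding = 0L, tRNA = 0L, rRNA = 0L, other = 0L)
    if (!is.null(features) && nrow(features)) {
        # census counts feature occurrences, not intervals: the
        # multi-interval (join) rows of one occurrence count once
        occ <- if ("occurrence" %in% names(features))
            features[!duplicated(features$occurrence), ] else features
        tab <- table(factor(occ$kind,
                            levels = c("coding", "tRNA", "rRNA", "other")))
        census <- setNames(as.integer(tab), names(census))
    }
    new("PlastomeStructure",
        totalLength = n,
        regions = regions,
        gcTotal = gcContent(s),
        geneCensus = census)
}

#' Write a plastome structure report as JSON
#'
#' @param structure A \linkS4class{PlastomeStructure}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeStructureReport <- function(structure, path) {
    obj <- list(total_length = structure@totalLength,
                gc_total = structure@gcTotal,
                regions = structure@regions,
                gene_census = as.list(structure@geneCensus))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}
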