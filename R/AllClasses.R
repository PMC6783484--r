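#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement DNAString letterFrequency width
#' @importFrom stats pchisq rbinom runif setNames
#' @importFrom utils write.table packageVersion
NULL

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")
BASES <- c("A", "C", "G", "T")

#' PlastomeAlignment: a gapped multiple sequence alignment of plastomes
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] holding one gapped row
#' per taxon.  All rows have identical width; taxon labels (names) are
#' unique and non-empty; the alphabet is restricted to A, C, G, T, N and
#' the gap character \code{-}.  IUPAC ambiguity codes are normalized to N
#' on construction by [readAlignment()].
#'
#' @slot seqs A \code{DNAStringSet} of equal-width gapped sequences,
#'   named by taxon.
#' @seealso [readAlignment()], [taxa()], [alignmentLength()],
#'   [alignmentMatrix()]
#' @export
setClass("PlastomeAlignment", representation(seqs = "DNAStringSet"))

setValidity("PlastomeAlignment", function(object) {
    s <- object@seqs
    if (length(s) < 1L)
        return("alignment must contain at least one sequence")
    w <- Biostrings::width(s)
    if (length(unique(w)) != 1L)
        return("all rows must have identical length (not aligned)")
    if (w[1L] < 1L)
        return("alignment length must be >= 1")
    nm <- names(s)
    if (is.null(nm) || any(!nzchar(nm)))
        return("all taxa must have non-empty labels")
    if (anyDuplicated(nm))
        return(paste0("duplicate taxon label: ",
                      nm[duplicated(nm)][1L]))
    freq <- Biostrings::letterFrequency(s, letters = ALN_ALPHABET)
    if (any(rowSums(freq) != w))
        return("alphabet restricted to {A,C,G,T,N,-}")
    TRUE
})

#' SiteClassification: per-column classification of an alignment
#'
#' One record per alignment column: whether the column is an indel
#' position (any row gapped), a SNP (>= 2 distinct non-missing nucleotide
#' states, gaps and N excluded), monomorphic, or uninformative (< 2
#' non-missing taxa).  A column may be both a SNP and an indel position;
#' the two flags are independent.  The character state matrix is retained
#' so allele-class partitions can be extracted per column.
#'
#' @slot taxa Character vector of taxon labels, in alignment order.
#' @slot isSnp,isIndel,isUninformative Logical vectors, one entry per
#'   column (0-based column \code{i} is entry \code{i + 1}).
#' @slot states Character matrix (taxa x columns) of normalized states.
#' @seealso [classifyColumns()], [alleleClasses()], [countTotals()]
#' @export
setClass("SiteClassification", representation(
    taxa = "character",
    isSnp = "logical",
    isIndel = "logical",
    isUninformative = "logical",
    states = "matrix"))

setValidity("SiteClassification", function(object) {
    n <- length(object@isSnp)
    if (length(object@isIndel) != n || length(object@isUninformative) != n)
        return("flag vectors must have one entry per column")
    if (ncol(object@states) != n || nrow(object@states) != length(object@taxa))
        return("states matrix must be taxa x columns")
    if (any(object@isSnp & object@isUninformative))
        return("a SNP column cannot be uninformative")
    TRUE
})

#' SnpPartition: private/shared SNP counts over taxon subsets
#'
#' Map from non-trivial taxon subsets (the Venn regions) to SNP counts.
#' At a SNP column every allele class — the maximal set of non-missing
#' taxa sharing one nucleotide state — that is a proper subset of the
#' taxon set is credited once.  Singleton credits are the private SNPs of
#' a species; the credit for a subset of size \eqn{k} counts columns at
#' which exactly those \eqn{k} species share a state that all other
#' non-missing species lack.
#'
#' @slot taxa Character vector of taxon labels.
#' @slot counts Named integer vector; names are subsets encoded as taxon
#'   labels sorted and joined by \code{"|"}.
#' @slot totalSnpColumns Number of SNP columns examined.
#' @seealso [snpPartition()], [subsetCounts()]
#' @export
setClass("SnpPartition", representation(
    taxa = "character",
    counts = "integer",
    totalSnpColumns = "integer"))

setValidity("SnpPartition", function(object) {
    if (any(object@counts < 0L)) return("all counts must be >= 0")
    if (is.null(names(object@counts)) && length(object@counts) > 0L)
        return("counts must be named by taxon subset")
    TRUE
})

#' WindowProfile: sliding-window variability profile
#'
#' Fixed-width windows of length \code{windowLength} advanced by
#' \code{step}; per window the number of distinct SNP columns, indel
#' positions, and the indel density per kb.  Coordinates are 0-based
#' half-open internally; writers emit 1-based inclusive coordinates.
#'
#' @slot windowLength,step Window length and step, bp.
#' @slot windows data.frame with columns start, end, midpoint, snpCount,
#'   indelCount, indelPerKb and optionally label.
#' @seealso [windowProfile()], [detectHotspots()], [annotateWindows()]
#' @export
setClass("WindowProfile", representation(
    windowLength = "integer",
    step = "integer",
    windows = "data.frame"))

setValidity("WindowProfile", function(object) {
    w <- object@windows
    need <- c("start", "end", "midpoint", "snpCount", "indelCount",
              "indelPerKb")
    if (!all(need %in% names(w)))
        return("windows must carry start,end,midpoint,snpCount,indelCount,indelPerKb")
    if (nrow(w) > 1L && any(diff(w$start) != object@step))
        return("window starts must advance by exactly one step")
    widths <- w$end - w$start
    if (nrow(w) && any(widths[-nrow(w)] != object@windowLength))
        return("all windows (bar a trailing partial one) must have width windowLength")
    if (nrow(w) && widths[nrow(w)] > object@windowLength)
        return("window width may not exceed windowLength")
    TRUE
})

#' PDistanceResult: pairwise p-distances under complete deletion
#'
#' Symmetric matrix of uncorrected pairwise distances (proportion of
#' differing sites), computed after removing every column that contains a
#' gap or an N in any row (complete deletion) or, optionally, per pair
#' (pairwise deletion).
#'
#' @slot matrix Symmetric numeric matrix of p-distances, zero diagonal.
#' @slot nComplete Number of columns retained (complete deletion), or the
#'   per-pair counts on the off-diagonal (pairwise deletion).
#' @slot deletion "complete" or "pairwise".
#' @seealso [pDistance()]
#' @export
setClass("PDistanceResult", representation(
    matrix = "matrix",
    nComplete = "matrix",
    deletion = "character"))

setValidity("PDistanceResult", function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("distance matrix must be square")
    if (any(abs(diag(m)) > 0)) return("diagonal must be zero")
    if (any(m < 0 | m > 1)) return("p-distances must lie in [0,1]")
    if (!isTRUE(all.equal(m, t(m)))) return("matrix must be symmetric")
    TRUE
})

#' PlastomeStructure: quadripartite plastome summary
#'
#' Coordinates of the large and small single-copy regions and the two
#' inverted repeats (IRb the reverse complement of IRa), region lengths
#' and GC content, and the gene census by feature kind.  Coordinates are
#' 0-based half-open on the input (circular) sequence; a region may wrap
#' the origin, in which case end < start and the length field is
#' authoritative.
#'
#' @slot totalLength Total sequence length, bp.
#' @slot regions data.frame with one row per region (LSC, IRa, SSC, IRb)
#'   and columns region, start, end, length, gc.
#' @slot gcTotal Overall GC percentage.
#' @slot geneCensus Named integer vector: counts of coding, tRNA, rRNA
#'   and other features (annotated occurrences, IR duplicates counted
#'   once each).
#' @seealso [summarizePlastome()], [detectInvertedRepeat()],
#'   [partitionRegions()]
#' @export
setClass("PlastomeStructure", representation(
    totalLength = "integer",
    regions = "data.frame",
    gcTotal = "numeric",
    geneCensus = "integer"))

setValidity("PlastomeStructure", function(object) {
    r <- object@regions
    if (!all(c("region", "start", "end", "length", "gc") %in% names(r)))
        return("regions must carry region,start,end,length,gc")
    if (sum(r$length) != object@totalLength)
        return("region lengths must sum to total length")
    gc <- r$gc[!is.na(r$gc)]
    if (any(gc < 0 | gc > 100)) return("GC must lie in [0,100]")
    TRUE
})
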