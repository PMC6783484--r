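#' Taxon labels of an object
#'
#' @param x A \linkS4class{PlastomeAlignment}, \linkS4class{SiteClassification}
#'   or \linkS4class{SnpPartition}.
#' @return Character vector of taxon labels in alignment order.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' Number of alignment columns
#'
#' @param x A \linkS4class{PlastomeAlignment} or
#'   \linkS4class{SiteClassification}.
#' @return Integer, alignment length in columns (bp).
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' Character state matrix of an alignment
#'
#' @param x A \linkS4class{PlastomeAlignment} or
#'   \linkS4class{SiteClassification}.
#' @return Character matrix, taxa (rows) by columns, over
#'   \code{{A,C,G,T,N,-}}.
#' @export
setGeneric("alignmentMatrix", function(x) standardGeneric("alignmentMatrix"))

#' Per-subset SNP counts of a partition
#'
#' @param x A \linkS4class{SnpPartition}.
#' @param drop Drop subsets with zero counts? Default \code{TRUE}.
#' @return Named integer vector; names encode taxon subsets with
#'   \code{"|"} separators.
#' @export
setGeneric("subsetCounts", function(x, drop = TRUE)
    standardGeneric("subsetCounts"))

#' Windows of a profile as a data.frame
#'
#' @param x A \linkS4class{WindowProfile}.
#' @return data.frame of windows (0-based half-open coordinates).
#' @export
setGeneric("profileWindows", function(x) standardGeneric("profileWindows"))

setMethod("taxa", "PlastomeAlignment", function(x) names(x@seqs))
setMethod("taxa", "SiteClassification", function(x) x@taxa)
setMethod("taxa", "SnpPartition", function(x) x@taxa)

setMethod("alignmentLength", "PlastomeAlignment",
          function(x) Biostrings::width(x@seqs)[1L])
setMethod("alignmentLength", "SiteClassification",
          function(x) length(x@isSnp))

setMethod("alignmentMatrix", "PlastomeAlignment", function(x) {
    m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
    rownames(m) <- names(x@seqs)
    m
})
setMethod("alignmentMatrix", "SiteClassification", function(x) x@states)

setMethod("subsetCounts", "SnpPartition", function(x, drop = TRUE) {
    if (drop) x@counts[x@counts > 0L] else x@counts
})

setMethod("profileWindows", "WindowProfile", function(x) x@windows)

setMethod("show", "PlastomeAlignment", function(object) {
    cat("PlastomeAlignment:", length(object@seqs), "taxa x",
        alignmentLength(object), "columns\n")
    cat("  taxa:", paste(utils::head(taxa(object), 8L), collapse = ", "))
    if (length(object@seqs) > 8L) cat(", ...")
    cat("\n")
})

setMethod("show", "SiteClassification", function(object) {
    cat("SiteClassification:", alignmentLength(object), "columns,",
        length(object@taxa), "taxa\n")
    cat(sprintf("  SNP: %d  indel: %d  uninformative: %d\n",
                sum(object@isSnp), sum(object@isIndel),
                sum(object@isUninformative)))
})

setMethod("show", "SnpPartition", function(object) {
    cat("SnpPartition over", length(object@taxa), "taxa;",
        object@totalSnpColumns, "SNP columns\n")
    cc <- sort(subsetCounts(object), decreasing = TRUE)
    for (nm in utils::head(names(cc), 6L))
        cat(sprintf("  {%s}: %d\n", nm, cc[[nm]]))
    if (length(cc) > 6L) cat("  ...\n")
})

setMethod("show", "WindowProfile", function(object) {
    cat("WindowProfile:", nrow(object@windows), "windows (L =",
        object@windowLength, "bp, step =", object@step, "bp)\n")
})

setMethod("show", "PDistanceResult", function(object) {
    cat("PDistanceResult (", object@deletion, " deletion)\n", sep = "")
    print(round(object@matrix, 4))
    if (object@deletion == "complete")
        cat("positions retained:", object@nComplete[1L, 1L], "\n")
})

setMethod("show", "PlastomeStructure", function(object) {
    cat("PlastomeStructure:", object@totalLength, "bp, GC",
        sprintf("%.1f%%\n", object@gcTotal))
    print(object@regions, row.names = FALSE)
    cat("gene census:",
        paste(names(object@geneCensus), object@geneCensus,
              sep = "=", collapse = "  "), "\n")
})
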