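#' Classify every alignment column
#'
#' Flags each column as a SNP (at least two distinct non-missing
#' nucleotide states among the rows; gaps and N are missing and never
#' create or block a SNP call), as an indel position (at least one row
#' gapped), and/or as uninformative (fewer than two non-missing rows).
#' The SNP and indel flags are independent: a gapped column can still be
#' a SNP among the non-gapped taxa.
#'
#' @param alignment A \linkS4class{PlastomeAlignment} with >= 2 taxa.
#' @return A \linkS4class{SiteClassification}.
#' @examples
#' aln <- plastomeAlignment(c(a = "ACGA", b = "ACTA", c = "AC-A"))
#' sites <- classifyColumns(aln)
#' countTotals(sites)
#' @export
classifyColumns <- function(alignment) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    m <- alignmentMatrix(alignment)
    if (nrow(m) < 2L)
        stop("classification requires at least 2 taxa")
    miss <- m == "N" | m == "-"
    nStates <- integer(ncol(m))
    for (b in BASES)
        nStates <- nStates + (colSums(m == b) > 0L)
    nonMissing <- nrow(m) - colSums(miss)
    new("SiteClassification",
        taxa = rownames(m),
        isSnp = nStates >= 2L,
        isIndel = colSums(m == "-") > 0L,
        isUninformative = nonMissing < 2L,
        states = m)
}

#' Allele-class partition of one column
#'
#' Partitions the non-missing taxa of a column by nucleotide state; taxa
#' carrying a gap or N are listed under \code{missing}.
#'
#' @param sites A \linkS4class{SiteClassification}.
#' @param column 0-based column index.
#' @return List with one element per observed state (character vectors of
#'   taxon labels) plus an element \code{missing}.
#' @export
alleleClasses <- function(sites, column) {
    stopifnot(is(sites, "SiteClassification"))
    if (column < 0L || column >= alignmentLength(sites))
        stop("column out of range")
    st <- sites@states[, column + 1L]
    isMiss <- st %in% c("N", "-")
    out <- split(sites@taxa[!isMiss], st[!isMiss])
    out$missing <- sites@taxa[isMiss]
    out
}

#' Column class totals
#'
#' @param sites A \linkS4class{SiteClassification}.
#' @return Named integer vector: \code{snp_columns},
#'   \code{indel_columns}, \code{uninformative_columns},
#'   \code{monomorphic_columns}.
#' @export
countTotals <- function(sites) {
    stopifnot(is(sites, "SiteClassification"))
    c(snp_columns = sum(sites@isSnp),
      indel_columns = sum(sites@isIndel),
      uninformative_columns = sum(sites@isUninformative),
      monomorphic_columns = sum(!sites@isSnp & !sites@isUninformative))
}

#' Private and shared SNPs over all taxon subsets
#'
#' For every SNP column, each allele class (the maximal set of
#' non-missing taxa sharing one nucleotide state) that is a proper,
#' non-empty subset of the full taxon set is credited once: every taxon
#' in the class shares one state and every other non-missing taxon
#' carries a different state.  Singleton credits are a species' private
#' SNPs — including columns where the remaining taxa are polymorphic
#' among themselves.  Monomorphic columns (a single class spanning all
#' non-missing taxa) credit nothing.  Each (column, subset) pair is
#' credited at most once.
#'
#' @param sites A \linkS4class{SiteClassification}.
#' @param taxaSet Optional character vector; must match the
#'   classification's taxa (any order).  Defaults to them.
#' @return A \linkS4class{SnpPartition}.
#' @examples
#' aln <- plastomeAlignment(c(q1 = "AAC", q2 = "CAC", q3 = "CAG",
#'                            q4 = "CAG", q5 = "CAC"))
#' subsetCounts(snpPartition(classifyColumns(aln)))
#' @export
snpPartition <- function(sites, taxaSet = taxa(sites)) {
    stopifnot(is(sites, "SiteClassification"))
    if (!setequal(taxaSet, taxa(sites)))
        stop("taxa do not match the classification")
    m <- sites@states
    tx <- sites@taxa
    counts <- new.env(parent = emptyenv())
    snpCols <- which(sites@isSnp)
    for (j in snpCols) {
        st <- m[, j]
        inf <- !(st %in% c("N", "-"))
        nInf <- sum(inf)
        cls <- split(tx[inf], st[inf])
        for (cl in cls) {
            if (length(cl) < nInf) {
                key <- paste(sort(cl), collapse = "|")
                counts[[key]] <- (if (is.null(counts[[key]])) 0L
                                  else counts[[key]]) + 1L
            }
        }
    }
    keys <- ls(counts)
    vals <- vapply(keys, function(k) counts[[k]], integer(1L))
    new("SnpPartition", taxa = tx,
        counts = setNames(as.integer(vals), keys),
        totalSnpColumns = length(snpCols))
}

#' Count of SNPs private to one taxon
#'
#' @param partition A \linkS4class{SnpPartition}.
#' @param taxon Taxon label.
#' @return Integer count of columns at which \code{taxon} carries a state
#'   unique among non-missing taxa.
#' @export
privateSnps <- function(partition, taxon) {
    stopifnot(is(partition, "SnpPartition"))
    if (!taxon %in% partition@taxa)
        stop("taxon '", taxon, "' not in partition")
    cc <- partition@counts
    if (taxon %in% names(cc)) unname(cc[[taxon]]) else 0L
}

#' Write the per-column site table to TSV
#'
#' Columns are reported 1-based; allele classes as
#' \code{state:taxon,taxon;...}.
#'
#' @param sites A \linkS4class{SiteClassification}.
#' @param path Output path.
#' @param variableOnly Only write SNP/indel columns (default TRUE; the
#'   full table of a plastome alignment is large).
#' @return Invisibly, \code{path}.
#' @export
writeSiteTable <- function(sites, path, variableOnly = TRUE) {
    keep <- if (variableOnly) which(sites@isSnp | sites@isIndel)
            else seq_len(alignmentLength(sites))
    cls <- ifelse(sites@isUninformative[keep], "uninformative",
                  ifelse(sites@isSnp[keep], "snp", "monomorphic"))
    alleles <- vapply(keep, function(j) {
        ac <- alleleClasses(sites, j - 1L)
        ac <- ac[names(ac) != "missing" | lengths(ac) > 0L]
        paste(vapply(names(ac), function(s)
            paste0(s, ":", paste(ac[[s]], collapse = ",")),
            character(1L)), collapse = ";")
    }, character(1L))
    out <- data.frame(column = keep, class = cls,
                      indel = sites@isIndel[keep], alleles = alleles)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write subset SNP counts as JSON
#'
#' Keys are sorted taxon-name tuples joined with \code{"|"}.
#'
#' @param partition A \linkS4class{SnpPartition}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSnpPartition <- function(partition, path) {
    obj <- list(taxa = partition@taxa,
                total_snp_columns = partition@totalSnpColumns,
                counts = as.list(subsetCounts(partition)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}
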