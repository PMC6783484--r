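IUPAC_AMBIG <- "RYSWKMBDHVryswkmbdhv"

#' Read a plastome multiple alignment from FASTA
#'
#' Reads a pre-aligned multi-FASTA file into a
#' \linkS4class{PlastomeAlignment}.  Lowercase letters are normalized to
#' uppercase and IUPAC ambiguity codes to N (a message reports how many
#' positions were normalized).  The gap character is \code{-} only;
#' \code{.} is rejected.
#'
#' @param path Path to an aligned FASTA file with >= 2 records.
#' @return A \linkS4class{PlastomeAlignment}.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "AC-T"), fa)
#' aln <- readAlignment(fa)
#' taxa(aln)
#' @export
readAlignment <- function(path) {
    if (!file.exists(path))
        stop("alignment file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) < 2L)
        stop("alignment must contain at least 2 records")
    labels <- sub("\\s.*$", "", names(raw))   # first token, FASTA convention
    rows <- as.character(raw)
    if (any(grepl(".", rows, fixed = TRUE)))
        stop("'.' gap characters are not supported; use '-'")
    if (anyDuplicated(labels))
        stop("duplicate taxon label: ", labels[duplicated(labels)][1L])
    widths <- nchar(rows)
    if (length(unique(widths)) != 1L) {
        bad <- labels[widths != widths[1L]][1L]
        stop("records are not aligned (unequal lengths); first offending record: ",
             bad)
    }
    rows <- toupper(rows)
    nAmbig <- sum(nchar(rows)) -
        sum(nchar(gsub(sprintf("[%s]", toupper(IUPAC_AMBIG)), "", rows)))
    if (nAmbig > 0L) {
        rows <- chartr(toupper(IUPAC_AMBIG),
                       strrep("N", nchar(IUPAC_AMBIG)), rows)
        message(nAmbig, " ambiguity position(s) normalized to N")
    }
    bad <- grepl("[^ACGTN-]", rows)
    if (any(bad))
        stop("record '", labels[bad][1L],
             "' contains characters outside {A,C,G,T,N,-}")
    seqs <- Biostrings::DNAStringSet(setNames(rows, labels))
    new("PlastomeAlignment", seqs = seqs)
}

#' Write an alignment to FASTA
#'
#' @param x A \linkS4class{PlastomeAlignment}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAlignment <- function(x, path) {
    stopifnot(is(x, "PlastomeAlignment"))
    Biostrings::writeXStringSet(x@seqs, path)
    invisible(path)
}

#' Construct a PlastomeAlignment from in-memory sequences
#'
#' @param rows Named character vector of equal-length gapped sequences,
#'   or a named \code{DNAStringSet}.
#' @return A \linkS4class{PlastomeAlignment}.
#' @export
plastomeAlignment <- function(rows) {
    if (is.character(rows))
        rows <- Biostrings::DNAStringSet(toupper(rows))
    new("PlastomeAlignment", seqs = rows)
}

#' Parse features and sequence from a GenBank flatfile
#'
#' Minimal GenBank flatfile parser: extracts the feature table (CDS,
#' tRNA, rRNA and other keys; \code{join}/\code{order}/\code{complement}
#' locations flattened to interval lists) and the ORIGIN sequence.
#' Coordinates are converted from GenBank 1-based inclusive to 0-based
#' half-open.  Unparseable locations are skipped with a warning.
#'
#' @param path Path to a GenBank flatfile containing an ORIGIN block.
#' @return A list with elements \code{features} (data.frame: name, kind
#'   in coding/tRNA/rRNA/other, start, end, strand) and \code{sequence}
#'   (a \code{DNAString}).
#' @export
readGenBankFeatures <- function(path) {
    lines <- readLines(path)
    oi <- grep("^ORIGIN", lines)
    if (length(oi) == 0L)
        stop("no ORIGIN sequence block in ", path)
    endi <- grep("^//", lines)
    endi <- if (length(endi)) endi[endi > oi[1L]][1L] else length(lines) + 1L
    seqlines <- lines[seq.int(oi[1L] + 1L, endi - 1L)]
    seqstr <- toupper(gsub("[^a-zA-Z]", "", paste(seqlines, collapse = "")))
    if (!nzchar(seqstr))
        stop("empty ORIGIN sequence in ", path)
    seqstr <- chartr(toupper(IUPAC_AMBIG), strrep("N", nchar(IUPAC_AMBIG)),
                     seqstr)

    fi <- grep("^FEATURES", lines)
    feats <- list()
    skipped <- 0L
    if (length(fi)) {
        block <- lines[seq.int(fi[1L] + 1L, oi[1L] - 1L)]
        # feature lines have the key at column 6; qualifiers are deeper
        isKey <- grepl("^ {5}\\S", block)
        keyIdx <- which(isKey)
        for (j in seq_along(keyIdx)) {
            i0 <- keyIdx[j]
            i1 <- if (j < length(keyIdx)) keyIdx[j + 1L] - 1L
                  else length(block)
            key <- sub("^ {5}(\\S+).*", "\\1", block[i0])
            if (key == "source") next
            body <- block[i0:i1]
            loc <- sub("^ {5}\\S+\\s+", "", body[1L])
            k <- 2L
            # location may continue on lines before the first qualifier
            while (k <= length(body) && !grepl("^\\s+/", body[k])) {
                loc <- paste0(loc, gsub("\\s", "", body[k]))
                k <- k + 1L
            }
            quals <- body[grepl("^\\s+/", body)]
            name <- .gbQualifier(quals, "gene")
            if (is.na(name)) name <- .gbQualifier(quals, "locus_tag")
            if (is.na(name)) name <- paste0(key, "_", j)
            strand <- if (grepl("complement", loc)) "-" else "+"
            ivs <- .gbLocationIntervals(loc)
            if (is.null(ivs)) {
                skipped <- skipped + 1L
                warning("skipping unparseable location for '", name,
                        "': ", loc, call. = FALSE)
                next
            }
            kind <- switch(key, CDS = "coding", tRNA = "tRNA",
                           rRNA = "rRNA", "other")
            feats[[length(feats) + 1L]] <- data.frame(
                name = name, kind = kind,
                start = ivs[, 1L], end = ivs[, 2L],
                strand = strand, occurrence = j,
                stringsAsFactors = FALSE)
        }
    }
    features <- if (length(feats)) do.call(rbind, feats)
        else data.frame(name = character(), kind = character(),
                        start = integer(), end = integer(),
                        strand = character(), occurrence = integer(),
                        stringsAsFactors = FALSE)
    if (any(features$end > nchar(seqstr)))
        warning("feature interval(s) extend beyond sequence length")
    list(features = features,
         sequence = Biostrings::DNAString(seqstr),
         skipped = skipped)
}

.gbQualifier <- function(quals, what) {
    hit <- grep(sprintf("^\\s+/%s=", what), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub("\"", "", sub(sprintf("^\\s+/%s=", what), "", hit[1L]))
}

# "10..30", "join(1..5,8..12)", "complement(join(...))", single base "42"
# -> matrix of 0-based half-open intervals, or NULL if unparseable
.gbLocationIntervals <- function(loc) {
    core <- gsub("complement\\(|join\\(|order\\(|\\)", "", loc)
    core <- gsub("[<>]", "", core)
    parts <- strsplit(core, ",", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return(NULL)
    ok <- grepl("^\\d+(\\.\\.\\d+)?$", parts)
    if (!all(ok)) return(NULL)
    ivs <- t(vapply(parts, function(p) {
        nn <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
        if (length(nn) == 1L) nn <- c(nn, nn)
        c(nn[1L] - 1L, nn[2L])
    }, integer(2L)))
    dimnames(ivs) <- NULL
    ivs
}

#' Write a feature table to TSV
#'
#' Intervals are written 1-based inclusive (GenBank convention).
#'
#' @param features Feature data.frame as returned by
#'   [readGenBankFeatures()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(features, path) {
    out <- data.frame(name = features$name, kind = features$kind,
                      start = features$start + 1L, end = features$end,
                      strand = features$strand)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Map ungapped positions to alignment columns (and back)
#'
#' \code{mapUngappedToAlignment} returns, for each 0-based position on a
#' taxon's ungapped sequence, the 0-based alignment column holding that
#' residue.  \code{mapAlignmentToUngapped} is the inverse, defined on
#' non-gap columns of the taxon's row.  The mapping is strictly monotone
#' and bijective between non-gap columns and ungapped positions.
#'
#' @param alignment A \linkS4class{PlastomeAlignment}.
#' @param taxon Taxon label.
#' @param positions Integer vector of 0-based ungapped positions.
#' @param columns Integer vector of 0-based alignment columns (non-gap in
#'   the taxon's row).
#' @return Integer vector of 0-based coordinates.
#' @export
mapUngappedToAlignment <- function(alignment, taxon, positions) {
    row <- .alignedRow(alignment, taxon)
    nonGap <- which(row != "-")
    if (any(positions < 0L) || any(positions >= length(nonGap)))
        stop("position out of range of ungapped sequence for '", taxon,
             "' (length ", length(nonGap), ")")
    nonGap[positions + 1L] - 1L
}

#' @rdname mapUngappedToAlignment
#' @export
mapAlignmentToUngapped <- function(alignment, taxon, columns) {
    row <- .alignedRow(alignment, taxon)
    if (any(columns < 0L) || any(columns >= length(row)))
        stop("column out of range")
    if (any(row[columns + 1L] == "-"))
        stop("column is a gap in '", taxon, "'")
    cumsum(row != "-")[columns + 1L] - 1L
}

.alignedRow <- function(alignment, taxon) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    if (!taxon %in% taxa(alignment))
        stop("taxon '", taxon, "' not found in alignment")
    strsplit(as.character(alignment@seqs[[taxon]]), "")[[1L]]
}
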