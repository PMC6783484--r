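#' Pairwise p-distances
#'
#' Uncorrected distances (proportion of differing sites).  Under complete
#' deletion (the default) every column containing a gap or an N in any
#' row is removed first, so all pairs share one denominator; under
#' pairwise deletion each pair uses its own set of fully resolved
#' columns.
#'
#' @param alignment A \linkS4class{PlastomeAlignment} with >= 2 taxa.
#' @param deletion \code{"complete"} (default) or \code{"pairwise"}.
#' @return A \linkS4class{PDistanceResult}.
#' @examples
#' aln <- plastomeAlignment(c(a = "ACGTACGTAC",
#'                            b = "ACGTACGTCC",
#'                            c = "AC-TACGTAC"))
#' pDistance(aln)
#' @export
pDistance <- function(alignment, deletion = c("complete", "pairwise")) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    deletion <- match.arg(deletion)
    m <- alignmentMatrix(alignment)
    if (nrow(m) < 2L) stop("p-distance requires at least 2 taxa")
    tx <- rownames(m)
    nt <- length(tx)
    d <- matrix(0, nt, nt, dimnames = list(tx, tx))
    nc <- matrix(0L, nt, nt, dimnames = list(tx, tx))
    miss <- m == "N" | m == "-"
    if (deletion == "complete") {
        keep <- colSums(miss) == 0L
        nComplete <- sum(keep)
        if (nComplete == 0L)
            stop("no complete columns after removing gaps and missing data")
        mm <- m[, keep, drop = FALSE]
        for (i in seq_len(nt - 1L)) for (j in seq.int(i + 1L, nt)) {
            mis <- sum(mm[i, ] != mm[j, ])
            d[i, j] <- d[j, i] <- mis / nComplete
        }
        nc[] <- nComplete
    } else {
        for (i in seq_len(nt - 1L)) for (j in seq.int(i + 1L, nt)) {
            ok <- !miss[i, ] & !miss[j, ]
            n <- sum(ok)
            if (n == 0L)
                stop("no comparable columns between '", tx[i], "' and '",
                     tx[j], "'")
            d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / n
            nc[i, j] <- nc[j, i] <- n
        }
        diag(nc) <- ncol(m)
    }
    new("PDistanceResult", matrix = d, nComplete = nc, deletion = deletion)
}

#' Number of columns retained by complete deletion
#'
#' @param x A \linkS4class{PDistanceResult} computed with
#'   \code{deletion = "complete"}.
#' @return Integer.
#' @export
nCompletePositions <- function(x) {
    stopifnot(is(x, "PDistanceResult"))
    if (x@deletion != "complete")
        stop("defined for complete deletion only")
    x@nComplete[1L, 1L]
}

#' Tajima's one-degree-of-freedom relative rate test
#'
#' Restricts the alignment to columns at which the two ingroup taxa and
#' the outgroup are all non-missing and non-gap, counts the sites at
#' which each ingroup taxon alone differs (\code{mA}: A differs while B
#' equals the outgroup; \code{mB} symmetric), and tests rate constancy
#' with \eqn{\chi^2 = (mA - mB)^2 / (mA + mB)} on 1 degree of freedom.
#' Equal unique-site counts are expected under equal rates; when the test
#' is significant the taxon with the smaller count is the slower lineage.
#' With \code{mA + mB = 0} the data carry no information: chi2 = 0,
#' p = 1.
#'
#' @param alignment A \linkS4class{PlastomeAlignment}.
#' @param taxonA,taxonB Ingroup taxon labels.
#' @param outgroup Outgroup taxon label.
#' @return List of class \code{rateTest}: taxonA, taxonB, outgroup, mA,
#'   mB, nSites (columns compared), chi2, p, slowerTaxon (NA when
#'   mA == mB).
#' @examples
#' aln <- plastomeAlignment(c(A = "ACGTACGTAA", B = "ACGTACGTAC",
#'                            O = "ACGTACGTAC"))
#' tajimaRRT(aln, "A", "B", "O")
#' @export
tajimaRRT <- function(alignment, taxonA, taxonB, outgroup) {
    stopifnot(is(alignment, "PlastomeAlignment"))
    who <- c(taxonA, taxonB, outgroup)
    if (anyDuplicated(who)) stop("taxa must be three distinct labels")
    missing <- setdiff(who, taxa(alignment))
    if (length(missing)) stop("taxon not found: ", missing[1L])
    m <- alignmentMatrix(alignment)[who, , drop = FALSE]
    ok <- colSums(m == "N" | m == "-") == 0L
    a <- m[1L, ok]; b <- m[2L, ok]; o <- m[3L, ok]
    mA <- sum(a != b & b == o)
    mB <- sum(b != a & a == o)
    chi2 <- if (mA + mB == 0L) 0 else (mA - mB)^2 / (mA + mB)
    p <- if (mA + mB == 0L) 1 else pchisq(chi2, df = 1L, lower.tail = FALSE)
    slower <- if (mA == mB) NA_character_
              else if (mA < mB) taxonA else taxonB
    structure(list(taxonA = taxonA, taxonB = taxonB, outgroup = outgroup,
                   mA = mA, mB = mB, nSites = sum(ok),
                   chi2 = chi2, p = p, slowerTaxon = slower),
              class = "rateTest")
}

#' @export
print.rateTest <- function(x, ...) {
    cat(sprintf(
        "Tajima relative rate test: %s vs %s (outgroup %s)\n",
        x$taxonA, x$taxonB, x$outgroup))
    cat(sprintf("  unique sites: %d vs %d (of %d compared)\n",
                x$mA, x$mB, x$nSites))
    cat(sprintf("  chi2 = %.4g (1 df), p = %.4g\n", x$chi2, x$p))
    if (!is.na(x$slowerTaxon))
        cat("  slower lineage:", x$slowerTaxon, "\n")
    invisible(x)
}

#' Relative rate tests for all ingroup pairs
#'
#' Runs [tajimaRRT()] on every unordered pair of ingroup taxa against a
#' common outgroup.
#'
#' @param alignment A \linkS4class{PlastomeAlignment}.
#' @param ingroup Character vector of >= 2 ingroup taxon labels.
#' @param outgroup Outgroup taxon label.
#' @param alpha Significance level for the annotation column (default
#'   0.01).
#' @return data.frame with one row per pair: taxonA, taxonB, mA, mB,
#'   chi2, p, significant (p < alpha), slowerTaxon (only reported for
#'   significant pairs).
#' @export
rrtAllPairs <- function(alignment, ingroup, outgroup, alpha = 0.01) {
    if (length(ingroup) < 2L) stop("need at least 2 ingroup taxa")
    prs <- utils::combn(ingroup, 2L)
    rows <- lapply(seq_len(ncol(prs)), function(k) {
        r <- tajimaRRT(alignment, prs[1L, k], prs[2L, k], outgroup)
        data.frame(taxonA = r$taxonA, taxonB = r$taxonB,
                   mA = r$mA, mB = r$mB, chi2 = r$chi2, p = r$p,
                   significant = r$p < alpha,
                   slowerTaxon = if (r$p < alpha) r$slowerTaxon
                                 else NA_character_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Write a p-distance matrix to TSV
#'
#' @param x A \linkS4class{PDistanceResult}.
#' @param path Output path.
#' @param digits Rounding for the distances (default 6).
#' @return Invisibly, \code{path}.
#' @export
writeDistanceMatrix <- function(x, path, digits = 6L) {
    con <- file(path, "w")
    on.exit(close(con))
    if (x@deletion == "complete")
        writeLines(sprintf("# complete deletion; positions retained=%d",
                           nCompletePositions(x)), con)
    else writeLines("# pairwise deletion", con)
    out <- cbind(taxon = rownames(x@matrix),
                 as.data.frame(round(x@matrix, digits)))
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a relative-rate-test table to TSV
#'
#' @param rrt data.frame from [rrtAllPairs()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeRrtTable <- function(rrt, path) {
    out <- rrt
    out$chi2 <- round(out$chi2, 4)
    out$p <- signif(out$p, 4)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
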