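#' Configuration for the plastome alignment simulator
#'
#' Defines the study conditions emulated by the generator: a
#' quadripartite plastome (LSC + IRa + SSC + IRb, with IRb the reverse
#' complement of IRa), five ingroup taxa plus one outgroup evolving on a
#' star tree, strongly reduced substitution and indel rates inside the
#' IRs, a handful of localized mutation hotspots standing in for
#' variable intergenic spacers, a background indel process, one long
#' single-taxon deletion, and optional lineage rate multipliers for
#' relative-rate power studies.
#'
#' Defaults mirror a real oak plastome comparison: region sizes 90353 /
#' 25840 / 18955 bp, base composition A 31.1 / C 18.7 / G 18.0 / T
#' 32.2 %, per-branch substitution rate 0.002 substitutions/site for the
#' ingroup (so pairwise distances on a star tree are about 0.004-0.005)
#' and 0.012 for the outgroup branch, IR rate multiplier 0.1, four 750
#' bp hotspots at 12x the background rate, gap-run initiation rate 2e-4
#' per site with mean run length 8 bp, and one planted 600 bp deletion.
#'
#' @param nIngroup Number of ingroup taxa (default 5).
#' @param outgroup Include an outgroup taxon? Default TRUE.
#' @param regionLengths Named integer vector \code{c(LSC, IRa, SSC)};
#'   IRb duplicates IRa.
#' @param baseFreqs Named A/C/G/T frequencies, summing to 1.
#' @param substRate Ingroup per-branch substitution rate
#'   (substitutions/site).
#' @param outgroupRate Outgroup branch substitution rate.
#' @param irMultiplier Rate multiplier inside the IRs (default 0.1).
#' @param hotspots data.frame(start, end, multiplier) in genome
#'   coordinates, or NULL for the default four hotspots.
#' @param indelRate Per-site, per-taxon probability of starting a gap
#'   run.
#' @param indelMeanLength Mean gap-run length, bp.
#' @param longDeletions data.frame(taxon, start, length) of planted
#'   deletions, or NULL for the default single event.
#' @param lineageMultipliers Per-ingroup-taxon rate multipliers
#'   (default all 1).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nIngroup = 5L,
                             outgroup = TRUE,
                             regionLengths = c(LSC = 90353L, IRa = 25840L,
                                               SSC = 18955L),
                             baseFreqs = c(A = 0.311, C = 0.187,
                                           G = 0.180, T = 0.322),
                             substRate = 0.002,
                             outgroupRate = 0.012,
                             irMultiplier = 0.1,
                             hotspots = NULL,
                             indelRate = 2e-4,
                             indelMeanLength = 8,
                             longDeletions = NULL,
                             lineageMultipliers = NULL,
                             seed = 1L) {
    regionLengths <- as.integer(regionLengths)
    names(regionLengths) <- c("LSC", "IRa", "SSC")
    if (any(regionLengths <= 0L)) stop("region lengths must be > 0")
    if (nIngroup < 2L) stop("need at least 2 ingroup taxa")
    if (abs(sum(baseFreqs) - 1) > 1e-6) stop("base frequencies must sum to 1")
    if (substRate < 0 || outgroupRate < 0 || indelRate < 0)
        stop("rates must be >= 0")
    if (irMultiplier <= 0) stop("multipliers must be > 0")
    lsc <- regionLengths[["LSC"]]; ira <- regionLengths[["IRa"]]
    ssc <- regionLengths[["SSC"]]
    total <- lsc + 2L * ira + ssc
    if (is.null(hotspots)) {
        # four hotspot spacers: three in the LSC, one at the SSC 3' end
        w <- min(750L, max(50L, lsc %/% 10L))
        starts <- c(round(lsc * c(0.10, 0.40, 0.72)),
                    lsc + ira + round(ssc * 0.75))
        hotspots <- data.frame(start = as.integer(starts),
                               end = as.integer(starts + w),
                               multiplier = 12)
    }
    if (any(hotspots$multiplier <= 0)) stop("multipliers must be > 0")
    if (any(hotspots$end > total)) stop("hotspot beyond genome end")
    if (is.null(longDeletions)) {
        len <- min(600L, lsc %/% 4L)
        longDeletions <- data.frame(taxon = 2L,
                                    start = as.integer(round(lsc * 0.55)),
                                    length = len)
    }
    if (is.null(lineageMultipliers))
        lineageMultipliers <- rep(1, nIngroup)
    if (length(lineageMultipliers) != nIngroup)
        stop("need one lineage multiplier per ingroup taxon")
    if (any(lineageMultipliers <= 0)) stop("multipliers must be > 0")
    structure(list(
        nIngroup = as.integer(nIngroup), outgroup = isTRUE(outgroup),
        regionLengths = regionLengths, baseFreqs = baseFreqs,
        substRate = substRate, outgroupRate = outgroupRate,
        irMultiplier = irMultiplier, hotspots = hotspots,
        indelRate = indelRate, indelMeanLength = indelMeanLength,
        longDeletions = longDeletions,
        lineageMultipliers = lineageMultipliers,
        seed = if (is.null(seed)) NULL else as.integer(seed)),
        class = "SimulationConfig")
}

.randomSeq <- function(n, freqs) {
    paste(sample(BASES, n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate an annotated reference plastome
#'
#' Builds a random quadripartite genome LSC + IRa + SSC + revcomp(IRa)
#' under the configured base composition and places toy CDS / tRNA /
#' rRNA features in each region (rRNAs inside the IRs, mirrored into
#' IRb, so the census counts each IR copy).
#'
#' @param config A \code{SimulationConfig}.
#' @return List: \code{sequence} (character string), \code{features}
#'   (data.frame: name, kind, start, end, strand, occurrence),
#'   \code{regions} (data.frame of true LSC/IRa/SSC/IRb spans),
#'   \code{config}.
#' @export
simulateReference <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (!is.null(config$seed)) set.seed(config$seed)
    lsc <- config$regionLengths[["LSC"]]
    irl <- config$regionLengths[["IRa"]]
    ssc <- config$regionLengths[["SSC"]]
    ira <- .randomSeq(irl, config$baseFreqs)
    genome <- paste0(.randomSeq(lsc, config$baseFreqs), ira,
                     .randomSeq(ssc, config$baseFreqs), revComp(ira))
    # the planted arms must be maximal: break complementarity at the four
    # junctions so no exact extension into the single-copy regions exists
    v <- strsplit(genome, "", fixed = TRUE)[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (v[lsc] == comp[[v[1L]]])                   # LSC end vs LSC start
        v[1L] <- setdiff(BASES, comp[[v[lsc]]])[1L]
    sscFirst <- lsc + irl + 1L
    sscLast <- lsc + irl + ssc
    if (v[sscFirst] == comp[[v[sscLast]]])         # SSC start vs SSC end
        v[sscFirst] <- setdiff(BASES, comp[[v[sscLast]]])[1L]
    genome <- paste(v, collapse = "")
    n <- nchar(genome)
    regions <- data.frame(
        region = c("LSC", "IRa", "SSC", "IRb"),
        start = c(0L, lsc, lsc + irl, lsc + irl + ssc),
        end = c(lsc, lsc + irl, lsc + irl + ssc, n),
        length = c(lsc, irl, ssc, irl))
    feats <- .toyFeatures(lsc, irl, ssc)
    list(sequence = genome, features = feats, regions = regions,
         config = config)
}

# toy annotation: evenly spaced CDS in the single-copy regions with a
# tRNA in each inter-gene gap; rRNAs in IRa mirrored into IRb
.toyFeatures <- function(lsc, irl, ssc) {
    rows <- list()
    occ <- 0L
    addGenes <- function(rows, offset, len, prefix) {
        geneLen <- max(60L, min(900L, len %/% 6L))
        pitch <- geneLen * 3L
        starts <- seq.int(offset + pitch %/% 4L, offset + len - geneLen,
                          by = pitch)
        for (i in seq_along(starts)) {
            occ <<- occ + 1L
            rows[[length(rows) + 1L]] <- data.frame(
                name = sprintf("%sG%d", prefix, i), kind = "coding",
                start = starts[i], end = starts[i] + geneLen,
                strand = if (i %% 2L) "+" else "-", occurrence = occ)
            tLen <- 72L
            tStart <- starts[i] + geneLen + (pitch - geneLen) %/% 2L
            if (tStart + tLen <= offset + len) {
                occ <<- occ + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    name = sprintf("%sT%d", prefix, i), kind = "tRNA",
                    start = tStart, end = tStart + tLen,
                    strand = "+", occurrence = occ)
            }
        }
        rows
    }
    rows <- addGenes(rows, 0L, lsc, "lsc")
    rows <- addGenes(rows, lsc + irl, ssc, "ssc")
    nRrna <- if (irl >= 400L) 4L else 1L
    rLen <- max(40L, min(1500L, irl %/% (2L * nRrna)))
    for (i in seq_len(nRrna)) {
        s <- lsc + round((i - 0.7) * irl / nRrna)
        occ <- occ + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("rrn%d", i), kind = "rRNA",
            start = s, end = s + rLen, strand = "+", occurrence = occ)
        # mirrored IRb copy
        total <- lsc + 2L * irl + ssc
        occ <- occ + 1L
        rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("rrn%d", i), kind = "rRNA",
            start = total - (s - lsc) - rLen,
            end = total - (s - lsc), strand = "-", occurrence = occ)
    }
    out <- do.call(rbind, rows)
    out$start <- as.integer(out$start); out$end <- as.integer(out$end)
    out[order(out$start), ]
}

#' Simulate a gapped multiple alignment from a reference plastome
#'
#' Each taxon evolves independently from the reference on a star tree.
#' Substitutions are Jukes-Cantor style (uniform choice among the three
#' alternative bases) with per-site probability branch rate x region
#' multiplier x hotspot multiplier x lineage multiplier.  Indels are
#' applied post-substitution as single-taxon gap runs (geometric
#' lengths) plus the configured planted long deletions; runs never
#' overlap a column already gapped in another taxon, keeping the truth
#' bookkeeping exact.  No insertions are simulated, so alignment columns
#' coincide with reference coordinates.
#'
#' @param reference Output of [simulateReference()].
#' @param config A \code{SimulationConfig} (defaults to the reference's).
#' @return List: \code{alignment} (a \linkS4class{PlastomeAlignment};
#'   taxa \code{ingroup1..k} plus \code{outgroup}) and \code{truth}
#'   (see Details).
#' @details The truth table contains per-column logical vectors
#'   \code{isSnp}, \code{isIndel}, \code{isUninformative} (computed from
#'   the simulated state matrix by a direct per-column enumeration),
#'   per-subset SNP credits \code{subsetCredits}, planted
#'   \code{hotspots}, realized \code{deletions}, true \code{regions} and
#'   \code{lineageRates}, and the \code{seed}.
#' @export
simulateAlignment <- function(reference, config = reference$config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (!is.null(config$seed))
        set.seed((config$seed + 1L) %% 2147483647L)
    refChars <- strsplit(reference$sequence, "", fixed = TRUE)[[1L]]
    n <- length(refChars)
    nIn <- config$nIngroup
    txNames <- c(paste0("ingroup", seq_len(nIn)),
                 if (config$outgroup) "outgroup")
    nTx <- length(txNames)

    # per-site rate multiplier: regions then hotspots
    mult <- rep(1, n)
    reg <- reference$regions
    for (i in seq_len(nrow(reg)))
        if (reg$region[i] %in% c("IRa", "IRb"))
            mult[seq.int(reg$start[i] + 1L, reg$end[i])] <- config$irMultiplier
    hs <- config$hotspots
    for (i in seq_len(nrow(hs)))
        mult[seq.int(hs$start[i] + 1L, hs$end[i])] <-
            mult[seq.int(hs$start[i] + 1L, hs$end[i])] * hs$multiplier[i]

    refIdx <- match(refChars, BASES)           # NA for N
    m <- matrix(refChars, nrow = nTx, ncol = n, byrow = TRUE,
                dimnames = list(txNames, NULL))
    branch <- c(config$substRate * config$lineageMultipliers,
                if (config$outgroup) config$outgroupRate)
    for (t in seq_len(nTx)) {
        p <- pmin(branch[t] * mult, 0.75)
        mut <- which(runif(n) < p & !is.na(refIdx))
        if (length(mut)) {
            shift <- sample.int(3L, length(mut), replace = TRUE)
            m[t, mut] <- BASES[(refIdx[mut] - 1L + shift) %% 4L + 1L]
        }
    }

    # indels: planted long deletions first, then background gap runs
    gapped <- logical(n)                       # columns gapped in ANY taxon
    delRows <- list()
    plant <- config$longDeletions
    for (i in seq_len(nrow(plant))) {
        t <- if (is.character(plant$taxon)) match(plant$taxon[i], txNames)
             else plant$taxon[i]
        if (is.na(t) || t < 1L || t > nTx)
            stop("long-deletion taxon not in simulated taxa")
        span <- seq.int(plant$start[i] + 1L,
                        min(n, plant$start[i] + plant$length[i]))
        m[t, span] <- "-"
        gapped[span] <- TRUE
        delRows[[length(delRows) + 1L]] <- data.frame(
            taxon = txNames[t], start = span[1L] - 1L,
            end = span[length(span)], planted = TRUE)
    }
    if (config$indelRate > 0) for (t in seq_len(nTx)) {
        pIndel <- pmin(config$indelRate * mult, 0.5)
        starts <- which(runif(n) < pIndel)
        if (!length(starts)) next
        lens <- stats::rgeom(length(starts), 1 / config$indelMeanLength) + 1L
        for (k in seq_along(starts)) {
            span <- seq.int(starts[k], min(n, starts[k] + lens[k] - 1L))
            if (any(gapped[span])) next        # keep events single-taxon
            m[t, span] <- "-"
            gapped[span] <- TRUE
            delRows[[length(delRows) + 1L]] <- data.frame(
                taxon = txNames[t], start = span[1L] - 1L,
                end = span[length(span)], planted = FALSE)
        }
    }
    deletions <- if (length(delRows)) do.call(rbind, delRows)
        else data.frame(taxon = character(), start = integer(),
                        end = integer(), planted = logical())

    truth <- .truthFromStates(m)
    truth$hotspots <- hs
    truth$deletions <- deletions[order(deletions$start), , drop = FALSE]
    truth$regions <- reg
    truth$lineageRates <- setNames(config$substRate *
                                   config$lineageMultipliers,
                                   txNames[seq_len(nIn)])
    truth$seed <- config$seed
    aln <- plastomeAlignment(setNames(
        vapply(seq_len(nTx), function(t) paste(m[t, ], collapse = ""),
               character(1L)), txNames))
    list(alignment = aln, truth = truth)
}

# ground truth by direct per-column enumeration over the state matrix
.truthFromStates <- function(m) {
    n <- ncol(m)
    isSnp <- logical(n); isIndel <- logical(n); isUninf <- logical(n)
    credits <- new.env(parent = emptyenv())
    tx <- rownames(m)
    # fast path: columns identical in all rows with no gap/N need no loop
    same <- colSums(m != m[rep(1L, nrow(m)), , drop = FALSE]) == 0L
    clean <- same & m[1L, ] %in% BASES
    for (j in which(!clean)) {
        st <- m[, j]
        isIndel[j] <- any(st == "-")
        inf <- !(st %in% c("N", "-"))
        nInf <- sum(inf)
        if (nInf < 2L) { isUninf[j] <- TRUE; next }
        cls <- split(tx[inf], st[inf])
        if (length(cls) >= 2L) {
            isSnp[j] <- TRUE
            for (cl in cls) if (length(cl) < nInf) {
                key <- paste(sort(cl), collapse = "|")
                credits[[key]] <- (if (is.null(credits[[key]])) 0L
                                   else credits[[key]]) + 1L
            }
        }
    }
    keys <- ls(credits)
    list(isSnp = isSnp, isIndel = isIndel, isUninformative = isUninf,
         subsetCredits = setNames(
             vapply(keys, function(k) credits[[k]], integer(1L)), keys))
}

#' Simulate replicate triples for relative-rate testing
#'
#' Generates independent (A, B, outgroup) alignments under flat per-site
#' rates: B evolves at \code{config$substRate}, A at
#' \code{rateRatio} times that, and the outgroup at
#' \code{config$outgroupRate}.  Used to measure the type-I error and the
#' power of [tajimaRRT()].
#'
#' @param config A \code{SimulationConfig} (its seed fixes the whole
#'   replicate stream).
#' @param nReplicates Number of replicates (>= 1).
#' @param seqLength Sequence length per replicate, bp (default 10000).
#' @param rateRatio Rate ratio A : B (default 1, the null).
#' @return List of \linkS4class{PlastomeAlignment}s with taxa A, B, O.
#' @export
simulateRRTReplicates <- function(config, nReplicates,
                                  seqLength = 10000L, rateRatio = 1) {
    stopifnot(inherits(config, "SimulationConfig"), nReplicates >= 1L)
    if (rateRatio <= 0) stop("rateRatio must be > 0")
    if (!is.null(config$seed))
        set.seed((config$seed + 2L) %% 2147483647L)
    n <- as.integer(seqLength)
    rates <- c(A = config$substRate * rateRatio, B = config$substRate,
               O = config$outgroupRate)
    lapply(seq_len(nReplicates), function(r) {
        anc <- sample.int(4L, n, replace = TRUE, prob = config$baseFreqs)
        rows <- vapply(rates, function(rate) {
            x <- anc
            mut <- which(runif(n) < min(rate, 0.75))
            if (length(mut)) {
                shift <- sample.int(3L, length(mut), replace = TRUE)
                x[mut] <- (x[mut] - 1L + shift) %% 4L + 1L
            }
            paste(BASES[x], collapse = "")
        }, character(1L))
        plastomeAlignment(rows)
    })
}
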