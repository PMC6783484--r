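plantedAlignment <- function(len, snpCols = integer(), gapRuns = list()) {
    m <- matrix("A", nrow = 5, ncol = len,
                dimnames = list(paste0("t", 1:5), NULL))
    m[1, snpCols] <- "G"
    for (g in gapRuns) m[g$taxon, g$cols] <- "-"
    matrixToAlignment(m)
}

test_that("window counts match a brute-force recount", {
    aln <- plantedAlignment(1000, snpCols = c(100, 300, 600))
    sites <- classifyColumns(aln)
    prof <- windowProfile(sites, L = 500, s = 250)
    w <- profileWindows(prof)
    expect_identical(w$start, c(0L, 250L, 500L))
    expect_identical(w$snpCount, c(2L, 2L, 1L))
    expect_identical(w$midpoint, w$start + 250)
    # brute-force recount of every window
    for (i in seq_len(nrow(w))) {
        cols <- seq.int(w$start[i] + 1L, w$end[i])
        expect_identical(w$snpCount[i], sum(sites@isSnp[cols]))
        expect_identical(w$indelCount[i], sum(sites@isIndel[cols]))
    }
    expect_equal(w$indelPerKb, w$indelCount / 500 * 1000)
})

test_that("zero variation gives all-zero counts and window math is validated", {
    aln <- plantedAlignment(1000)
    sites <- classifyColumns(aln)
    prof <- windowProfile(sites)
    expect_true(all(profileWindows(prof)$snpCount == 0))
    expect_error(windowProfile(sites, L = 2000), "smaller L")
    expect_error(windowProfile(sites, L = 500, s = 600), "step")
    # non-overlapping windows partition the covered span
    p2 <- windowProfile(sites, L = 250, s = 250)
    expect_identical(sum(profileWindows(p2)$snpCount),
                     sum(sites@isSnp[1:1000]))
})

test_that("overlapping selected windows merge and distinct SNPs are counted once", {
    aln <- plantedAlignment(1000, snpCols = c(11, 261, 401, 601))
    sites <- classifyColumns(aln)
    prof <- windowProfile(sites, L = 500, s = 250)
    # windows [0,500) and [250,750) hold >= 2 SNPs each; [500,1000) has 1
    hs <- detectHotspots(prof, sites, "min_count", 2)
    expect_identical(nrow(hs), 1L)
    expect_identical(c(hs$start, hs$end), c(0L, 750L))
    expect_identical(hs$snpTotal, 4L)
    expect_identical(hs$mergedWindowCount, 2L)
    # no window meets an impossible threshold
    expect_identical(nrow(detectHotspots(prof, sites, "min_count", 99)), 0L)
    expect_error(detectHotspots(prof, sites, "min_count", 0), "param")
})

test_that("top_k selects the highest-count windows deterministically", {
    aln <- plantedAlignment(2000, snpCols = c(100:110, 1600:1620))
    sites <- classifyColumns(aln)
    prof <- windowProfile(sites, L = 500, s = 250)
    hs <- detectHotspots(prof, sites, "top_k", 3)
    # two top windows cover the dense cluster and merge; the third is the
    # sparse cluster
    expect_identical(nrow(hs), 2L)
    expect_identical(hs$snpTotal, c(21L, 11L))
    expect_true(hs$start[2] <= 99 && hs$end[2] > 110)
})

test_that("high-deletion windows flag taxa above the gap fraction", {
    aln <- plantedAlignment(1000, gapRuns = list(
        list(taxon = 2, cols = 1:400)))          # 400/500 = 0.8 in window 1
    hd <- highDeletionWindows(aln, L = 500, s = 250, fraction = 0.70)
    expect_identical(hd$taxon, "t2")
    expect_identical(c(hd$start, hd$end), c(0L, 500L))
    expect_equal(hd$gapFraction, 0.8)
    expect_identical(nrow(highDeletionWindows(plantedAlignment(1000))), 0L)
    expect_error(highDeletionWindows(aln, fraction = 1.2), "fraction")
})

test_that("a planted 600 bp deletion flags exactly the windows overlapping > 70% of L", {
    start <- 1201                                # 0-based 1200, length 600
    aln <- plantedAlignment(3000, gapRuns = list(
        list(taxon = 3, cols = start:(start + 599))))
    hd <- highDeletionWindows(aln, L = 500, s = 250, fraction = 0.70)
    starts0 <- seq(0, 2500, by = 250)
    overlap <- pmin(starts0 + 500, 1800) - pmax(starts0, 1200)
    expected <- starts0[overlap > 350]
    expect_identical(hd$start, as.integer(expected))
})

test_that("windowed identity handles mismatches, gaps and incomparable windows", {
    m <- matrix("A", nrow = 3, ncol = 1000,
                dimnames = list(c("ref", "same", "div"), NULL))
    m["div", 1:5] <- "C"                         # 5 mismatches in window 1
    aln <- matrixToAlignment(m)
    idp <- identityProfile(aln, "ref", L = 500, s = 250)
    expect_equal(idp$div[1], 99.0)
    expect_true(all(idp$same == 100))            # identical rows: 100 everywhere
    # gap vs base is a mismatch; gap vs gap excluded; all-N incomparable
    m2 <- matrix("A", nrow = 2, ncol = 500,
                 dimnames = list(c("ref", "x"), NULL))
    m2["x", 1:50] <- "-"                         # 50 mismatching positions
    m2["ref", 51:100] <- "-"; m2["x", 51:100] <- "-"  # excluded
    idp2 <- identityProfile(matrixToAlignment(m2), "ref", L = 500, s = 500)
    expect_equal(idp2$x, (400 / 450) * 100)
    m2[] <- "N"
    idp3 <- identityProfile(matrixToAlignment(m2), "ref", L = 500, s = 500)
    expect_true(is.na(idp3$x))
})

test_that("windows are labeled with genes and named spacers", {
    feats <- data.frame(
        name = c("trnS", "trnR"), kind = "tRNA",
        start = c(100L, 700L), end = c(300L, 900L), strand = "+",
        occurrence = 1:2)
    aln <- plantedAlignment(1000)
    prof <- windowProfile(classifyColumns(aln), L = 200, s = 200)
    lab <- profileWindows(annotateWindows(prof, feats, aln, "t1"))$label
    expect_identical(lab[1], "trnS")                  # [0,200) inside trnS
    expect_identical(lab[3], "trnS-trnR spacer")      # [400,600) inside spacer
    expect_true(grepl("trnS", lab[2]) && grepl("spacer", lab[2]))  # straddles
    expect_error(annotateWindows(prof, feats, aln, "zz"), "not in alignment")
})

test_that("annotation labels survive gapped reference coordinates", {
    rows <- c(r = paste0(strrep("A", 50), strrep("-", 20), strrep("A", 30)),
              s = strrep("C", 100))
    aln <- plastomeAlignment(rows)
    feats <- data.frame(name = "g1", kind = "coding",
                        start = 55L, end = 70L, strand = "+",
                        occurrence = 1L)
    prof <- windowProfile(classifyColumns(aln), L = 20, s = 20)
    lab <- profileWindows(annotateWindows(prof, feats, aln, "r"))$label
    # ungapped 55 maps to column 75: label lands in windows 4-5, not 3
    expect_identical(which(lab == "g1"), c(4L, 5L))
})
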