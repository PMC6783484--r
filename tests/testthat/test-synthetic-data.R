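noIndelConfig <- function(...) {
    simulationConfig(...,
        indelRate = 0,
        longDeletions = data.frame(taxon = integer(), start = integer(),
                                   length = integer()))
}

smallRegions <- c(LSC = 3000, IRa = 800, SSC = 600)

test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(regionLengths = c(LSC = 2000, IRa = 500,
                                                    SSC = 0)), "> 0")
    expect_error(simulationConfig(substRate = -1), ">= 0")
    expect_error(simulationConfig(irMultiplier = 0), "> 0")
    expect_error(simulationConfig(nIngroup = 5,
                                  lineageMultipliers = c(1, 2)),
                 "one lineage multiplier")
    expect_error(simulationConfig(baseFreqs = c(A = 1, C = 1, G = 0, T = 0)),
                 "sum to 1")
})

test_that("the reference genome is quadripartite by construction", {
    cfg <- simulationConfig(regionLengths = c(LSC = 2000, IRa = 500,
                                              SSC = 800), seed = 2)
    ref <- simulateReference(cfg)
    expect_identical(nchar(ref$sequence), 2000L + 500L + 800L + 500L)
    ira <- substr(ref$sequence, 2001, 2500)
    irb <- substr(ref$sequence, 3301, 3800)
    expect_identical(ira, revComp(irb))
    ir <- detectInvertedRepeat(ref$sequence, minLength = 200)
    expect_equal(ir$ira, c(2000, 2500))
    expect_equal(ir$irb, c(3300, 3800))
})

test_that("zero rates reproduce the reference in every row", {
    cfg <- noIndelConfig(regionLengths = smallRegions,
                         substRate = 0, outgroupRate = 0, seed = 4)
    ref <- simulateReference(cfg)
    sim <- simulateAlignment(ref)
    m <- alignmentMatrix(sim$alignment)
    refRow <- strsplit(ref$sequence, "")[[1]]
    for (t in seq_len(nrow(m)))
        expect_identical(unname(m[t, ]), refRow)
    expect_false(any(sim$truth$isSnp))
    expect_false(any(sim$truth$isIndel))
    expect_length(sim$truth$subsetCredits, 0L)
})

test_that("a fixed seed gives byte-identical alignments and truth", {
    cfg <- simulationConfig(regionLengths = smallRegions, seed = 9)
    a <- simulateAlignment(simulateReference(cfg))
    b <- simulateAlignment(simulateReference(cfg))
    expect_identical(as.character(a$alignment@seqs),
                     as.character(b$alignment@seqs))
    expect_identical(a$truth$subsetCredits, b$truth$subsetCredits)
    expect_identical(a$truth$deletions, b$truth$deletions)
})

test_that("analysis modules recover the simulator's truth table", {
    cfg <- simulationConfig(regionLengths = smallRegions, seed = 12)
    ref <- simulateReference(cfg)
    sim <- simulateAlignment(ref)
    sites <- classifyColumns(sim$alignment)
    expect_identical(unname(sites@isSnp), sim$truth$isSnp)
    expect_identical(unname(sites@isIndel), sim$truth$isIndel)
    got <- subsetCounts(snpPartition(sites))
    want <- sim$truth$subsetCredits
    expect_identical(got[order(names(got))], want[order(names(want))])
    # planted long deletion is present as a gap run in its taxon
    del <- sim$truth$deletions[sim$truth$deletions$planted, ][1, ]
    row <- alignmentMatrix(sim$alignment)[del$taxon, ]
    expect_true(all(row[(del$start + 1):del$end] == "-"))
})

test_that("IR regions are close to invariant while hotspots are enriched", {
    cfg <- noIndelConfig(regionLengths = c(LSC = 6000, IRa = 2000,
                                           SSC = 1500), seed = 21)
    ref <- simulateReference(cfg)
    sim <- simulateAlignment(ref)
    snp <- sim$truth$isSnp
    reg <- ref$regions
    irCols <- unlist(lapply(which(reg$region %in% c("IRa", "IRb")), function(i)
        seq.int(reg$start[i] + 1L, reg$end[i])))
    lscCols <- seq.int(reg$start[1] + 1L, reg$end[1])
    rateIr <- mean(snp[irCols]); rateLsc <- mean(snp[lscCols])
    expect_lt(rateIr, rateLsc / 2)
    hs <- cfg$hotspots
    hsCols <- unlist(lapply(seq_len(nrow(hs)), function(i)
        seq.int(hs$start[i] + 1L, hs$end[i])))
    expect_gt(mean(snp[hsCols]), 2 * rateLsc)
})

test_that("hotspot detection recovers planted hotspot intervals", {
    cfg <- noIndelConfig(regionLengths = c(LSC = 6000, IRa = 2000,
                                           SSC = 1500), seed = 22)
    ref <- simulateReference(cfg)
    sim <- simulateAlignment(ref)
    sites <- classifyColumns(sim$alignment)
    prof <- windowProfile(sites, L = 500, s = 250)
    found <- detectHotspots(prof, sites, "top_k", 2 * nrow(cfg$hotspots))
    hs <- cfg$hotspots
    overlaps <- vapply(seq_len(nrow(hs)), function(i)
        any(found$start < hs$end[i] & found$end > hs$start[i]),
        logical(1))
    expect_true(all(overlaps))
})

test_that("replicate triples respect the determinism and null contracts", {
    cfg <- simulationConfig(seed = 33)
    reps <- simulateRRTReplicates(cfg, 3, seqLength = 2000)
    expect_length(reps, 3L)
    expect_identical(taxa(reps[[1]]), c("A", "B", "O"))
    reps2 <- simulateRRTReplicates(cfg, 3, seqLength = 2000)
    expect_identical(as.character(reps[[2]]@seqs),
                     as.character(reps2[[2]]@seqs))
    # zero branch lengths: no information, chi2 identically 0
    null <- simulationConfig(substRate = 0, outgroupRate = 0, seed = 34)
    for (aln in simulateRRTReplicates(null, 5, seqLength = 500)) {
        rt <- tajimaRRT(aln, "A", "B", "O")
        expect_equal(c(rt$chi2, rt$p), c(0, 1))
    }
})

test_that("a 5x faster lineage is detected with high power and never called slower", {
    cfg <- simulationConfig(seed = 35)
    reps <- simulateRRTReplicates(cfg, 40, seqLength = 20000, rateRatio = 5)
    res <- lapply(reps, tajimaRRT, taxonA = "A", taxonB = "B",
                  outgroup = "O")
    sig <- vapply(res, function(r) r$p < 0.05, logical(1))
    expect_gt(mean(sig), 0.9)
    slower <- vapply(res[sig], function(r) r$slowerTaxon, character(1))
    expect_false(any(slower == "A"))
})
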