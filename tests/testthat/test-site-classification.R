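colAln <- function(...) {
    # build an alignment from per-taxon columns given as strings
    rows <- c(...)
    plastomeAlignment(setNames(rows, paste0("t", seq_along(rows))))
}

test_that("column flags follow the stated classification rules", {
    aln <- colAln("AAN", "A-N", "AAN", "ANN", "AC-")
    sites <- classifyColumns(aln)
    # col 1: monomorphic, no indel
    expect_false(sites@isSnp[1]); expect_false(sites@isIndel[1])
    expect_false(sites@isUninformative[1])
    # col 2: (A,-,A,N,C) both indel and SNP
    expect_true(sites@isSnp[2]); expect_true(sites@isIndel[2])
    ac <- alleleClasses(sites, 1L)
    expect_identical(ac$A, c("t1", "t3"))
    expect_identical(ac$C, "t5")
    expect_setequal(ac$missing, c("t2", "t4"))
    # col 3: (N,N,N,N,-) uninformative
    expect_true(sites@isUninformative[3]); expect_false(sites@isSnp[3])
})

test_that("count totals tally planted SNP columns exactly", {
    mono <- plastomeAlignment(c(a = "AAAA", b = "AAAA"))
    tot <- countTotals(classifyColumns(mono))
    expect_identical(unname(tot["snp_columns"]), 0L)
    expect_identical(unname(tot["monomorphic_columns"]), 4L)

    set.seed(5)
    m <- matrix("A", nrow = 4, ncol = 60,
                dimnames = list(paste0("t", 1:4), NULL))
    snpCols <- sample(60, 12)
    m[1, snpCols] <- "G"
    tot <- countTotals(classifyColumns(matrixToAlignment(m)))
    expect_identical(unname(tot["snp_columns"]), 12L)
    expect_identical(unname(tot["indel_columns"]), 0L)
})

test_that("allele classes credit the documented subsets", {
    p1 <- snpPartition(classifyColumns(colAln("A", "C", "C", "C", "C")))
    expect_identical(sort(names(subsetCounts(p1))),
                     sort(c("t1", "t2|t3|t4|t5")))
    expect_identical(unname(subsetCounts(p1)[["t1"]]), 1L)

    p2 <- snpPartition(classifyColumns(colAln("A", "C", "C", "G", "G")))
    expect_setequal(names(subsetCounts(p2)), c("t1", "t2|t3", "t4|t5"))

    # private call even when the remaining taxa are polymorphic
    expect_identical(privateSnps(p2, "t1"), 1L)
    # monomorphic columns credit nothing
    p3 <- snpPartition(classifyColumns(colAln("AA", "AA", "AA")))
    expect_length(subsetCounts(p3), 0L)
    expect_identical(p3@totalSnpColumns, 0L)
})

test_that("taxa mismatch is rejected", {
    sites <- classifyColumns(colAln("AC", "AG"))
    expect_error(snpPartition(sites, c("t1", "zz")), "do not match")
    expect_error(privateSnps(snpPartition(sites), "zz"), "not in partition")
})

test_that("classification and partition match the brute-force oracle", {
    set.seed(101)
    for (rep in 1:25) {
        nt <- sample(2:8, 1)
        m <- randomStateMatrix(nt, sample(20:80, 1),
                               pGap = 0.1, pN = 0.1)
        sites <- classifyColumns(matrixToAlignment(m))
        orc <- oracleClassify(m)
        expect_identical(unname(sites@isSnp), orc$isSnp)
        expect_identical(unname(sites@isIndel), orc$isIndel)
        expect_identical(unname(sites@isUninformative), orc$isUninformative)
        got <- subsetCounts(snpPartition(sites))
        want <- oracleSubsetCredits(m)
        expect_identical(got[order(names(got))],
                         want[order(names(want))])
    }
})

test_that("permuting taxon order permutes labels but preserves counts", {
    set.seed(7)
    m <- randomStateMatrix(5, 100, pGap = 0.05, pN = 0.05)
    base <- subsetCounts(snpPartition(classifyColumns(matrixToAlignment(m))))
    perm <- m[sample(nrow(m)), , drop = FALSE]
    got <- subsetCounts(snpPartition(classifyColumns(matrixToAlignment(perm))))
    expect_identical(base[order(names(base))], got[order(names(got))])
})

test_that("biallelic complete columns credit exactly the two complementary classes", {
    set.seed(13)
    m <- randomStateMatrix(5, 150, pGap = 0, pN = 0)
    sites <- classifyColumns(matrixToAlignment(m))
    part <- snpPartition(sites)
    cc <- subsetCounts(part)
    biallelic <- vapply(which(sites@isSnp), function(j)
        length(unique(m[, j])) == 2L, logical(1))
    # every biallelic gap-free column contributes one complementary pair
    nPairCredits <- sum(vapply(names(cc), function(k) {
        members <- strsplit(k, "|", fixed = TRUE)[[1]]
        comp <- paste(sort(setdiff(rownames(m), members)), collapse = "|")
        comp %in% names(cc)
    }, logical(1)) * cc)
    expect_gte(nPairCredits, 2L * sum(biallelic))
})
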