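test_that("complete deletion drops gapped columns and divides by the remainder", {
    aln <- plastomeAlignment(c(a = "ACGTACGTAC",
                               b = "ACGTACGTCC",
                               c = "AC-TACGTAC"))
    pd <- pDistance(aln)
    expect_identical(nCompletePositions(pd), 9L)
    expect_equal(pd@matrix["a", "b"], 1 / 9)
    expect_equal(pd@matrix["a", "c"], 0)
    expect_equal(pd@matrix, t(pd@matrix))

    ident <- pDistance(plastomeAlignment(c(x = "ACGT", y = "ACGT")))
    expect_true(all(ident@matrix == 0))
    expect_error(pDistance(plastomeAlignment(c(x = "A-G", y = "-C-"))),
                 "no complete columns")
})

test_that("N columns are removed by complete deletion like gaps", {
    aln <- plastomeAlignment(c(a = "ANGT", b = "ACGT", c = "TCGT"))
    pd <- pDistance(aln)
    expect_identical(nCompletePositions(pd), 3L)
    expect_equal(pd@matrix["a", "c"], 1 / 3)
})

test_that("p-distances agree with an independent implementation", {
    skip_if_not_installed("ape")
    set.seed(23)
    m <- randomStateMatrix(5, 400, pGap = 0, pN = 0)
    pd <- pDistance(matrixToAlignment(m))
    bin <- ape::as.DNAbin(tolower(m))
    ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = FALSE))
    expect_equal(pd@matrix, ref[rownames(pd@matrix), colnames(pd@matrix)],
                 tolerance = 1e-12)
})

test_that("pairwise deletion uses per-pair denominators", {
    aln <- plastomeAlignment(c(a = "ACGT-C", b = "ACGANC", c = "ACGTAC"))
    pd <- pDistance(aln, deletion = "pairwise")
    expect_identical(pd@nComplete["a", "b"], 5L)   # only column 5 shared-missing
    expect_identical(pd@nComplete["a", "c"], 5L)
    expect_equal(pd@matrix["a", "b"], 1 / 5)
})

test_that("relative rate test reproduces the hand-computed chi-square", {
    # 8 sites where A alone differs, 2 where B alone differs
    n <- 40
    a <- rep("A", n); b <- rep("A", n); o <- rep("A", n)
    a[1:8] <- "C"
    b[9:10] <- "G"
    aln <- plastomeAlignment(c(A = paste(a, collapse = ""),
                               B = paste(b, collapse = ""),
                               O = paste(o, collapse = "")))
    rt <- tajimaRRT(aln, "A", "B", "O")
    expect_identical(c(rt$mA, rt$mB), c(8L, 2L))
    expect_equal(rt$chi2, 3.6)
    expect_equal(rt$p, pchisq(3.6, df = 1, lower.tail = FALSE))
    expect_identical(rt$slowerTaxon, "B")
    # swapping A and B swaps the counts but not the statistic
    rt2 <- tajimaRRT(aln, "B", "A", "O")
    expect_identical(c(rt2$mA, rt2$mB), c(2L, 8L))
    expect_equal(rt2$chi2, rt$chi2)
})

test_that("balanced and empty unique-site counts are handled", {
    n <- 30
    a <- rep("A", n); b <- rep("A", n)
    a[1:10] <- "C"; b[11:20] <- "G"
    aln <- plastomeAlignment(c(A = paste(a, collapse = ""),
                               B = paste(b, collapse = ""),
                               O = strrep("A", n)))
    rt <- tajimaRRT(aln, "A", "B", "O")
    expect_identical(c(rt$mA, rt$mB), c(10L, 10L))
    expect_equal(rt$chi2, 0)
    expect_true(is.na(rt$slowerTaxon))

    same <- plastomeAlignment(c(A = "ACGT", B = "ACGT", O = "ACGT"))
    rt0 <- tajimaRRT(same, "A", "B", "O")
    expect_equal(c(rt0$chi2, rt0$p), c(0, 1))
    expect_error(tajimaRRT(same, "A", "A", "O"), "distinct")
    expect_error(tajimaRRT(same, "A", "B", "Z"), "not found")
})

test_that("unique-site counts match a brute-force column scan", {
    set.seed(31)
    for (rep in 1:20) {
        m <- randomStateMatrix(3, 120, pGap = 0.05, pN = 0.05)
        rownames(m) <- c("A", "B", "O")
        rt <- tajimaRRT(matrixToAlignment(m), "A", "B", "O")
        orc <- oracleRrtCounts(m["A", ], m["B", ], m["O", ])
        expect_identical(c(rt$mA, rt$mB), unname(orc))
    }
})

test_that("all-pairs table annotates significance at the chosen level", {
    n <- 2000
    set.seed(3)
    o <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    fast <- o; idx <- sample(n, 120)
    fast[idx] <- c("C", "G", "T", "A")[match(o[idx], c("A", "C", "G", "T"))]
    aln <- plastomeAlignment(c(f = paste(fast, collapse = ""),
                               s1 = paste(o, collapse = ""),
                               s2 = paste(o, collapse = ""),
                               out = paste(o, collapse = "")))
    tab <- rrtAllPairs(aln, c("f", "s1", "s2"), "out")
    expect_identical(nrow(tab), 3L)
    fs <- tab[tab$taxonA == "f" & tab$taxonB == "s1", ]
    expect_true(fs$significant)
    expect_identical(fs$slowerTaxon, "s1")
    ss <- tab[tab$taxonA == "s1" & tab$taxonB == "s2", ]
    expect_equal(c(ss$chi2, ss$p), c(0, 1))
    expect_true(is.na(ss$slowerTaxon))
})
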