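# Brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

# random gapped alignment as a character matrix (taxa x columns)
randomStateMatrix <- function(nTaxa, nCols, pGap = 0.05, pN = 0.05) {
    states <- sample(c("A", "C", "G", "T", "N", "-"), nTaxa * nCols,
                     replace = TRUE,
                     prob = c(rep((1 - pGap - pN) / 4, 4), pN, pGap))
    matrix(states, nrow = nTaxa,
           dimnames = list(paste0("t", seq_len(nTaxa)), NULL))
}

matrixToAlignment <- function(m) {
    plastomeAlignment(setNames(apply(m, 1L, paste, collapse = ""),
                               rownames(m)))
}

# per-column classification by explicit enumeration
oracleClassify <- function(m) {
    n <- ncol(m)
    isSnp <- logical(n); isIndel <- logical(n); isUninf <- logical(n)
    for (j in seq_len(n)) {
        col <- m[, j]
        isIndel[j] <- any(col == "-")
        obs <- col[col %in% c("A", "C", "G", "T")]
        if (length(obs) < 2L) isUninf[j] <- TRUE
        else isSnp[j] <- length(unique(obs)) >= 2L
    }
    list(isSnp = isSnp, isIndel = isIndel, isUninformative = isUninf)
}

# subset credits by literal enumeration of every non-empty proper subset:
# S is credited at a column iff all taxa in S are non-missing and share
# one state, and every non-missing taxon outside S carries a different
# state
oracleSubsetCredits <- function(m) {
    tx <- rownames(m)
    nt <- length(tx)
    counts <- list()
    for (mask in seq_len(2L^nt - 2L)) {
        inS <- as.logical(bitwAnd(mask, 2L^(seq_len(nt) - 1L)))
        key <- paste(sort(tx[inS]), collapse = "|")
        hits <- 0L
        for (j in seq_len(ncol(m))) {
            col <- m[, j]
            nonMiss <- col %in% c("A", "C", "G", "T")
            if (!all(nonMiss[inS])) next
            sStates <- unique(col[inS])
            if (length(sStates) != 1L) next
            others <- which(!inS & nonMiss)
            if (length(others) == 0L) next       # S spans all informative taxa
            if (any(col[others] == sStates)) next
            hits <- hits + 1L
        }
        if (hits > 0L) counts[[key]] <- hits
    }
    unlist(counts)
}

# unique-site counts for the relative rate test by explicit column scan
oracleRrtCounts <- function(a, b, o) {
    mA <- 0L; mB <- 0L
    for (j in seq_along(a)) {
        if (any(c(a[j], b[j], o[j]) %in% c("N", "-"))) next
        if (a[j] != b[j] && b[j] == o[j]) mA <- mA + 1L
        if (b[j] != a[j] && a[j] == o[j]) mB <- mB + 1L
    }
    c(mA = mA, mB = mB)
}

# longest reverse-complement repeat by quadratic scan (small inputs only)
oracleLongestRcRepeat <- function(s) {
    v <- strsplit(s, "")[[1L]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    n <- length(v)
    best <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            # match v[i..] against revcomp arm ending at j
            L <- 0L
            while (i + L <= n && j - L >= 1L &&
                   v[i + L] == comp[[v[j - L]]]) {
                L <- L + 1L
            }
            # arms [i, i+L) and [j-L+1, j+1) must be disjoint
            if (L > best && i + L - 1L < j - L + 1L) best <- L
        }
    }
    best
}
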