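toyPrimers <- function() {
    new("PrimerPair", markerId = "toy",
        forward = "ACGTACGTACGTACGTACGA",   # 20 nt
        reverse = "TGCATGCATGCATGCATGCA",   # 20 nt
        expectedSize = 45)
}

test_that("in-silico PCR finds the constructed product", {
    pp <- toyPrimers()
    rcRev <- oracleRevcomp(pp@reverse)
    tmpl <- paste0(pp@forward, "AAAAA", rcRev)
    res <- insilicoPCR(tmpl, pp)
    plus <- res[res$strand == "+", ]
    expect_equal(nrow(plus), 1)
    expect_equal(plus$length, 45)
    expect_equal(plus$start, 0)
    expect_equal(plus$end, 45)
    expect_identical(plus$sequence, tmpl)

    # no reverse site -> no product (empty result, not an error)
    none <- insilicoPCR(paste0(pp@forward, "AAAAA"), pp)
    expect_equal(nrow(none), 0)

    # two reverse sites -> two products
    tmpl2 <- paste0(pp@forward, "AAAAA", rcRev, "TTTTT", rcRev)
    res2 <- insilicoPCR(tmpl2, pp)
    plus2 <- res2[res2$strand == "+", ]
    expect_equal(nrow(plus2), 2)
    expect_equal(sort(plus2$length), c(45, 70))
})

test_that("in-silico PCR agrees with the exhaustive placement oracle", {
    pp <- toyPrimers()
    rcRev <- oracleRevcomp(pp@reverse)
    set.seed(401)
    for (i in 1:40) {
        tmpl <- randomDNA(1000)
        # plant a variable number of sites, sometimes none
        for (k in seq_len(sample(0:2, 1)))
            tmpl <- plantWord(tmpl, pp@forward, sample(900, 1))
        for (k in seq_len(sample(0:2, 1)))
            tmpl <- plantWord(tmpl, rcRev, sample(900, 1))
        got <- insilicoPCR(tmpl, pp)
        for (strand in c("+", "-")) {
            s <- if (strand == "+") tmpl else oracleRevcomp(tmpl)
            want <- oraclePCRStrand(s, pp@forward, pp@reverse)
            sub <- got[got$strand == strand, c("start", "end")]
            if (is.null(want)) {
                expect_equal(nrow(sub), 0)
            } else {
                want <- want[order(want[, "start"], want[, "end"]), ,
                             drop = FALSE]
                expect_equal(unname(as.matrix(sub)), unname(want))
            }
        }
    }
})

test_that("product lengths are strand-symmetric", {
    pp <- toyPrimers()
    set.seed(77)
    tmpl <- randomDNA(800)
    tmpl <- plantWord(tmpl, pp@forward, 50)
    tmpl <- plantWord(tmpl, oracleRevcomp(pp@reverse), 300)
    tmpl <- plantWord(tmpl, oracleRevcomp(pp@forward), 700)
    a <- insilicoPCR(tmpl, pp)
    b <- insilicoPCR(oracleRevcomp(tmpl), pp)
    expect_equal(sort(a$length), sort(b$length))
})

test_that("tandem repeat search returns the longest run, leftmost on ties", {
    r <- findTandemRepeat("TTAGCAGCAGCAGCAGCGG", "AGC")
    expect_equal(r$start, 2)
    expect_equal(r$repeat_count, 5)
    expect_equal(r$span_bp, 15)

    # two runs: the longer one wins regardless of order
    s <- paste0("TT", strrep("AGC", 3), "TTTT", strrep("AGC", 6), "TT")
    r2 <- findTandemRepeat(s, "AGC")
    expect_equal(r2$repeat_count, 6)
    expect_equal(r2$start, 2 + 9 + 4)

    # ties resolve to the leftmost run
    s3 <- paste0("T", strrep("AGC", 4), "TTTT", strrep("AGC", 4))
    expect_equal(findTandemRepeat(s3, "AGC")$start, 1)

    # absent motif is a distinct none-found signal
    expect_null(findTandemRepeat("TTTTTT", "AGC"))

    # brute-force check against all-substrings enumeration
    set.seed(19)
    for (i in 1:20) {
        s <- randomDNA(200)
        got <- findTandemRepeat(s, "AGC")
        # oracle: longest k with any rotation word repeated k times
        best <- c(start = -1L, count = 0L)
        for (w in c("AGC", "GCA", "CAG")) {
            for (start in 1:198) {
                k <- 0L
                while (start + 3 * k + 2 <= 200 &&
                       substr(s, start + 3 * k, start + 3 * k + 2) == w)
                    k <- k + 1L
                if (k > best[["count"]]) best <- c(start = start - 1L,
                                                   count = k)
            }
        }
        if (best[["count"]] == 0L) {
            expect_null(got)
        } else {
            expect_equal(got$repeat_count, best[["count"]])
        }
    }
})

test_that("SNP states are read through the SSR length difference", {
    ref <- referenceAllele()
    st <- extractSnpStates(ref$sequence)
    expect_identical(bareStates(st), c("C", "G", "A", "A"))
    expect_false(any(attr(st, "novel")))

    # Allele 3: SSR expanded by 2 units, SNP1 C->T, SNP2 G->T, SNP4 A->G
    al3 <- simulateAlleleSequence(namedAlleleSpecs()$Allele3)
    st3 <- extractSnpStates(al3$sequence)
    expect_identical(bareStates(st3), c("T", "T", "A", "G"))

    # a base outside {ref, alt} is returned and flagged, not fatal
    q <- ref$sequence
    substr(q, 316, 316) <- "G"   # SNP1 offset 315 (0-based)
    stN <- extractSnpStates(q)
    expect_identical(unname(stN[["SNP1"]]), "G")
    expect_true(attr(stN, "novel")[["SNP1"]])

    # a deletion in a flank violates the tract-confined assumption
    del <- paste0(substr(ref$sequence, 1, 49),
                  substr(ref$sequence, 51, nchar(ref$sequence)))
    expect_condition(extractSnpStates(del),
                     class = "apricotMAS_alignment_error")

    # a substitution at a non-SNP position is an alignment ambiguity
    mm <- ref$sequence
    substr(mm, 1000, 1000) <- chartr("ACGT", "CGTA",
                                     substr(mm, 1000, 1000))
    expect_condition(extractSnpStates(mm),
                     class = "apricotMAS_alignment_error")
})

test_that("haplotypes assemble against the four-allele table", {
    expect_identical(alleleName(assembleHaplotype(108, c("C", "G", "A", "A"))),
                     "Allele1")
    expect_identical(alleleName(assembleHaplotype(111, c("C", "G", "G", "G"))),
                     "Allele2")
    expect_identical(alleleName(assembleHaplotype(114, c("T", "T", "A", "G"))),
                     "Allele3")
    expect_identical(alleleName(assembleHaplotype(120, c("C", "G", "A", "G"))),
                     "Allele4")
    # any off-table combination is preserved as novel
    nov <- assembleHaplotype(108, c("T", "T", "A", "G"))
    expect_identical(alleleName(nov), "novel")
    expect_equal(ssrSize(nov), 108)
    expect_identical(unname(snpStates(nov)), c("T", "T", "A", "G"))
    # named states are reordered into SNP1..SNP4
    sh <- assembleHaplotype(114, c(SNP4 = "G", SNP2 = "T",
                                   SNP1 = "T", SNP3 = "A"))
    expect_identical(alleleName(sh), "Allele3")
})

test_that("amplicon sizes differ by 3 bp per repeat unit", {
    sizes <- vapply(c(2, 4, 5, 6, 8, 11), function(n)
        simulateAlleleSequence(alleleSpec(repeatCount = n))$amplicon_size,
        numeric(1))
    expect_equal(diff(sizes), 3 * diff(c(2, 4, 5, 6, 8, 11)))
})
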