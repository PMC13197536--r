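test_that("cohort simulation is a pure function of its config", {
    cfg <- cohortConfig(nIndividuals = 40, mislabelRate = 0.1, seed = 99)
    s1 <- simulateCohort(cfg)
    s2 <- simulateCohort(cfg)
    expect_identical(s1, s2)
    s3 <- simulateCohort(cohortConfig(nIndividuals = 40,
                                      mislabelRate = 0.1, seed = 100))
    expect_false(identical(s1$truth, s3$truth))

    # the caller's RNG stream is untouched
    set.seed(1); before <- runif(3)
    set.seed(1); invisible(runif(1))
    invisible(simulateCohort(cfg))
    expect_identical(runif(2), before[2:3])
})

test_that("config validation rejects degenerate settings", {
    expect_error(cohortConfig(genotypeFrequencies = c("C/C" = 0.7,
                                                      "C/T" = 0.7)),
                 "sum to 1")
    expect_error(cohortConfig(mislabelRate = 1.5), "mislabelRate")
    expect_error(cohortConfig(hueModel = list(orange = c(mean = 73, sd = 0),
                                              yellow = c(mean = 88, sd = 2))),
                 "sds must be positive")
})

test_that("a clean cohort scores 100% and mislabels depress it", {
    clean <- simulateCohort(cohortConfig(nIndividuals = 300, seed = 3))
    res <- runPipeline(clean$colorimeter, clean$genotypes,
                       verbose = FALSE)
    expect_equal(unweightedEfficiency(res$report), 100)

    noisy <- simulateCohort(cohortConfig(nIndividuals = 1000,
                                         mislabelRate = 0.1, seed = 3))
    resN <- runPipeline(noisy$colorimeter, noisy$genotypes,
                        verbose = FALSE)
    # within the 99% binomial envelope of 90%
    bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.9)
    expect_gte(resN$report@nCorrect, bounds[1])
    expect_lte(resN$report@nCorrect, bounds[2])
})

test_that("generated hue replicates recover the class-conditional moments", {
    cfg <- cohortConfig(nIndividuals = 900, seed = 17)
    sim <- simulateCohort(cfg)
    hue <- hueAngle(sim$colorimeter$a, sim$colorimeter$b)
    cls <- sim$truth$emitted_class[match(sim$colorimeter$individual_id,
                                         sim$truth$individual_id)]
    for (cl in c("orange", "yellow")) {
        h <- hue[cls == cl]
        m <- cfg$hueModel[[cl]]
        se <- m[["sd"]] / sqrt(length(h))
        expect_lt(abs(mean(h) - m[["mean"]]), 3 * se)
        expect_lt(abs(sd(h) - m[["sd"]]), 0.1)
    }
})

test_that("back-computed CIELAB coordinates sit at the configured chroma", {
    sim <- simulateCohort(cohortConfig(nIndividuals = 10, seed = 2,
                                       chroma = 50))
    expect_equal(sqrt(sim$colorimeter$a^2 + sim$colorimeter$b^2),
                 rep(50, nrow(sim$colorimeter)))
})

test_that("allele construction rejects colliding or degenerate specs", {
    expect_error(alleleSpec(repeatCount = 1), "repeatCount")
    expect_error(alleleSpec(snpStates = c("C", "G", "A")), "four bases")
    expect_error(alleleSpec(snpStates = c("C", "G", "A", "Z")), "bases")
    # constructing from an off-frame AlleleCall is refused
    expect_error(simulateAlleleSequence(
        assembleHaplotype(110, c("C", "G", "A", "A"))), "off-frame")
})

test_that("the simulated locus carries its documented features", {
    al <- simulateAlleleSequence(alleleSpec())
    pp <- col1Primers()
    expect_equal(nchar(al$sequence), 1257)
    expect_equal(al$amplicon_size, 108)
    tr <- findTandemRepeat(al$sequence, "AGC")
    expect_equal(tr$start, al$tract_start)
    expect_equal(tr$repeat_count, 4)
    # declared SNP offsets carry the declared states
    for (lab in names(al$snp_offsets)) {
        o <- al$snp_offsets[[lab]]
        expect_identical(substr(al$sequence, o + 1, o + 1),
                         snpDefinitions()$ref[snpDefinitions()$label == lab])
    }
    # genomic spacing between SNP1 and SNP2/SNP3 is preserved
    defs <- snpDefinitions()
    off <- defs$ref_offset; names(off) <- defs$label
    pos <- defs$genomic_position; names(pos) <- defs$label
    expect_equal(off[["SNP2"]] - off[["SNP1"]],
                 pos[["SNP2"]] - pos[["SNP1"]])
    expect_equal(off[["SNP3"]] - off[["SNP1"]],
                 pos[["SNP3"]] - pos[["SNP1"]])
})

test_that("full synthetic round trip recovers arbitrary specs", {
    set.seed(23)
    for (i in 1:8) {
        spec <- alleleSpec(
            repeatCount = sample(2:12, 1),
            snpStates = c(SNP1 = sample(c("C", "T"), 1),
                          SNP2 = sample(c("G", "T"), 1),
                          SNP3 = sample(c("A", "G"), 1),
                          SNP4 = sample(c("A", "G"), 1)))
        al <- simulateAlleleSequence(spec)
        amp <- insilicoPCR(al$sequence, col1Primers())
        amp <- amp[amp$strand == "+", ]
        expect_equal(nrow(amp), 1)
        expect_equal(amp$length, al$amplicon_size)
        tr <- findTandemRepeat(amp$sequence, "AGC")
        expect_equal(tr$repeat_count, spec$repeatCount)
        st <- extractSnpStates(al$sequence)
        expect_identical(bareStates(st), unname(spec$snpStates))
        call <- assembleHaplotype(amp$length, st)
        expect_equal(ssrSize(call), 108 + 3 * (spec$repeatCount - 4))
    }
})
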