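test_that("genotype calls are parsed, canonicalized and flagged", {
    r <- parseGenotype("C/T", "snp1", "P1")
    expect_identical(r$allele_1, "C")
    expect_identical(r$allele_2, "T")
    expect_false(r$missing)
    expect_identical(r$marker_id, "S3_22924169")

    # order-insensitive canonical form
    expect_identical(parseGenotype("T/C", "snp1")[c("allele_1", "allele_2")],
                     parseGenotype("C/T", "snp1")[c("allele_1", "allele_2")])
    # numeric canonicalization for SSR sizes
    r2 <- parseGenotype("114/108", "col1")
    expect_identical(c(r2$allele_1, r2$allele_2), c("108", "114"))

    expect_true(parseGenotype("X/X", "snp1")$missing)
    expect_error(parseGenotype("C", "snp1"), "malformed")
    expect_error(parseGenotype("C/T/T", "snp1"), "malformed")
    expect_error(parseGenotype("A/C", "snp1"), "not one of the marker's")
    expect_error(parseGenotype("ab/108", "col1"), "fragment sizes")
})

test_that("marker rules predict the published genotype-class pattern", {
    expect_identical(predictPhenotype("C/C", "snp1"), "yellow")
    expect_identical(predictPhenotype("C/T", "snp1"), "orange")
    expect_identical(predictPhenotype("T/T", "snp1"), "orange")
    expect_identical(predictPhenotype("A/A", "snp4"), "yellow")
    expect_identical(predictPhenotype("A/G", "snp4"), "orange")
    expect_identical(predictPhenotype("G/G", "snp4"), "orange")
    # SSR: 108 homozygote yellow, any orange allele dominant
    expect_identical(predictPhenotype("108/108", "col1"), "yellow")
    expect_identical(predictPhenotype("108/114", "col1"), "orange")
    expect_identical(predictPhenotype("111/120", "col1"), "orange")
    expect_condition(predictPhenotype("105/105", "col1"),
                     class = "apricotMAS_unknown_genotype")
    expect_condition(predictPhenotype("X/X", "col1"),
                     class = "apricotMAS_not_scorable")
})

test_that("only the light-orange-to-orange collapse reproduces the panel", {
    # brute-force collapse-rule oracle, independent of the package's
    # scoring path: score the 57-cultivar panel under both admissible
    # binary collapses of the transitional class
    fx <- apricotFixture("table2_cultivars")
    pred <- ifelse(fx$genotype == "C/C", "yellow", "orange")
    correctUnder <- function(loGroup) {
        obs <- ifelse(fx$hue_class == "yellow", "yellow",
               ifelse(fx$hue_class == "orange", "orange", loGroup))
        sum(pred == obs)
    }
    expect_identical(correctUnder("orange"), 51L)   # 51/57 = 89.5%
    expect_false(correctUnder("yellow") == 51L)     # the alternative fails
    # and the package's collapse is the one that reproduces it
    expect_identical(collapseClass("light_orange"), "orange")
    expect_true(scoreConcordance("orange", "light_orange"))
    expect_true(scoreConcordance("yellow", "yellow"))
    expect_false(scoreConcordance("orange", "yellow"))
})

makeToy <- function(calls, hues, ids = paste0("i", seq_along(calls))) {
    list(g = data.frame(individual_id = ids, call = calls),
         p = data.frame(individual_id = ids, hue_mean = hues))
}

test_that("efficiency statistics count, weight and exclude correctly", {
    # yellow-group 2/2 correct, orange-group 1/2 correct
    toy <- makeToy(c("C/C", "C/C", "C/T", "C/C"), c(90, 88, 70, 70))
    rep <- markerEfficiency(toy$g, toy$p, "snp1")
    expect_equal(unweightedEfficiency(rep), 75)
    expect_equal(weightedEfficiency(rep), 75)
    expect_identical(misclassifiedIds(rep), "i4")
    expect_equal(unname(perClassAccuracy(rep)),
                 c(0.5, 1))  # orange, yellow

    # missing calls drop out of numerator and denominator
    toy2 <- makeToy(c("C/C", "X/X", "C/T"), c(90, 90, 70))
    rep2 <- markerEfficiency(toy2$g, toy2$p, "snp1")
    expect_equal(rep2@nTotal, 3L)
    expect_equal(rep2@nScored, 2L)
    expect_equal(unweightedEfficiency(rep2), 100)
    expect_identical(unname(rep2@excludedIds), "i2")

    # a positively weighted empty class is an explicit error
    toy3 <- makeToy(c("C/T", "C/T"), c(70, 72))
    expect_error(markerEfficiency(toy3$g, toy3$p, "snp1"),
                 "undefined")
    # ... but scoring works with all weight on the populated class
    rep3 <- markerEfficiency(toy3$g, toy3$p, "snp1",
                             weights = c(orange = 1, yellow = 0))
    expect_equal(unweightedEfficiency(rep3), 100)
})

test_that("weighted equals unweighted under equal class sizes", {
    set.seed(5)
    for (k in c(4, 10, 24)) {
        calls <- c(sample(c("C/T", "T/T"), k, TRUE), rep("C/C", k))
        hues <- c(runif(k, 60, 76), runif(k, 84, 95))
        # inject some errors symmetrically at random
        flip <- sample(2 * k, 3)
        hues[flip] <- ifelse(hues[flip] < 80, 90, 70)
        toy <- makeToy(calls, hues)
        # skip draws that emptied a class
        obs <- collapseClass(classifyHue(hues))
        if (length(unique(obs)) < 2) next
        rep <- markerEfficiency(toy$g, toy$p, "snp1")
        accs <- perClassAccuracy(rep)
        sizes <- table(obs)
        if (sizes[["orange"]] == sizes[["yellow"]])
            expect_equal(weightedEfficiency(rep),
                         unweightedEfficiency(rep))
    }
    # deterministic equal-size case
    toy <- makeToy(c("C/C", "C/T", "C/C", "C/T"), c(90, 70, 70, 90))
    rep <- markerEfficiency(toy$g, toy$p, "snp1")
    expect_equal(unweightedEfficiency(rep), 50)
    expect_equal(weightedEfficiency(rep), 50)
})

test_that("weighted efficiency is invariant under duplicating one class", {
    fx <- apricotFixture("table2_cultivars")
    g <- data.frame(individual_id = fx$individual_id, call = fx$genotype)
    base <- markerEfficiency(g, fx, "snp1")

    yellows <- fx[collapseClass(fx$hue_class) == "yellow", ]
    dup <- yellows
    dup$individual_id <- paste0(dup$individual_id, "_dup")
    fx2 <- rbind(fx, dup)
    g2 <- data.frame(individual_id = fx2$individual_id,
                     call = fx2$genotype)
    doubled <- markerEfficiency(g2, fx2, "snp1")
    expect_equal(weightedEfficiency(doubled), weightedEfficiency(base))
    # while the unweighted statistic shifts with the class balance
    expect_false(isTRUE(all.equal(unweightedEfficiency(doubled),
                                  unweightedEfficiency(base))))
})

test_that("efficiency bounds and the perfect-score condition hold", {
    toy <- makeToy(c("C/C", "C/T"), c(90, 70))
    rep <- markerEfficiency(toy$g, toy$p, "snp1")
    expect_equal(unweightedEfficiency(rep), 100)
    expect_equal(weightedEfficiency(rep), 100)
    expect_length(misclassifiedIds(rep), 0)

    toy2 <- makeToy(c("C/C", "C/T"), c(70, 90))
    rep2 <- markerEfficiency(toy2$g, toy2$p, "snp1")
    expect_equal(unweightedEfficiency(rep2), 0)
    expect_length(misclassifiedIds(rep2), 2)
})
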