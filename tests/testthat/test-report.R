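test_that("overlap counts enumerate membership patterns exactly", {
    two <- overlapCounts(list(A = paste0("k", 1:7), B = paste0("k", 1:7)))
    expect_equal(two$pattern, "A+B")
    expect_equal(two$count, 7L)
    got <- overlapCounts(list(A = c("1", "2"), B = c("2", "3")))
    expect_setequal(paste(got$pattern, got$count),
                    c("A 1", "A+B 1", "B 1"))
    expect_equal(sum(got$count), 3)       # union size
    five <- lapply(1:5, function(i)
        c(paste0("shared", 1:7), paste0("own", i, "_", seq_len(i))))
    names(five) <- LETTERS[1:5]
    oc <- overlapCounts(five)
    expect_equal(oc$count[oc$pattern == "A+B+C+D+E"], 7L)
    expect_equal(sum(oc$count), length(unique(unlist(five))))
    expect_error(overlapCounts(list(A = "x")), "at least two")
})

test_that("substitutions classify as transitions and transversions", {
    expect_equal(classifySubstitution("A", "G"), "transition")
    expect_equal(classifySubstitution("C", "T"), "transition")
    expect_equal(classifySubstitution("A", "C"), "transversion")
    expect_equal(classifySubstitution(c("G", "T"), c("A", "G")),
                 c("transition", "transversion"))
    expect_error(classifySubstitution("N", "A"), "A/C/G/T")
})

test_that("ti/tv ratio counts classes and guards the all-transition case", {
    ref <- c(rep("A", 24), rep("A", 9))
    alt <- c(rep("G", 24), rep("C", 9))
    r <- titvRatio(ref, alt)
    expect_equal(as.numeric(r), 24 / 9)
    expect_equal(attr(r, "ti"), 24)
    r2 <- titvRatio(c("A", "C"), c("C", "A"))
    expect_equal(as.numeric(r2), 0)
    expect_true(is.na(titvRatio("A", "G")))
})

test_that("the spectrum strand-collapses into six classes and flags CpG", {
    got <- mutationSpectrum(c("G", "C", "T", "A"), c("A", "T", "G", "T"))
    expect_equal(as.integer(got$counts[c("C>T", "T>G", "T>A")]),
                 c(2L, 1L, 1L))
    expect_equal(sum(got$counts), 4)      # conservation
    expect_true(is.na(got$cpg))
    ## complementary substitutions land in the same class
    a <- mutationSpectrum("G", "A")$counts
    b <- mutationSpectrum("C", "T")$counts
    expect_equal(a, b)
    ## CpG: C>T in an ACG context; G>A preceded by C on the other strand
    got <- mutationSpectrum(c("C", "G", "C"), c("T", "A", "T"),
                            context = c("ACG", "CGT", "ACA"))
    expect_equal(got$cpg, 2L)
})

test_that("transmission statistics reproduce printed-style rates and p-values", {
    rw <- transmissionStats(14, 21)
    expect_equal(round(100 * rw$rate), 67)
    sb <- transmissionStats(15, 29)
    expect_equal(round(100 * sb$rate), 52)
    all33 <- transmissionStats(21, 33)
    expect_equal(round(all33$p_one_sided, 2), 0.08)
    expect_equal(all33$p_two_sided, binomTwoSidedP(21, 33))
    expect_error(transmissionStats(0, 0), "no candidates")
})

test_that("transmission summary supports genotype and read-support definitions", {
    cfg <- simConfig(genome_length = 1e5, mu_true = 0,
                     n_background_sites = 2000, seed = 31)
    sim <- simulateTrio(cfg)
    sp <- injectSpikes(sim$records, sim$truth, nSpikes = 200, seed = 7)
    g <- simulateThirdGeneration(sp$records, sp$truth, seed = 8)
    tt <- truthTable(g$truth)
    cand <- data.frame(chrom = "1", pos = tt$pos[tt$kind == "dnm"],
                       allele_index = 1L)
    byGt <- transmissionSummary(cand, g$records, definition = "genotype")
    byRd <- transmissionSummary(cand, g$records,
                                definition = "read_support",
                                minAltReads = 3)
    expect_equal(byGt$total, 200)
    ## both definitions should track the ledger's transmission truth
    truthRate <- mean(tt$transmitted[tt$kind == "dnm"])
    expect_lt(abs(byGt$rate - truthRate), 0.05)
    expect_lt(abs(byRd$rate - truthRate), 0.05)
    expect_error(transmissionSummary(cand[0, ], g$records),
                 "no candidate sites")
})

test_that("the filter sweep varies one family at a time", {
    sim <- simulateTrio(simConfig(genome_length = 1e5, mu_true = 1e-4,
                                  n_background_sites = 2000, seed = 37))
    lb <- filterPreset("LB")
    grid <- list(gq = list(none = list(),
                           gq20 = list(gq_min = c(parent = 20, child = 20)),
                           gq60 = list(gq_min = c(parent = 60, child = 60)),
                           gq80 = list(gq_min = c(parent = 80, child = 80))))
    sw <- filterSweep(sim$records, sim$truth, TRIO, lb, grid)
    gqRows <- sw[sw$family == "gq", ]
    expect_equal(gqRows$setting, c("none", "gq20", "gq60", "gq80"))
    expect_true(all(diff(gqRows$n_candidates) <= 0))
    ## base row reproduces the plain pipeline run
    plain <- runPipeline(sim$records, TRIO, lb)
    expect_equal(sw$n_candidates[sw$family == "base"],
                 nrow(plain$candidates))
    ## narrowing the AB window never lowers the AB-based FNR
    abGrid <- list(ab = list(
        loose = list(mode = "window", ab_min = 0.2, ab_max = 1),
        mid = list(mode = "window", ab_min = 0.3, ab_max = 0.7),
        tight = list(mode = "window", ab_min = 0.4, ab_max = 0.6)))
    sw2 <- filterSweep(sim$records, sim$truth, TRIO, lb, abGrid,
                       includeBase = FALSE)
    expect_true(all(diff(sw2$fnr) >= 0))
    expect_error(filterSweep(sim$records, sim$truth, TRIO, lb,
                             list(bogus = list(a = list()))),
                 "filter sections")
})

test_that("the standardized report covers the checklist and flags gaps", {
    sim <- simulateTrio(simConfig(genome_length = 1e5, mu_true = 1e-4,
                                  n_background_sites = 2000, seed = 41))
    lb <- filterPreset("LB")
    res <- runPipeline(sim$records, TRIO, lb)
    bg <- backgroundRecords(sim$records, sim$truth)
    cg <- callableGenomeCount(bg, TRIO, lb,
                              genomeSites = genomeLength(sim$truth))
    fnr <- fnrSiteFilterProportion(sim$records, lb)
    rate <- mutationRate(nrow(res$candidates), fdr = fdrFromValidation(9, 1),
                         cg = cg, fnr = fnr)
    rep1 <- standardizedReport(res, lb, rate = rate)
    expect_equal(rep1$fdr$value, 0.1)
    expect_equal(rep1$callable_genome$method, "count_based")
    expect_equal(rep1$n_final_candidates, nrow(res$candidates))
    ## accounting passes through verbatim
    expect_identical(rep1$candidates_after_each_filter, res$accounting)
    ## no validation data: the FDR field reads "not reported"
    rep2 <- standardizedReport(res, lb)
    expect_equal(rep2$fdr, "not reported")
    expect_equal(rep2$spectrum$cpg_percent, "not computed")
    out <- withr::local_tempfile(fileext = ".json")
    writeStandardizedReport(rep1, out)
    expect_true(jsonlite::validate(paste(readLines(out), collapse = "")))
    md <- withr::local_tempfile(fileext = ".md")
    writeStandardizedReport(rep1, md, format = "markdown")
    expect_gt(length(readLines(md)), 10)
})
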