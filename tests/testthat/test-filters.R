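test_that("site filter fails on strict violations and passes at bounds", {
    cfg <- filterPreset("gatk_default")
    ann <- data.frame(qual = NA, qd = c(1.5, 2.0, 25), mq = c(60, 40, 60),
                      fs = c(10, 60, 10), sor = c(1, 3, 1),
                      mq_rank_sum = c(0, -12.5, NA),
                      read_pos_rank_sum = c(0, -8, 0),
                      base_q_rank_sum = NA)
    v <- siteFilter(ann, cfg)
    expect_false(verdictPassed(v)[1])
    expect_match(v@reasons[1], "QD=1.5<2")
    ## every annotation exactly at its threshold passes
    expect_true(verdictPassed(v)[2])
    ## missing annotation is recorded, others decide
    expect_true(verdictPassed(v)[3])
    expect_true("MQRankSum" %in% notEvaluable(v)[[3]])
})

test_that("missing_policy=fail removes calls with missing data", {
    cfg <- filterConfig(site = list(qd_min = 2), missing_policy = "fail")
    v <- siteFilter(data.frame(qd = NA_real_), cfg)
    expect_false(verdictPassed(v))
    expect_match(v@reasons, "QD=NA")
})

test_that("depth filter covers absolute, relative, sigma and Poisson modes", {
    cAbs <- filterConfig(depth = list(dp_min = 10, dp_max = 80))
    v <- depthFilter(c(9, 10, 80, 81, NA), config = cAbs)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, TRUE, FALSE, TRUE))
    expect_true("DP" %in% notEvaluable(v)[[5]])

    cRel <- filterConfig(depth = list(low_mult = 0.5, high_mult = 2))
    v <- depthFilter(c(150, 140, 34), stats = list(mean = 70), config = cRel)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, FALSE))

    cSig <- filterConfig(depth = list(n_sigma = 3))
    v <- depthFilter(c(40, 70, 101), stats = list(mean = 70, sd = 10),
                     config = cSig)
    expect_equal(verdictPassed(v), c(TRUE, TRUE, FALSE))

    cTrio <- filterConfig(depth = list(trio_low_mult = 0.5,
                                       trio_high_mult = 2))
    v <- depthFilter(c(24, 25, 101), trioStats = list(mean = 50),
                     stats = list(mean = 50), config = cTrio)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, FALSE))

    cPois <- filterConfig(depth = list(poisson_p = 2e-4))
    v <- depthFilter(c(140, 70), stats = list(mean = 70), config = cPois)
    expect_equal(verdictPassed(v), c(FALSE, TRUE))
    ## direction switch for the literal reading
    cHigh <- filterConfig(depth = list(poisson_p = 2e-4,
                                       poisson_direction = "high"))
    v <- depthFilter(c(140, 70), stats = list(mean = 70), config = cHigh)
    expect_equal(verdictPassed(v), c(TRUE, FALSE))
})

test_that("exact binomial and Poisson tails equal brute-force mass sums", {
    for (n in 1:30) {
        for (k in c(0L, n %/% 3L, n %/% 2L, n)) {
            mass <- dbinom(0:n, n, 0.5)
            lower <- sum(mass[seq_len(k + 1)])
            upper <- sum(mass[(k + 1):(n + 1)])
            expect_equal(binomTwoSidedP(k, n),
                         min(1, 2 * min(lower, upper)), tolerance = 1e-12)
        }
    }
    for (lambda in c(0.5, 3, 10)) {
        for (x in 0:30) {
            mass <- dpois(0:400, lambda)       # tail truncation negligible
            lower <- sum(mass[seq_len(x + 1)])
            upper <- sum(mass[(x + 1):length(mass)])
            expect_equal(poissonTwoSidedP(x, lambda),
                         min(1, 2 * min(lower, upper)), tolerance = 1e-9)
        }
    }
})

test_that("genotype quality filter works in GQ and PL-gap modes", {
    cGq <- filterConfig(gq = list(gq_min = c(parent = 40, child = 60)))
    v <- genotypeQualityFilter(c(55, 60, 99), role = "child", config = cGq)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, TRUE))
    v <- genotypeQualityFilter(55, role = "parent", config = cGq)
    expect_true(verdictPassed(v))
    ## boundary: gq exactly at the threshold passes
    cStrict <- filterConfig(gq = list(gq_min = c(parent = 99, child = 99)))
    expect_true(verdictPassed(genotypeQualityFilter(99, role = "child",
                                                    config = cStrict)))
    cPl <- filterConfig(gq = list(pl_gap_min = c(hom = 100, het = 200)))
    pl <- rbind(c(0, 120, 800), c(0, 250, 900), c(0, 150, 120))
    v <- genotypeQualityFilter(rep(NA, 3), pl = pl,
                               zygosity = c("het", "het", "hom"),
                               config = cPl)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, TRUE))
    ## nothing to evaluate
    v <- genotypeQualityFilter(NA_real_, role = "child", config = cGq)
    expect_true(verdictPassed(v))
    expect_true("GQ.child" %in% notEvaluable(v)[[1]])
})

test_that("parental alt-read filter enforces AD and low-quality AD caps", {
    ad <- rbind(c(30, 1), c(30, 1), c(30, 0))
    c0 <- filterConfig(parent_allele = list(parent_ad_max = 0))
    expect_equal(verdictPassed(parentAlleleFilter(ad, rep(1L, 3),
                                                  config = c0)),
                 c(FALSE, FALSE, TRUE))
    c1 <- filterConfig(parent_allele = list(parent_ad_max = 1))
    expect_true(all(verdictPassed(parentAlleleFilter(ad, rep(1L, 3),
                                                     config = c1))))
    cLq <- filterConfig(parent_allele = list(parent_ad_max = 1,
                                             lowq_ad_alt_max = 1))
    v <- parentAlleleFilter(ad, rep(1L, 3), lowqAdAlt = c(2, 1, 0),
                            config = cLq)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, TRUE))
})

test_that("allelic balance is ad[alt] over informative reads", {
    ad <- rbind(c(15, 15), c(20, 5), c(0, 12), c(0, 0))
    ab <- allelicBalance(ad, rep(1L, 4))
    expect_equal(ab[1:3], c(0.5, 0.2, 1.0))
    expect_true(is.nan(ab[4]))
})

test_that("AB filter window and binomial modes behave as specified", {
    cw <- filterConfig(ab = list(mode = "window", ab_min = 0.3,
                                 ab_max = 0.7))
    ad <- rbind(c(8, 2), c(7, 3), c(3, 7), c(2, 8))   # AB .2 .3 .7 .8
    expect_equal(verdictPassed(abFilter(ad, rep(1L, 4), cw)),
                 c(FALSE, TRUE, TRUE, FALSE))
    cb <- filterConfig(ab = list(mode = "binomial", p_threshold = 0.05))
    ad2 <- rbind(c(25, 5), c(16, 14))
    expect_equal(verdictPassed(abFilter(ad2, rep(1L, 2), cb)),
                 c(FALSE, TRUE))
    ## symmetry of the two-sided test
    expect_equal(binomTwoSidedP(5, 30), binomTwoSidedP(25, 30))
    ## zero informative reads is not evaluable
    v <- abFilter(rbind(c(0, 0)), 1L, cw)
    expect_true(verdictPassed(v))
    expect_true("AB" %in% notEvaluable(v)[[1]])
})

test_that("cluster filter removes dense windows and close pairs", {
    cfg <- filterConfig(cluster = list(window_bp = 200, max_in_window = 4))
    keep <- clusterFilter(rep("1", 4), c(100, 150, 200, 250), cfg)
    expect_equal(keep, rep(FALSE, 4))
    ## three candidates in the window survive
    keep <- clusterFilter(rep("1", 3), c(100, 150, 200), cfg)
    expect_equal(keep, rep(TRUE, 3))
    cfgP <- filterConfig(cluster = list(pair_min_distance_bp = 10))
    expect_equal(clusterFilter(rep("1", 2), c(100, 105), cfgP),
                 c(FALSE, FALSE))
    ## strictly-closer rule: distance exactly 10 is kept
    expect_equal(clusterFilter(rep("1", 2), c(100, 110), cfgP),
                 c(TRUE, TRUE))
    ## different chromosomes never pair
    expect_equal(clusterFilter(c("1", "2"), c(100, 105), cfgP),
                 c(TRUE, TRUE))
    expect_equal(clusterFilter("1", 100, cfgP), TRUE)
})

test_that("exclusion filter hits population SNPs, masks and other carriers", {
    cfg <- filterConfig(exclusion = list(masks = "LCR"))
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines("1\t500\t600", bed)
    masks <- list(LCR = readMask(bed, "LCR"))
    pop <- data.frame(chrom = "1", pos = 1000)
    v <- exclusionFilter(chrom = rep("1", 3), pos = c(550, 1000, 77),
                         allele = c("G", "G", "G"),
                         populationSnps = pop, masks = masks, config = cfg)
    expect_equal(verdictPassed(v), c(FALSE, FALSE, TRUE))
    expect_match(v@reasons[1], "mask:LCR")
    expect_match(v@reasons[2], "populationSNP")
    oc <- data.frame(chrom = "1", pos = 77)
    v <- exclusionFilter(chrom = "1", pos = 77, otherCarriers = oc,
                         config = cfg)
    expect_false(verdictPassed(v))
})

test_that("strand filter requires alt support on both strands when set", {
    cfg <- filterConfig(strand = list(both_strands = TRUE))
    v <- strandFilter(c(5, 1, NA), c(0, 1, 2), cfg)
    expect_equal(verdictPassed(v), c(FALSE, TRUE, TRUE))
    expect_true("strand" %in% notEvaluable(v)[[3]])
    off <- filterConfig()
    expect_true(all(verdictPassed(strandFilter(c(5, 0), c(0, 0), off))))
})

test_that("named presets transcribe the published pipeline thresholds", {
    lb <- filterPreset("LB")
    expect_equal(lb@ab[c("ab_min", "ab_max")],
                 list(ab_min = 0.3, ab_max = 0.7))
    expect_equal(lb@gq$gq_min[["child"]], 60)
    expect_null(lb@parent_allele$parent_ad_max)
    expect_equal(lb@site$fs_max, 20)
    rw <- filterPreset("RW")
    expect_equal(rw@depth[c("dp_min", "dp_max")],
                 list(dp_min = 20, dp_max = 80))
    expect_true(rw@strand$both_strands)
    sb <- filterPreset("SB")
    expect_equal(sb@depth$dp_min, 10)
    expect_equal(sb@depth$high_mult, 2)
    expect_equal(sb@parent_allele$lowq_ad_alt_max, 1)
    expect_equal(filterPreset("gatk_default")@site$fs_max, 60)
    tt <- filterPreset("TT")
    expect_equal(tt@violation_mode, "allele_absence")
    expect_error(filterPreset("nope"), "available")
})

test_that("YAML config overrides a preset key by key", {
    yml <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("preset: LB", "ab:", "  ab_min: 0.2",
                 "missing_policy: fail"), yml)
    cfg <- readFilterConfig(yml)
    expect_equal(cfg@ab$ab_min, 0.2)
    expect_equal(cfg@ab$ab_max, 0.7)      # preset value kept
    expect_equal(cfg@missing_policy, "fail")
})

test_that("homopolymer masks cover A/T runs of ten or more", {
    seqs <- list(chr1 = paste0("GCGC", strrep("A", 12), "GG",
                               strrep("T", 9), "C"))
    m <- homopolymerMask(seqs)
    expect_equal(length(m), 1)            # the T run is too short
    expect_equal(GenomicRanges::start(m), 5)
    expect_equal(GenomicRanges::end(m), 16)
})

test_that("failed verdicts replay from their named reasons", {
    cfg <- filterPreset("gatk_default")
    set.seed(1)
    ann <- data.frame(qd = runif(200, 0, 5), mq = runif(200, 30, 60),
                      fs = runif(200, 0, 100), sor = runif(200, 0, 5),
                      qual = NA, mq_rank_sum = rnorm(200, 0, 8),
                      read_pos_rank_sum = rnorm(200, 0, 5),
                      base_q_rank_sum = NA)
    v <- siteFilter(ann, cfg)
    failed <- which(!verdictPassed(v))
    expect_gt(length(failed), 0)
    for (i in failed[1:25]) {
        names <- sub("=.*", "", verdictReasons(v)[[i]])
        expect_gt(length(names), 0)
        ## replaying only the named filters reproduces the failure
        replay <- list(QD = ann$qd[i] < 2, MQ = ann$mq[i] < 40,
                       FS = ann$fs[i] > 60, SOR = ann$sor[i] > 3,
                       MQRankSum = ann$mq_rank_sum[i] < -12.5,
                       ReadPosRankSum = ann$read_pos_rank_sum[i] < -8)
        expect_true(all(unlist(replay[names])))
    }
})
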