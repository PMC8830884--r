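test_that("count-based callable genome counts hand-verifiable toy tables", {
    ## 5 sites; exactly 3 satisfy DP in [10,80] and GQ >= 20 for all members
    rec <- toyRecords(rbind(
        site(1, "0/0|40|40,0|99", "0/0|40|40,0|99", "0/0|40|40,0|99"),
        site(2, "0/0|9|9,0|99",  "0/0|40|40,0|99", "0/0|40|40,0|99"),
        site(3, "0/0|40|40,0|99", "0/0|40|40,0|15", "0/0|40|40,0|99"),
        site(4, "0/0|80|80,0|20", "0/0|10|10,0|20", "0/0|30|30,0|55"),
        site(5, "0/0|50|50,0|99", "0/0|60|60,0|99", "0/0|70|70,0|99")))
    cfg <- filterConfig(depth = list(dp_min = 10, dp_max = 80),
                        gq = list(gq_min = c(parent = 20, child = 20)))
    got <- callableGenomeCount(rec, TRIO, cfg)
    expect_equal(got@cgSites, 3)
    expect_equal(got@nExamined, 5)
    ## empty input and the all-pass degenerate case
    empty <- rec[integer(0)]
    expect_equal(callableGenomeCount(empty, TRIO, cfg)@cgSites, 0)
    loose <- filterConfig()
    expect_equal(callableGenomeCount(rec, TRIO, loose)@cgSites, 5)
    ## extrapolation from a uniform sample
    ex <- callableGenomeCount(rec, TRIO, cfg, genomeSites = 1000)
    expect_equal(cgSites(ex), 3 / 5 * 1000)
})

test_that("non-homref-parent-only input is rejected with BP-resolution advice", {
    rec <- toyRecords(site(1, "0/1|40|20,20|99", "0/0|40|40,0|99",
                           "0/1|40|20,20|99"))
    expect_error(callableGenomeCount(rec, TRIO, filterConfig()),
                 "BP-resolution")
})

test_that("callable genome shrinks (never grows) under stricter thresholds", {
    sim <- simulateTrio(simConfig(genome_length = 5e4,
                                  n_background_sites = 3000, seed = 4))
    bg <- backgroundRecords(sim$records, sim$truth)
    cgAt <- function(dpMin, gqMin)
        callableGenomeCount(bg, TRIO, filterConfig(
            depth = list(dp_min = dpMin),
            gq = list(gq_min = c(parent = gqMin, child = gqMin))))@cgSites
    base <- cgAt(10, 20)
    expect_lte(cgAt(30, 20), base)
    expect_lte(cgAt(10, 60), base)
    expect_lte(cgAt(30, 60), min(cgAt(30, 20), cgAt(10, 60)))
})

test_that("probabilistic callable genome sums empirical pass probabilities", {
    inh <- data.frame(dp_father = rep(40, 100), dp_mother = 40,
                      dp_child = 40, passed = TRUE)
    prof <- data.frame(dp_father = rep(40, 10), dp_mother = 40,
                       dp_child = 40, weight = 100)
    got <- callableGenomeProbabilistic(inh, prof)
    expect_equal(got@cgSites, 1000)       # identically-1 table: full length
    inh$passed <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 20)  # 0.8
    got <- callableGenomeProbabilistic(inh, prof)
    expect_equal(got@cgSites, 800)
    ## reduces to the count when probabilities are 0/1
    inh2 <- data.frame(dp_father = c(rep(20, 50), rep(60, 50)),
                       dp_mother = 40, dp_child = 40,
                       passed = rep(c(FALSE, TRUE), each = 50))
    prof2 <- data.frame(dp_father = c(20, 60), dp_mother = 40,
                        dp_child = 40, weight = c(300, 700))
    expect_equal(callableGenomeProbabilistic(inh2, prof2)@cgSites, 700)
    ## empty bins borrow the nearest populated bin
    prof3 <- data.frame(dp_father = 25, dp_mother = 40, dp_child = 40)
    got3 <- callableGenomeProbabilistic(inh2, prof3)
    expect_equal(got3@cgSites, 0)         # nearest bin is the dp=20 one
})

test_that("probabilistic table from simulation matches truth pass rates", {
    set.seed(8)
    n <- 4000
    dp <- rpois(n, 40)
    nalt <- rbinom(n, dp, 0.5)
    passed <- nalt / dp >= 0.3 & nalt / dp <= 0.7
    passed[is.na(passed)] <- FALSE
    inh <- data.frame(dp_father = 40, dp_mother = 40, dp_child = dp,
                      passed = passed)
    prof <- data.frame(dp_father = 40, dp_mother = 40,
                       dp_child = rpois(2000, 40))
    got <- callableGenomeProbabilistic(inh, prof)
    pTrue <- mean(passed)
    se <- sqrt(pTrue * (1 - pTrue) / n) * 2000
    expect_lt(abs(got@cgSites - pTrue * 2000), 4 * se + 20)
})

test_that("spike-in FNR is the missed fraction and hits 0 when nothing is lost", {
    cfg <- simConfig(genome_length = 1e5, mu_true = 0, sequencing_error = 0,
                     annotation_outlier_fraction = 0,
                     n_background_sites = 1000, seed = 14)
    sim <- simulateTrio(cfg)
    sp <- injectSpikes(sim$records, sim$truth, nSpikes = 300, seed = 3)
    est <- fnrSpikeIn(sp$records, sp$truth, TRIO, permissiveConfig())
    expect_equal(est@value, 0)
    expect_equal(est@nBasis, 300)
    ## a filter that rejects some spikes raises the estimate accordingly
    abCfg <- permissiveConfig(ab = list(mode = "window", ab_min = 0.45,
                                        ab_max = 0.55))
    est2 <- fnrSpikeIn(sp$records, sp$truth, TRIO, abCfg)
    expect_gt(est2@value, 0)
    ## no injected DNMs: undefined
    expect_error(fnrSpikeIn(sim$records, sim$truth, TRIO,
                            permissiveConfig()), "undefined")
})

test_that("AB-based FNR is the out-of-window fraction of true heterozygotes", {
    cfg <- filterConfig(ab = list(mode = "window", ab_min = 0.3,
                                  ab_max = 0.7))
    ## 158 of 1000 constructed outside the window
    adAlt <- c(rep(2L, 158), rep(10L, 842))
    adRef <- 20L - adAlt
    est <- fnrAb(adRef, adAlt, cfg)
    expect_equal(est@value, 0.158)
    expect_equal(est@nBasis, 1000)
    ## the vacuous window filters nothing
    wide <- filterConfig(ab = list(mode = "window", ab_min = 0,
                                   ab_max = 1))
    expect_equal(fnrAb(adRef, adAlt, wide)@value, 0)
    expect_error(fnrAb(integer(0), integer(0), cfg), "undefined")
})

test_that("site-filter FNR is the trusted-variant loss and grows when tightened", {
    ann <- data.frame(qd = rep(25, 1000), mq = 60,
                      fs = c(rep(80, 25), rep(5, 975)), sor = 1,
                      qual = NA, mq_rank_sum = 0, read_pos_rank_sum = 0,
                      base_q_rank_sum = NA)
    cfg <- filterConfig(site = list(fs_max = 60))
    expect_equal(fnrSiteFilterProportion(ann, cfg)@value, 0.025)
    none <- filterConfig(site = list(fs_max = 200))
    expect_equal(fnrSiteFilterProportion(ann, none)@value, 0)
    tighter <- filterConfig(site = list(fs_max = 3))
    expect_gte(fnrSiteFilterProportion(ann, tighter)@value, 0.025)
})

test_that("FNR sources combine as complementary products", {
    a <- new("FnrEstimate", value = 0.05, method = "site_filter_proportion",
             nBasis = 100)
    b <- new("FnrEstimate", value = 0.10, method = "ab_empirical",
             nBasis = 100)
    expect_equal(combineFnr(list(a, b))@value, 0.145)
    expect_equal(combineFnr(list(0.08), mode = "single")@value, 0.08)
    expect_equal(combineFnr(list(a, 1))@value, 1)     # absorbing
    expect_error(combineFnr(list(1.2)), "\\[0,1\\]")
})
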