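test_that("pedigree parsing derives trios and generations", {
    ped <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM F 0 0 1 0", "FAM M 0 0 2 0", "FAM C F M 2 0"), ped)
    p <- readPedigree(ped)
    tt <- trios(p)
    expect_equal(nrow(tt), 1)
    expect_equal(tt$child, "C")
    expect_true(tt$complete)
    expect_equal(pedigreeTable(p)$generation,
                 c(0L, 0L, 1L))
})

test_that("a three-generation pedigree with an unknown grandparent resolves", {
    ped <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM Noot 0 0 1 0",
                 "FAM M 0 0 2 0",
                 "FAM Heineken Noot M 2 0",
                 "FAM Hoegaarde 0 Heineken 2 0"), ped)
    p <- readPedigree(ped)
    tt <- trios(p)
    expect_setequal(tt$child, c("Heineken", "Hoegaarde"))
    expect_false(tt$complete[tt$child == "Hoegaarde"])
    tb <- pedigreeTable(p)
    expect_equal(tb$generation[tb$id == "Hoegaarde"], 2L)
    expect_error(resolveTrio(p, "Hoegaarde"), "lacks a known parent")
    got <- resolveTrio(p, "Heineken")
    expect_equal(got, list(father = "Noot", mother = "M",
                           child = "Heineken"))
})

test_that("cyclic or self-referential parentage is a structural error", {
    ped <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("FAM F 0 0 1 0", "FAM M 0 0 2 0", "FAM C C M 2 0"), ped)
    expect_error(readPedigree(ped), "own parent")
    writeLines(c("FAM A B 0 1 0", "FAM B A 0 1 0", "FAM C A B 1 0"), ped)
    expect_error(readPedigree(ped), "cyclic")
})

test_that("VCF records map to calls with missingness preserved", {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
        "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"pl\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tfather\tmother\tchild",
        paste("1", 100, ".", "A", "G", "500", "PASS", "QD=20.5;MQ=60",
              "GT:DP:AD:GQ:PL", "0/0:40:40,0:99:0,120,1800",
              "0/0:38:38,0:99:0,114,1710", "0/1:42:20,22:99:500,0,480",
              sep = "\t"),
        paste("1", 200, ".", "G", "C,A", "300", "PASS", "QD=15",
              "GT:DP:AD:GQ:PL", "0/1:30:15,15,0:80:300,0,400,350,390,700",
              "0/0:30:30,0,0:90:0,90,1350,90,1350,1350",
              "0/2:35:18,0,17:85:350,380,700,0,390,420", sep = "\t")),
        vcf)
    rec <- readTrioVcf(vcf)
    expect_equal(length(rec), 2)
    expect_equal(sampleIds(rec), c("father", "mother", "child"))
    f <- sampleCalls(rec, "father")
    expect_equal(f$gt1, c(0L, 0L))
    expect_equal(f$gt2, c(0L, 1L))
    expect_equal(f$dp, c(40L, 30L))
    ## absence preserved, never a default
    expect_true(is.na(siteInfo(rec)$mq_rank_sum[1]))
    expect_true(is.na(siteInfo(rec)$mq[2]))
    ## multi-allelic kept with all alt alleles
    expect_equal(rec@alt[2], "C,A")
    ch <- sampleCalls(rec, "child")
    expect_equal(ch$gt2[2], 2L)
    expect_equal(ch$ad[2, 3], 17)
})

test_that("pedigree samples absent from the VCF are a configuration error", {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX1\tX2\tX3",
        "1\t5\t.\tA\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"), vcf)
    ped <- withr::local_tempfile(fileext = ".ped")
    writeLines(c("F F 0 0 1 0", "F M 0 0 2 0", "F C F M 2 0"), ped)
    expect_error(readTrioVcf(vcf, readPedigree(ped)), "F, M, C")
})

test_that("BED masks merge, reject bad rows, and use half-open coordinates", {
    bed <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("chr1\t10\t20", "chr1\t15\t30"), bed)
    m <- readMask(bed, "LCR")
    expect_equal(length(m), 1)
    expect_equal(GenomicRanges::start(m), 11)   # 1-based internal
    expect_equal(GenomicRanges::end(m), 30)
    ## a VCF pos p is inside iff p-1 in [start, end)
    expect_true(inMask(m, "chr1", 11))
    expect_false(inMask(m, "chr1", 10))
    expect_true(inMask(m, "chr1", 30))
    expect_false(inMask(m, "chr1", 31))

    writeLines(character(0), bed)
    expect_equal(length(readMask(bed)), 0)

    writeLines(c("chr1\t20\t10", "chr1\t5\t8"), bed)
    expect_warning(m2 <- readMask(bed), "rejected")
    expect_equal(length(m2), 1)
})

test_that("candidate TSV round-trips exactly and VCF output carries provenance", {
    sim <- simulateTrio(simConfig(genome_length = 5e4, mu_true = 2e-4,
                                  n_background_sites = 500, seed = 42))
    res <- runPipeline(sim$records, TRIO, filterPreset("TT"))
    expect_gt(nrow(res$candidates), 0)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeCandidates(res$candidates, tsv, "tsv")
    back <- readCandidates(tsv)
    expect_equal(back$pos, res$candidates$pos)
    expect_equal(back$alt, res$candidates$alt)
    expect_equal(back$status, res$candidates$status)
    ## zero candidates: header-only file
    writeCandidates(res$candidates[0, ], tsv, "tsv")
    expect_equal(nrow(readCandidates(tsv)), 0)
    vcfOut <- withr::local_tempfile(fileext = ".vcf")
    writeCandidates(res$candidates, vcfOut, "vcf")
    lines <- readLines(vcfOut)
    expect_true(any(grepl("PROV=", lines)))
})

test_that("simulator VCF round-trips chrom/pos/alleles/genotypes exactly", {
    sim <- simulateTrio(simConfig(genome_length = 2e4, mu_true = 1e-4,
                                  n_background_sites = 200, seed = 5))
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeTrioVcf(sim$records, vcf)
    back <- readTrioVcf(vcf)
    expect_equal(back@chrom, sim$records@chrom)
    expect_equal(back@pos, sim$records@pos)
    expect_equal(back@ref, sim$records@ref)
    expect_equal(back@alt, sim$records@alt)
    for (id in sampleIds(sim$records)) {
        a <- sampleCalls(back, id); b <- sampleCalls(sim$records, id)
        expect_equal(a$gt1, b$gt1)
        expect_equal(a$gt2, b$gt2)
        expect_equal(a$dp, b$dp)
        expect_equal(unname(a$ad), unname(b$ad))
    }
})
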