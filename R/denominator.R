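## Callable-genome (CG) and false-negative-rate (FNR) estimation.

#' Count-based callable-genome estimate
#'
#' Counts the sites at which a DNM would have been detected: both parents
#' confidently homozygous for the reference allele and every trio member
#' passing the configured depth and genotype-quality filters. The input
#' must cover non-variant positions (BP-resolution-style records, ALT
#' \code{"."}).
#'
#' @param records a \code{TrioGenotypes} covering non-variant sites.
#' @param trio list with \code{father}, \code{mother}, \code{child} ids.
#' @param config a \code{FilterConfig} (its \code{depth} and \code{gq}
#'   sections are applied).
#' @param genomeSites total number of genome sites the examined records
#'   represent; when the records are a uniform sample (as emitted by the
#'   simulator) the callable count is extrapolated as
#'   \code{cg/nExamined * genomeSites}.
#' @param depthStats optional per-individual \code{list(mean, sd)} for
#'   relative depth rules.
#' @param requireParentAdPurity also require the parental
#'   alternative-allele-read filter to pass (off by default; the published
#'   pipelines differ on this point).
#' @return a \code{\linkS4class{CallableResult}}.
#' @export
callableGenomeCount <- function(records, trio, config, genomeSites = NA_real_,
                                depthStats = NULL,
                                requireParentAdPurity = FALSE) {
    n <- length(records)
    if (n == 0)
        return(new("CallableResult", cgSites = 0, nExamined = 0,
                   method = "count_based", perChrom = data.frame(),
                   genomeSites = as.numeric(genomeSites),
                   cgExtrapolated = NA_real_, filters = list()))
    f <- sampleCalls(records, trio$father)
    m <- sampleCalls(records, trio$mother)
    homref <- !is.na(f$gt1) & f$gt1 == 0L & !is.na(f$gt2) & f$gt2 == 0L &
        !is.na(m$gt1) & m$gt1 == 0L & !is.na(m$gt2) & m$gt2 == 0L
    nonVariant <- records@alt == "." | homref
    if (!any(nonVariant))
        stop("input contains no non-variant (BP-resolution) sites; ",
             "callable-genome counting needs per-site records that ",
             "include monomorphic positions")

    members <- c(trio$father, trio$mother, trio$child)
    needStats <- any(c("low_mult", "high_mult", "n_sigma", "poisson_p",
                       "trio_low_mult", "trio_high_mult") %in%
                     names(config@depth))
    if (is.null(depthStats) && needStats)
        depthStats <- lapply(records@geno[members], function(g)
            list(mean = mean(g$dp, na.rm = TRUE),
                 sd = stats::sd(g$dp, na.rm = TRUE)))
    trioMean <- if (needStats)
        mean(vapply(depthStats[members], `[[`, 0, "mean")) else NA_real_

    pass <- homref
    for (id in members) {
        g <- sampleCalls(records, id)
        role <- if (id == trio$child) "child" else "parent"
        dv <- depthFilter(g$dp, stats = depthStats[[id]],
                          trioStats = list(mean = trioMean), config)
        zyg <- ifelse(!is.na(g$gt1) & !is.na(g$gt2) & g$gt1 == g$gt2,
                      "hom", "het")
        qv <- genotypeQualityFilter(g$gq, g$pl, role = role, zygosity = zyg,
                                    config = config)
        pass <- pass & verdictPassed(dv) & verdictPassed(qv)
        if (requireParentAdPurity && role == "parent") {
            av <- parentAlleleFilter(g$ad, rep(1L, n), g$lowq_ad_alt, config)
            pass <- pass & verdictPassed(av)
        }
    }
    perChrom <- stats::aggregate(list(cg = as.integer(pass)),
                                 by = list(chrom = records@chrom), FUN = sum)
    cg <- sum(pass)
    new("CallableResult", cgSites = cg, nExamined = n,
        method = "count_based", perChrom = perChrom,
        genomeSites = as.numeric(genomeSites),
        cgExtrapolated = if (is.na(genomeSites)) NA_real_ else
            cg / n * genomeSites,
        filters = list(depth = config@depth, gq = config@gq))
}

#' Probabilistic callable-genome estimate from inherited variants
#'
#' Uses inherited (transmitted heterozygous) variants to estimate the
#' probability that a DNM at a site would pass all filters conditional on
#' the trio's depths, then sums those probabilities over the genome's
#' depth profile. Depths are binned per individual; an empty bin borrows
#' the probability of the nearest populated bin (the number of such
#' fallback lookups is recorded as attribute \code{"nFallback"} on the
#' result's filter snapshot).
#'
#' @param inherited data.frame of inherited variants with columns
#'   \code{dp_father}, \code{dp_mother}, \code{dp_child} and logical
#'   \code{passed} (did the variant pass the filter stack).
#' @param depthProfile data.frame with the same depth columns, one row per
#'   genome site (optionally a \code{weight} column of site counts).
#' @param binWidth depth-bin width (reads).
#' @return a \code{\linkS4class{CallableResult}} with \code{method}
#'   \code{"probabilistic"}; \code{cgSites} is the (real-valued) expected
#'   number of callable sites.
#' @export
callableGenomeProbabilistic <- function(inherited, depthProfile,
                                        binWidth = 10L) {
    if (nrow(inherited) == 0)
        stop("no inherited variants supplied")
    bin <- function(df) paste(df$dp_father %/% binWidth,
                              df$dp_mother %/% binWidth,
                              df$dp_child %/% binWidth)
    binCoord <- function(df) cbind(df$dp_father %/% binWidth,
                                   df$dp_mother %/% binWidth,
                                   df$dp_child %/% binWidth)
    tabKeys <- bin(inherited)
    pTab <- tapply(inherited$passed, tabKeys, mean)
    keyCoord <- do.call(rbind, lapply(strsplit(names(pTab), " "), as.integer))

    profKeys <- bin(depthProfile)
    p <- pTab[profKeys]
    nFallback <- sum(is.na(p))
    if (nFallback > 0) {
        missIdx <- which(is.na(p))
        mc <- binCoord(depthProfile)[missIdx, , drop = FALSE]
        for (i in seq_along(missIdx)) {
            d <- rowSums(abs(keyCoord - matrix(mc[i, ], nrow(keyCoord), 3,
                                               byrow = TRUE)))
            p[missIdx[i]] <- pTab[which.min(d)]
        }
    }
    w <- if (!is.null(depthProfile$weight)) depthProfile$weight else 1
    cg <- sum(p * w)
    filters <- list(binWidth = binWidth, nBins = length(pTab))
    attr(filters, "nFallback") <- nFallback
    new("CallableResult", cgSites = cg, nExamined = sum(w * rep(1, length(p))),
        method = "probabilistic", perChrom = data.frame(),
        genomeSites = NA_real_, cgExtrapolated = NA_real_,
        filters = filters)
}

#' Spike-in false-negative-rate estimate
#'
#' Runs the full detection pipeline on simulated records carrying a truth
#' ledger of injected germline DNMs and reports the fraction missed:
#' (injected - recovered) / injected.
#'
#' @param records a simulated \code{TrioGenotypes} (see
#'   \code{\link{simulateTrio}}, \code{\link{injectSpikes}}).
#' @param truth the matching \code{\linkS4class{SimTruth}}.
#' @param trio,config,masks,populationSnps passed to
#'   \code{\link{runPipeline}}.
#' @return a \code{\linkS4class{FnrEstimate}} with \code{method}
#'   \code{"spike_in"}.
#' @export
fnrSpikeIn <- function(records, truth, trio, config, masks = list(),
                       populationSnps = NULL) {
    tt <- truthTable(truth)
    dnm <- tt[tt$kind == "dnm", , drop = FALSE]
    if (nrow(dnm) == 0)
        stop("no injected DNMs in the truth ledger; FNR undefined")
    res <- runPipeline(records, trio, config, masks = masks,
                       populationSnps = populationSnps)
    found <- paste(res$candidates$pos, res$candidates$alt)
    recovered <- sum(paste(dnm$pos, dnm$allele) %in% found)
    new("FnrEstimate", value = (nrow(dnm) - recovered) / nrow(dnm),
        method = "spike_in", nBasis = nrow(dnm))
}

#' Allelic-balance false-negative-rate estimate
#'
#' Estimates the fraction of true DNMs lost to the allelic-balance filter
#' from true heterozygous sites in the offspring (sites where one parent is
#' 0/0, the other 1/1, so the offspring is an obligate heterozygote):
#' FNR = (true het sites outside the AB filter) / (true het sites). Window
#' membership uses the same strict-inequality convention as
#' \code{\link{abFilter}}.
#'
#' @param adRef,adAlt reference / alternative read counts of the offspring
#'   at forced-heterozygote sites.
#' @param config a \code{FilterConfig} whose \code{ab} section defines the
#'   filter.
#' @return a \code{\linkS4class{FnrEstimate}} with \code{method}
#'   \code{"ab_empirical"}.
#' @export
fnrAb <- function(adRef, adAlt, config) {
    n <- length(adRef)
    if (n == 0) stop("no qualifying heterozygous sites; FNR undefined")
    ad <- cbind(adRef, adAlt)
    v <- abFilter(ad, rep(1L, n), config)
    new("FnrEstimate", value = mean(!verdictPassed(v)),
        method = "ab_empirical", nBasis = n)
}

#' Closed-form allelic-balance FNR at fixed depth
#'
#' Probability that a true heterozygote at depth \code{d} falls outside the
#' AB window \code{[ab_min, ab_max]} when alt reads follow
#' Binomial(d, 0.5): \code{1 - P(ceiling(ab_min d) <= X <= floor(ab_max d))}
#' (strict-violation convention: a count exactly on the bound passes).
#'
#' @param depth read depth(s).
#' @param abMin,abMax window bounds.
#' @return numeric FNR value(s).
#' @export
abWindowTailFnr <- function(depth, abMin, abMax) {
    lo <- ceiling(abMin * depth)
    hi <- floor(abMax * depth)
    1 - (stats::pbinom(hi, depth, 0.5) - stats::pbinom(lo - 1, depth, 0.5))
}

#' Site-filter-proportion false-negative-rate estimate
#'
#' Fraction of a trusted variant set removed by the configured site
#' filters: the same loss is assumed to apply to true DNMs.
#'
#' @param records a \code{TrioGenotypes} (or annotation data.frame) of
#'   trusted variants.
#' @param config a \code{FilterConfig}.
#' @return a \code{\linkS4class{FnrEstimate}} with \code{method}
#'   \code{"site_filter_proportion"}.
#' @export
fnrSiteFilterProportion <- function(records, config) {
    v <- siteFilter(records, config)
    n <- length(verdictPassed(v))
    if (n == 0) stop("no trusted variants supplied; FNR undefined")
    new("FnrEstimate", value = mean(!verdictPassed(v)),
        method = "site_filter_proportion", nBasis = n)
}

#' Combine independent false-negative-rate estimates
#'
#' \code{complement_product} assumes independent loss processes:
#' combined = 1 - prod(1 - value_i). \code{single} passes a single
#' estimate through.
#'
#' @param estimates list of \code{FnrEstimate}s (or numeric values).
#' @param mode \code{"complement_product"} or \code{"single"}.
#' @return a \code{\linkS4class{FnrEstimate}}.
#' @export
combineFnr <- function(estimates, mode = c("complement_product", "single")) {
    mode <- match.arg(mode)
    vals <- vapply(estimates, function(e)
        if (is(e, "FnrEstimate")) e@value else as.numeric(e), 0)
    if (any(vals < 0 | vals > 1))
        stop("FNR values must lie in [0,1]")
    basis <- sum(vapply(estimates, function(e)
        if (is(e, "FnrEstimate")) e@nBasis else 0, 0))
    if (mode == "single") {
        if (length(vals) != 1) stop("mode 'single' needs exactly one estimate")
        return(new("FnrEstimate", value = vals, method = "combined",
                   nBasis = basis))
    }
    new("FnrEstimate", value = 1 - prod(1 - vals), method = "combined",
        nBasis = basis)
}
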