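## Site-specific, sample-specific and auxiliary hard filters.
##
## All filters are vectorized over records/calls and return a FilterVerdict
## whose i-th element describes call i. Threshold violations are strict:
## values exactly at a bound pass. Missing data are routed per the config's
## missing_policy ("pass" records the filter as not evaluable; "fail"
## removes the call).

## -- verdict accumulator ----------------------------------------------------

.vdNew <- function(n) list(re = character(n), ne = character(n))

.vdFail <- function(vd, idx, msg) {
    if (!any(idx)) return(vd)
    sep <- ifelse(vd$re[idx] == "", "", ";")
    vd$re[idx] <- paste0(vd$re[idx], sep, msg)
    vd
}

.vdNE <- function(vd, idx, name) {
    if (!any(idx)) return(vd)
    sep <- ifelse(vd$ne[idx] == "", "", ";")
    vd$ne[idx] <- paste0(vd$ne[idx], sep, name)
    vd
}

## missing datum: not-evaluable under "pass", failure under "fail"
.vdMissing <- function(vd, idx, name, policy) {
    if (policy == "fail") .vdFail(vd, idx, paste0(name, "=NA"))
    else .vdNE(vd, idx, name)
}

.vdDone <- function(vd) {
    methods::new("FilterVerdict", passed = vd$re == "", reasons = vd$re,
                 notEvaluable = vd$ne)
}

.fmt <- function(x) trimws(formatC(x, format = "g", digits = 6))

## one bound: fail when cmp(value, threshold) is TRUE
.applyBound <- function(vd, value, threshold, name, op, policy) {
    if (is.null(threshold)) return(vd)
    miss <- is.na(value)
    vd <- .vdMissing(vd, miss, name, policy)
    bad <- !miss & op(value, threshold)
    sym <- if (identical(op, `<`)) "<" else ">"
    if (any(bad))
        vd <- .vdFail(vd, bad, paste0(name, "=", .fmt(value[bad]), sym,
                                      .fmt(threshold)))
    vd
}

.applyWindow <- function(vd, value, win, name, policy) {
    if (is.null(win)) return(vd)
    miss <- is.na(value)
    vd <- .vdMissing(vd, miss, name, policy)
    bad <- !miss & (value < win[1] | value > win[2])
    if (any(bad))
        vd <- .vdFail(vd, bad, paste0(name, "=", .fmt(value[bad]),
                                      "!in[", .fmt(win[1]), ",",
                                      .fmt(win[2]), "]"))
    vd
}

## -- exact tail tests -------------------------------------------------------

#' Two-sided exact binomial tail p-value
#'
#' Doubled smaller tail, capped at 1: \code{min(1, 2 min(P(X <= k),
#' P(X >= k)))} for \code{X ~ Binomial(n, p)}. Symmetric in \code{k} and
#' \code{n - k} when \code{p = 0.5}.
#'
#' @param k successes; @param n trials; @param p success probability.
#' @return p-value vector.
#' @export
binomTwoSidedP <- function(k, n, p = 0.5) {
    pmin(1, 2 * pmin(stats::pbinom(k, n, p),
                     stats::pbinom(k - 1, n, p, lower.tail = FALSE)))
}

#' Two-sided exact Poisson tail p-value
#'
#' Doubled smaller tail, capped at 1, for \code{X ~ Poisson(lambda)}.
#'
#' @param x observed count; @param lambda mean.
#' @return p-value vector.
#' @export
poissonTwoSidedP <- function(x, lambda) {
    pmin(1, 2 * pmin(stats::ppois(x, lambda),
                     stats::ppois(x - 1, lambda, lower.tail = FALSE)))
}

## -- site filters -----------------------------------------------------------

#' Site-annotation hard filter
#'
#' Applies the configured QUAL/QD/MQ/FS/SOR and rank-sum thresholds to the
#' site annotations of each record. A record fails iff any present
#' annotation strictly violates its threshold (QD < qd_min, MQ < mq_min,
#' FS > fs_max, SOR > sor_max, QUAL < qual_min, rank sums outside their
#' windows); absent annotations follow the missing policy.
#'
#' @param records a \code{TrioGenotypes} (or a data.frame of annotations).
#' @param config a \code{FilterConfig}.
#' @return a \code{\linkS4class{FilterVerdict}} with one element per record.
#' @export
siteFilter <- function(records, config) {
    info <- if (is(records, "TrioGenotypes")) siteInfo(records)
            else as.data.frame(records)
    s <- config@site
    pol <- config@missing_policy
    vd <- .vdNew(nrow(info))
    vd <- .applyBound(vd, info$qual, s$qual_min, "QUAL", `<`, pol)
    vd <- .applyBound(vd, info$qd, s$qd_min, "QD", `<`, pol)
    vd <- .applyBound(vd, info$mq, s$mq_min, "MQ", `<`, pol)
    vd <- .applyBound(vd, info$fs, s$fs_max, "FS", `>`, pol)
    vd <- .applyBound(vd, info$sor, s$sor_max, "SOR", `>`, pol)
    vd <- .applyWindow(vd, info$mq_rank_sum, s$mq_rank_sum_window,
                       "MQRankSum", pol)
    vd <- .applyWindow(vd, info$read_pos_rank_sum, s$read_pos_rank_sum_window,
                       "ReadPosRankSum", pol)
    vd <- .applyWindow(vd, info$base_q_rank_sum, s$base_q_rank_sum_window,
                       "BaseQRankSum", pol)
    .vdDone(vd)
}

## -- depth ------------------------------------------------------------------

#' Per-sample read-depth filter
#'
#' Evaluates every configured depth constraint: absolute bounds
#' (\code{dp_min}/\code{dp_max}), bounds relative to the individual mean
#' depth (\code{low_mult}/\code{high_mult}), relative to the trio mean
#' (\code{trio_low_mult}/\code{trio_high_mult}), a sigma rule
#' (\code{|dp - mean| > n_sigma * sd}), and an exact two-sided Poisson test
#' of dp against lambda = individual mean (removal when the p-value falls
#' below \code{poisson_p}; set \code{poisson_direction = "high"} to apply
#' the test in the opposite, literal-reading direction).
#'
#' @param dp integer depth vector for one individual.
#' @param stats list with the individual's \code{mean} (and \code{sd} for
#'   the sigma rule).
#' @param trioStats list with the trio \code{mean} (for trio-relative
#'   bounds).
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
depthFilter <- function(dp, stats = list(), trioStats = list(), config) {
    d <- config@depth
    pol <- config@missing_policy
    vd <- .vdNew(length(dp))
    miss <- is.na(dp)
    if (length(d) && any(miss)) vd <- .vdMissing(vd, miss, "DP", pol)
    vd <- .applyBound(vd, dp, d$dp_min, "DP", `<`, pol)
    vd <- .applyBound(vd, dp, d$dp_max, "DP", `>`, pol)
    needMean <- !is.null(d$low_mult) || !is.null(d$high_mult) ||
        !is.null(d$n_sigma) || !is.null(d$poisson_p)
    if (needMean && is.null(stats$mean))
        stop("depth filter configured relative to the individual mean but no mean supplied")
    vd <- .applyBound(vd, dp, if (is.null(d$low_mult)) NULL else
        d$low_mult * stats$mean, "DPrel", `<`, pol)
    vd <- .applyBound(vd, dp, if (is.null(d$high_mult)) NULL else
        d$high_mult * stats$mean, "DPrel", `>`, pol)
    if (!is.null(d$trio_low_mult) || !is.null(d$trio_high_mult)) {
        if (is.null(trioStats$mean))
            stop("trio-relative depth filter needs the trio mean depth")
        vd <- .applyBound(vd, dp, if (is.null(d$trio_low_mult)) NULL else
            d$trio_low_mult * trioStats$mean, "DPtrio", `<`, pol)
        vd <- .applyBound(vd, dp, if (is.null(d$trio_high_mult)) NULL else
            d$trio_high_mult * trioStats$mean, "DPtrio", `>`, pol)
    }
    if (!is.null(d$n_sigma)) {
        if (is.null(stats$sd))
            stop("sigma depth rule needs the individual depth sd")
        dev <- abs(dp - stats$mean)
        vd <- .applyBound(vd, dev, d$n_sigma * stats$sd, "DPsigma", `>`, pol)
    }
    if (!is.null(d$poisson_p)) {
        p <- poissonTwoSidedP(dp, stats$mean)
        if (identical(d$poisson_direction, "high"))
            vd <- .applyBound(vd, p, d$poisson_p, "DPpois", `>`, pol)
        else
            vd <- .applyBound(vd, p, d$poisson_p, "DPpois", `<`, pol)
    }
    .vdDone(vd)
}

## -- genotype quality -------------------------------------------------------

#' Genotype-quality filter (GQ or PL-gap mode)
#'
#' In GQ mode a call fails when \code{gq < gq_min[role]}. In PL-gap mode
#' the call fails when the difference between the second-smallest and the
#' smallest Phred-scaled genotype likelihood is below
#' \code{pl_gap_min[zygosity]} (PL gaps are not capped at 99, unlike GQ).
#' When both GQ and PL are missing the filter is not evaluable.
#'
#' @param gq numeric GQ vector (Phred, capped at 99 on input).
#' @param pl PL matrix (one row per call) or \code{NULL}.
#' @param role \code{"parent"} or \code{"child"} (GQ mode threshold lookup).
#' @param zygosity \code{"hom"}/\code{"het"} per call (PL mode threshold
#'   lookup).
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
genotypeQualityFilter <- function(gq, pl = NULL, role = "child",
                                  zygosity = NULL, config) {
    q <- config@gq
    pol <- config@missing_policy
    n <- length(gq)
    vd <- .vdNew(n)
    if (!is.null(q$gq_min)) {
        thr <- q$gq_min[[role]]
        vd <- .applyBound(vd, gq, thr, paste0("GQ.", role), `<`, pol)
    } else if (!is.null(q$pl_gap_min)) {
        if (is.null(pl) || is.null(zygosity))
            stop("PL-gap mode needs pl and zygosity")
        gap <- .plGap(pl)
        thr <- unname(q$pl_gap_min[zygosity])
        miss <- is.na(gap) | is.na(thr)
        vd <- .vdMissing(vd, miss, "PLgap", pol)
        bad <- !miss & gap < thr
        if (any(bad))
            vd <- .vdFail(vd, bad, paste0("PLgap=", .fmt(gap[bad]), "<",
                                          .fmt(thr[bad])))
    }
    .vdDone(vd)
}

## second-smallest minus smallest PL per row
.plGap <- function(pl) {
    if (ncol(pl) == 3) {
        a <- pl[, 1]; b <- pl[, 2]; c <- pl[, 3]
        mn <- pmin(a, b, c)
        (a + b + c) - mn - pmax(a, b, c) - mn
    } else {
        apply(pl, 1, function(r) {
            r <- r[!is.na(r)]
            if (length(r) < 2) return(NA_real_)
            s <- sort(r)
            s[2] - s[1]
        })
    }
}

## -- parental allelic depth -------------------------------------------------

#' Parental alternative-allele read filter
#'
#' A parent call fails when the number of reads supporting the candidate
#' alternative allele exceeds \code{parent_ad_max} (so
#' \code{parent_ad_max = 0} forbids any alt-supporting read), or when the
#' count of alternative alleles among low-quality reads exceeds
#' \code{lowq_ad_alt_max}.
#'
#' @param ad allelic-depth matrix (REF first) for the parent.
#' @param altIndex 1-based alt-allele index per call (1 = first ALT).
#' @param lowqAdAlt optional low-quality alt-read counts.
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
parentAlleleFilter <- function(ad, altIndex, lowqAdAlt = NULL, config) {
    pa <- config@parent_allele
    pol <- config@missing_policy
    n <- nrow(ad)
    vd <- .vdNew(n)
    if (!is.null(pa$parent_ad_max)) {
        adAlt <- ad[cbind(seq_len(n), altIndex + 1L)]
        vd <- .applyBound(vd, adAlt, pa$parent_ad_max, "parentAD", `>`, pol)
    }
    if (!is.null(pa$lowq_ad_alt_max)) {
        if (is.null(lowqAdAlt)) lowqAdAlt <- rep(NA_real_, n)
        vd <- .applyBound(vd, lowqAdAlt, pa$lowq_ad_alt_max, "lowqAD", `>`,
                          pol)
    }
    .vdDone(vd)
}

## -- allelic balance --------------------------------------------------------

#' Allelic balance of a call
#'
#' Fraction of reads supporting the alternative allele among reads
#' supporting either the reference or that alternative allele:
#' \code{ad[alt] / (ad[ref] + ad[alt])}. \code{NaN} when no informative
#' read exists (callers route this to not-evaluable).
#'
#' @param ad allelic-depth matrix (REF first).
#' @param altIndex 1-based alt-allele index per call.
#' @return numeric vector in [0, 1] (or \code{NaN}/\code{NA}).
#' @export
allelicBalance <- function(ad, altIndex) {
    n <- nrow(ad)
    adAlt <- ad[cbind(seq_len(n), altIndex + 1L)]
    adRef <- ad[, 1]
    tot <- adRef + adAlt
    out <- adAlt / tot
    out[!is.na(tot) & tot == 0] <- NaN
    out
}

#' Allelic-balance filter (window or exact binomial mode)
#'
#' Window mode fails calls with AB strictly outside
#' \code{[ab_min, ab_max]}. Binomial mode applies the two-sided exact
#' binomial test of \code{ad[alt]} successes in \code{ad[ref] + ad[alt]}
#' trials against p = 0.5 (doubled smaller tail, capped at 1) and fails
#' calls with p-value below \code{p_threshold}.
#'
#' @inheritParams allelicBalance
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
abFilter <- function(ad, altIndex, config) {
    a <- config@ab
    pol <- config@missing_policy
    n <- nrow(ad)
    vd <- .vdNew(n)
    if (length(a) == 0) return(.vdDone(vd))
    adAlt <- ad[cbind(seq_len(n), altIndex + 1L)]
    tot <- ad[, 1] + adAlt
    miss <- is.na(tot) | tot == 0
    vd <- .vdMissing(vd, miss, "AB", pol)
    if (identical(a$mode, "binomial")) {
        p <- binomTwoSidedP(adAlt, tot)
        bad <- !miss & p < a$p_threshold
        if (any(bad))
            vd <- .vdFail(vd, bad, paste0("ABbinom=", .fmt(p[bad]), "<",
                                          .fmt(a$p_threshold)))
    } else {
        ab <- adAlt / tot
        lo <- if (is.null(a$ab_min)) -Inf else a$ab_min
        hi <- if (is.null(a$ab_max)) Inf else a$ab_max
        bad <- !miss & (ab < lo | ab > hi)
        if (any(bad))
            vd <- .vdFail(vd, bad, paste0("AB=", .fmt(ab[bad]), "!in[",
                                          .fmt(lo), ",", .fmt(hi), "]"))
    }
    .vdDone(vd)
}

## -- strand -----------------------------------------------------------------

#' Alternative-allele strand-support filter
#'
#' When \code{both_strands} is set, a call fails unless the alternative
#' allele is seen on both the forward and the reverse strand. Unavailable
#' counts follow the missing policy; an unset flag passes everything.
#'
#' @param altFwd,altRev alt-supporting read counts per strand.
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
strandFilter <- function(altFwd, altRev, config) {
    n <- length(altFwd)
    vd <- .vdNew(n)
    if (isTRUE(config@strand$both_strands)) {
        miss <- is.na(altFwd) | is.na(altRev)
        vd <- .vdMissing(vd, miss, "strand", config@missing_policy)
        bad <- !miss & (altFwd == 0 | altRev == 0)
        if (any(bad))
            vd <- .vdFail(vd, bad, paste0("strand=", altFwd[bad], "/",
                                          altRev[bad]))
    }
    .vdDone(vd)
}

## -- clusters ---------------------------------------------------------------

#' Mutation-cluster filter
#'
#' Window rule: every candidate belonging to a same-chromosome run of at
#' least \code{max_in_window} candidates spanning at most \code{window_bp}
#' is removed. Pair rule: both members of any same-chromosome pair strictly
#' closer than \code{pair_min_distance_bp} are removed. Both rules are
#' evaluated on the original candidate set in one pass and their removals
#' unioned.
#'
#' @param chrom,pos candidate coordinates, sorted by (chrom, pos).
#' @param config a \code{FilterConfig}.
#' @return logical vector: \code{TRUE} for kept candidates.
#' @export
clusterFilter <- function(chrom, pos, config) {
    cl <- config@cluster
    n <- length(pos)
    keep <- rep(TRUE, n)
    if (n == 0 || length(cl) == 0) return(keep)
    if (!identical(order(chrom, pos), seq_along(pos)))
        stop("candidates must be sorted by (chrom, pos)")
    rm <- rep(FALSE, n)
    if (!is.null(cl$window_bp) && !is.null(cl$max_in_window)) {
        m <- cl$max_in_window
        if (n >= m) for (i in seq_len(n - m + 1)) {
            j <- i + m - 1L
            if (chrom[i] == chrom[j] && pos[j] - pos[i] <= cl$window_bp)
                rm[i:j] <- TRUE
        }
    }
    if (!is.null(cl$pair_min_distance_bp) && n >= 2) {
        d <- diff(pos)
        same <- chrom[-1] == chrom[-n]
        close <- same & d < cl$pair_min_distance_bp
        idx <- which(close)
        rm[idx] <- TRUE
        rm[idx + 1L] <- TRUE
    }
    !rm
}

## -- exclusion resources ----------------------------------------------------

#' Exclusion filter against other samples, population SNPs and region masks
#'
#' A candidate fails when its mutant allele is carried by any supplied
#' non-focal individual at that site, when its position is a known
#' population SNP, or when it lies inside any applied mask.
#'
#' @param chrom,pos,allele candidate coordinates and mutant allele.
#' @param otherCarriers optional data.frame (\code{chrom}, \code{pos},
#'   optionally \code{allele}) of sites where a configured non-focal
#'   individual carries the allele.
#' @param populationSnps optional data.frame (\code{chrom}, \code{pos}) of
#'   known polymorphic positions.
#' @param masks named list of \code{GRanges} masks; only those whose names
#'   appear in \code{config@exclusion$masks} are applied (all, when the
#'   config lists none but masks are supplied).
#' @param config a \code{FilterConfig}.
#' @return a \code{FilterVerdict}.
#' @export
exclusionFilter <- function(chrom, pos, allele = NULL, otherCarriers = NULL,
                            populationSnps = NULL, masks = list(), config) {
    n <- length(pos)
    vd <- .vdNew(n)
    key <- paste(chrom, pos)
    if (!is.null(otherCarriers) && nrow(otherCarriers) > 0) {
        okey <- paste(otherCarriers$chrom, otherCarriers$pos)
        if (!is.null(allele) && !is.null(otherCarriers$allele)) {
            key2 <- paste(key, allele)
            okey <- paste(okey, otherCarriers$allele)
            bad <- key2 %in% okey
        } else bad <- key %in% okey
        vd <- .vdFail(vd, bad, "otherSample")
    }
    if (!is.null(populationSnps) && nrow(populationSnps) > 0) {
        pkey <- paste(populationSnps$chrom, populationSnps$pos)
        vd <- .vdFail(vd, key %in% pkey, "populationSNP")
    }
    apply_masks <- masks
    lbls <- config@exclusion$masks
    if (!is.null(lbls) && length(masks))
        apply_masks <- masks[intersect(names(masks), lbls)]
    for (nm in names(apply_masks)) {
        bad <- inMask(apply_masks[[nm]], chrom, pos)
        vd <- .vdFail(vd, bad, paste0("mask:", nm))
    }
    .vdDone(vd)
}

## -- reference-derived homopolymer mask -------------------------------------

#' Build a homopolymer mask from a reference sequence
#'
#' Marks every run of at least \code{minRun} identical A or T bases,
#' expanded to the run's span, as masked.
#'
#' @param seq a character string (one chromosome's sequence) or named list
#'   of such strings.
#' @param minRun minimum run length (default 10).
#' @return a \code{GRanges} mask in 1-based coordinates.
#' @export
homopolymerMask <- function(seq, minRun = 10L) {
    if (!is.list(seq)) seq <- list(chr1 = seq)
    grs <- lapply(names(seq), function(ch) {
        m <- gregexpr(sprintf("A{%d,}|T{%d,}", minRun, minRun),
                      toupper(seq[[ch]]))[[1]]
        if (m[1] == -1) return(GenomicRanges::GRanges())
        GenomicRanges::GRanges(ch, IRanges::IRanges(
            start = as.integer(m),
            width = attr(m, "match.length")))
    })
    gr <- GenomicRanges::reduce(do.call(c, grs))
    S4Vectors::metadata(gr)$label <- "homopolymer"
    gr
}
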