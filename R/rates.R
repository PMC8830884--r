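## FDR estimation, corrections, the per-generation mutation rate, and the
## binomial study-design calculators.

#' FDR from PCR/Sanger validation counts
#'
#' FDR = failed / (validated + failed). Candidates that did not amplify are
#' excluded from both counts.
#'
#' @param validated candidates confirmed as true DNMs.
#' @param failed candidates that amplified but failed validation.
#' @return a \code{\linkS4class{FdrEstimate}}.
#' @examples
#' fdrFromValidation(33, 6)   # 6/39
#' @export
fdrFromValidation <- function(validated, failed) {
    if (validated + failed <= 0)
        stop("validated + failed must be positive; FDR undefined")
    new("FdrEstimate", value = failed / (validated + failed),
        method = "validation",
        basis = c(validated = validated, failed = failed))
}

#' FDR from deviation off the expected 50\% transmission rate
#'
#' Under the model that true DNMs transmit to the next generation at 50\%
#' and false positives never do, FDR = max(0, 1 - 2 transmitted/total).
#' Observed transmission at or above 50\% gives an FDR of 0.
#'
#' @param transmitted candidates observed in the third generation.
#' @param total candidates assessed.
#' @return a \code{\linkS4class{FdrEstimate}}.
#' @export
fdrFromTransmission <- function(transmitted, total) {
    if (total <= 0) stop("total must be positive")
    if (transmitted > total) stop("transmitted cannot exceed total")
    new("FdrEstimate", value = max(0, 1 - 2 * transmitted / total),
        method = "transmission",
        basis = c(transmitted = transmitted, total = total))
}

#' FP-corrected candidate count
#'
#' @param n raw candidate count.
#' @param fdr numeric FDR or an \code{FdrEstimate}.
#' @return \code{n * (1 - fdr)}.
#' @export
correctedCandidates <- function(n, fdr) {
    if (is(fdr, "FdrEstimate")) fdr <- fdr@value
    stopifnot(fdr >= 0, fdr <= 1)
    n * (1 - fdr)
}

#' Per-site per-generation germline mutation rate
#'
#' mu = n (1 - FDR) / (2 CG (1 - FNR)) for a diploid genome, with a
#' binomial confidence interval computed on the effective per-site
#' proportion (the corrected count over the corrected diploid denominator;
#' uncertainty in FDR and FNR themselves is not propagated).
#'
#' @param n raw candidate DNM count.
#' @param fdr numeric FDR or \code{FdrEstimate} (0 when no correction).
#' @param cg callable sites: numeric or \code{CallableResult}.
#' @param fnr numeric FNR or \code{FnrEstimate} (0 when no correction).
#' @param ciLevel confidence level (default 0.95).
#' @param ciMethod \code{"wilson"} (default; the score interval) or
#'   \code{"clopper-pearson"}.
#' @return a \code{\linkS4class{RateEstimate}}.
#' @examples
#' mutationRate(28, fdr = 0, cg = 2.2e9, fnr = 0.05)
#' @export
mutationRate <- function(n, fdr = 0, cg, fnr = 0, ciLevel = 0.95,
                         ciMethod = c("wilson", "clopper-pearson")) {
    ciMethod <- match.arg(ciMethod)
    components <- list()
    if (is(fdr, "FdrEstimate")) { components$fdr <- fdr; fdr <- fdr@value }
    if (is(fnr, "FnrEstimate")) { components$fnr <- fnr; fnr <- fnr@value }
    if (is(cg, "CallableResult")) { components$cg <- cg; cg <- cgSites(cg) }
    if (cg <= 0) stop("callable genome must be positive")
    if (fnr >= 1) stop("FNR of 1 leaves no detection power; rate undefined")
    effN <- n * (1 - fdr)
    denom <- 2 * cg * (1 - fnr)
    mu <- effN / denom
    ci <- rateConfidenceInterval(effN, denom, level = ciLevel,
                                 method = ciMethod)
    new("RateEstimate", mu = mu, nCandidates = n, fdr = fdr, fnr = fnr,
        cgSites = cg, ci = ci, ciLevel = ciLevel, ciMethod = ciMethod,
        components = components)
}

#' Binomial confidence interval for a per-site rate
#'
#' Wilson score interval (the default; well behaved for the very small
#' proportions a mutation rate is) or Clopper-Pearson exact interval for
#' the proportion \code{effectiveN / denominatorSites}, returned on the
#' per-site scale.
#'
#' @param effectiveN (possibly non-integer) event count.
#' @param denominatorSites number of sites (trials).
#' @param level confidence level in (0,1).
#' @param method \code{"wilson"} or \code{"clopper-pearson"}.
#' @return numeric(2): lower and upper bound.
#' @export
rateConfidenceInterval <- function(effectiveN, denominatorSites,
                                   level = 0.95,
                                   method = c("wilson", "clopper-pearson")) {
    method <- match.arg(method)
    if (denominatorSites <= 0) stop("denominatorSites must be positive")
    if (effectiveN > denominatorSites)
        stop("effectiveN cannot exceed denominatorSites")
    if (level <= 0 || level >= 1) stop("level must be in (0,1)")
    x <- effectiveN; n <- denominatorSites
    if (method == "wilson") {
        z <- stats::qnorm(1 - (1 - level) / 2)
        phat <- x / n
        den <- 1 + z^2 / n
        center <- (phat + z^2 / (2 * n)) / den
        half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
        c(max(0, center - half), min(1, center + half))
    } else {
        alpha <- 1 - level
        lo <- if (x <= 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
        hi <- if (x >= n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
        c(lo, hi)
    }
}

## ---------------------------------------------------------------------------
## Study-design calculators
## ---------------------------------------------------------------------------

#' Probability of allele dropout in a heterozygote
#'
#' Probability that none of \code{depth} reads samples one given allele of
#' a heterozygote: 0.5^depth. At 15x this is 3.05e-5, which across a
#' genome with a million heterozygous positions yields roughly 30
#' spuriously homozygous calls.
#'
#' @param depth read depth.
#' @return probability.
#' @export
alleleDropoutProbability <- function(depth) {
    stopifnot(all(depth >= 0))
    0.5^depth
}

#' Expected number of allele-dropout sites genome-wide
#'
#' @param depth read depth.
#' @param nHetSites number of heterozygous positions in the genome.
#' @return \code{nHetSites * 0.5^depth}.
#' @export
expectedDropoutSites <- function(depth, nHetSites) {
    stopifnot(all(nHetSites >= 0))
    nHetSites * alleleDropoutProbability(depth)
}

#' Probability a somatic variant leaks past a read-fraction threshold
#'
#' Probability that a mutation present in a fraction \code{cellFraction} of
#' cells is supported by at least \code{readFractionThreshold} of the reads
#' at a site: \code{P(X >= ceiling(threshold * depth))} with
#' \code{X ~ Binomial(depth, cellFraction)} (the variant-read fraction is
#' modelled as equal to the cell fraction).
#'
#' @param depth read depth.
#' @param cellFraction fraction of cells carrying the variant.
#' @param readFractionThreshold read-fraction threshold.
#' @return probability.
#' @examples
#' somaticLeakProbability(20, 0.10, 0.30)  # 0.0113
#' somaticLeakProbability(35, 0.10, 0.30)  # 0.0004
#' @export
somaticLeakProbability <- function(depth, cellFraction,
                                   readFractionThreshold) {
    stopifnot(cellFraction >= 0, cellFraction <= 1,
              readFractionThreshold >= 0, readFractionThreshold <= 1)
    k <- ceiling(readFractionThreshold * depth)
    stats::pbinom(k - 1, depth, cellFraction, lower.tail = FALSE)
}

#' Expected fraction of DNMs on a hom-alt parental background
#'
#' Approximates the fraction of true DNMs arising where both parents are
#' homozygous for the alternative allele by the sequence divergence to the
#' reference genome: at 2\% divergence, about 1 in 50 true DNMs sits on
#' such a background and is lost when the analysis keeps only
#' hom-ref x hom-ref configurations.
#'
#' @param divergence per-site divergence to the reference in [0,1].
#' @return the expected fraction (equal to \code{divergence}).
#' @export
altBackgroundFraction <- function(divergence) {
    stopifnot(divergence >= 0, divergence <= 1)
    divergence
}
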