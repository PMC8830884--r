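#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of sequenced individuals
#'
#' Holds one or more father--mother--offspring trios parsed from a 6-column
#' PED file, with a generation index computed from the parent links and an
#' optional age-at-conception column supplied by a sidecar table.
#'
#' @slot tab data.frame with columns \code{family}, \code{id}, \code{father},
#'   \code{mother}, \code{sex}, \code{phenotype}, \code{generation},
#'   \code{age_at_conception}. Unknown parents are \code{NA}.
#' @exportClass Pedigree
setClass("Pedigree", representation(tab = "data.frame"))

setValidity("Pedigree", function(object) {
    tb <- object@tab
    need <- c("family", "id", "father", "mother", "sex", "phenotype",
              "generation", "age_at_conception")
    if (!all(need %in% names(tb)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(tb)), collapse = ", ")))
    if (anyDuplicated(tb$id))
        return("duplicated individual ids")
    par <- c(tb$father, tb$mother)
    par <- par[!is.na(par)]
    if (!all(par %in% tb$id))
        return("parent ids that do not resolve to pedigree members")
    ## cycle check: generation assignment must have succeeded
    if (any(is.na(tb$generation)))
        return("cyclic parentage: generation indices could not be assigned")
    TRUE
})

## ---------------------------------------------------------------------------
## TrioGenotypes: columnar per-site records for a pedigree
## ---------------------------------------------------------------------------

#' Per-site multi-sample genotype records
#'
#' A columnar container for one genomic site per row with per-individual
#' calls (GT, DP, AD, GQ, PL, optional low-quality alt depth and per-strand
#' alt counts) and site-level annotations (QUAL, QD, MQ, FS, SOR and the
#' rank-sum statistics). Positions are 1-based. Absent annotations and
#' FORMAT subfields are stored as \code{NA}, never as 0.
#'
#' @slot chrom character chromosome per record.
#' @slot pos integer 1-based position per record.
#' @slot ref character reference allele per record.
#' @slot alt character alternative allele(s), comma-separated when
#'   multi-allelic.
#' @slot info data.frame of site annotations: \code{qual}, \code{qd},
#'   \code{mq}, \code{fs}, \code{sor}, \code{mq_rank_sum},
#'   \code{read_pos_rank_sum}, \code{base_q_rank_sum}.
#' @slot geno named list (one element per sample id); each element is a list
#'   with vectors \code{gt1}, \code{gt2} (allele indices, 0 = REF, NA =
#'   missing), \code{dp}, \code{gq}, \code{lowq_ad_alt} and matrices
#'   \code{ad} (one column per allele, REF first), \code{pl} (one column per
#'   diploid genotype) and \code{adf}/\code{adr} (per-allele forward/reverse
#'   depths, all-\code{NA} when strand information is unavailable).
#' @exportClass TrioGenotypes
setClass("TrioGenotypes",
         representation(chrom = "character", pos = "integer",
                        ref = "character", alt = "character",
                        info = "data.frame", geno = "list"))

setValidity("TrioGenotypes", function(object) {
    n <- length(object@pos)
    if (length(object@chrom) != n || length(object@ref) != n ||
        length(object@alt) != n)
        return("chrom/pos/ref/alt lengths differ")
    if (nrow(object@info) != n)
        return("info has wrong number of rows")
    if (n > 0 && any(object@pos < 1L))
        return("positions must be >= 1")
    if (n > 0 && (any(!nzchar(object@ref)) || any(!nzchar(object@alt))))
        return("alleles must be nonempty")
    infoNeed <- c("qual", "qd", "mq", "fs", "sor", "mq_rank_sum",
                  "read_pos_rank_sum", "base_q_rank_sum")
    if (!all(infoNeed %in% names(object@info)))
        return("info lacks required annotation columns")
    for (id in names(object@geno)) {
        g <- object@geno[[id]]
        for (f in c("gt1", "gt2", "dp", "gq"))
            if (length(g[[f]]) != n)
                return(sprintf("sample %s: field %s has wrong length", id, f))
        if (!is.matrix(g$ad) || nrow(g$ad) != n)
            return(sprintf("sample %s: ad must be a matrix with one row per site", id))
        if (!is.matrix(g$pl) || nrow(g$pl) != n)
            return(sprintf("sample %s: pl must be a matrix with one row per site", id))
        bad <- !is.na(g$dp) & rowSums(g$ad, na.rm = TRUE) > g$dp
        if (any(bad))
            return(sprintf("sample %s: sum(AD) exceeds DP at %d site(s)",
                           id, sum(bad)))
    }
    TRUE
})

## ---------------------------------------------------------------------------
## FilterConfig
## ---------------------------------------------------------------------------

#' Complete hard-filter threshold set
#'
#' Materialized configuration for every site-specific, sample-specific and
#' auxiliary filter. Built by \code{\link{filterPreset}} or
#' \code{\link{readFilterConfig}}. All threshold violations are strict:
#' values exactly at a bound pass.
#'
#' @slot preset character name of the preset this config was derived from,
#'   or \code{NA}.
#' @slot site list of site-annotation thresholds (\code{qual_min},
#'   \code{qd_min}, \code{mq_min}, \code{fs_max}, \code{sor_max}, and
#'   \code{*_rank_sum_window} two-element windows); \code{NULL} entries are
#'   unused filters.
#' @slot depth list: any configured subset of \code{dp_min}, \code{dp_max}
#'   (absolute), \code{low_mult}, \code{high_mult} (times the individual
#'   mean), \code{trio_low_mult}, \code{trio_high_mult} (times the trio
#'   mean), \code{n_sigma}, \code{poisson_p} (+ \code{poisson_direction}
#'   \code{"low"}/\code{"high"}) applies.
#' @slot gq list: \code{gq_min} named per role (\code{parent}, \code{child})
#'   or \code{pl_gap_min} named per zygosity (\code{hom}, \code{het}).
#' @slot parent_allele list: \code{parent_ad_max}, \code{lowq_ad_alt_max}.
#' @slot ab list: \code{mode} \code{"window"} or \code{"binomial"};
#'   \code{ab_min}, \code{ab_max} or \code{p_threshold}.
#' @slot strand list: \code{both_strands} flag.
#' @slot cluster list: \code{window_bp}, \code{max_in_window},
#'   \code{pair_min_distance_bp}.
#' @slot exclusion list: \code{use_population_snps}, \code{use_other_samples},
#'   \code{masks} (labels of masks to apply).
#' @slot violation_mode \code{"homref_config"}, \code{"all_configs"} or
#'   \code{"allele_absence"}.
#' @slot missing_policy \code{"pass"} or \code{"fail"}: what a filter does
#'   when the data it needs are missing.
#' @slot exclude_chroms character chromosomes dropped before detection
#'   (sex chromosomes by default).
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(preset = "character", site = "list", depth = "list",
                        gq = "list", parent_allele = "list", ab = "list",
                        strand = "list", cluster = "list", exclusion = "list",
                        violation_mode = "character",
                        missing_policy = "character",
                        exclude_chroms = "character"))

setValidity("FilterConfig", function(object) {
    ok01 <- function(x) is.null(x) || (x > 0 && x < 1)
    for (w in c("mq_rank_sum_window", "read_pos_rank_sum_window",
                "base_q_rank_sum_window")) {
        win <- object@site[[w]]
        if (!is.null(win) && (length(win) != 2 || win[1] > win[2]))
            return(sprintf("%s must be (low, high) with low <= high", w))
    }
    d <- object@depth
    for (m in c("low_mult", "high_mult", "trio_low_mult", "trio_high_mult",
                "n_sigma"))
        if (!is.null(d[[m]]) && d[[m]] <= 0)
            return(sprintf("depth$%s must be positive", m))
    if (!ok01(d$poisson_p))
        return("depth$poisson_p must be in (0,1)")
    if (!is.null(object@ab$p_threshold) && !ok01(object@ab$p_threshold))
        return("ab$p_threshold must be in (0,1)")
    if (!is.null(object@ab$ab_min) && !is.null(object@ab$ab_max) &&
        object@ab$ab_min > object@ab$ab_max)
        return("ab window must satisfy ab_min <= ab_max")
    if (!object@violation_mode %in%
        c("homref_config", "all_configs", "allele_absence"))
        return("unknown violation_mode")
    if (!object@missing_policy %in% c("pass", "fail"))
        return("missing_policy must be 'pass' or 'fail'")
    TRUE
})

## ---------------------------------------------------------------------------
## FilterVerdict (vectorized: one element per evaluated record/call)
## ---------------------------------------------------------------------------

#' Outcome of applying a filter (or filter family) to one or more calls
#'
#' Parallel vectors: \code{passed[i]} is \code{TRUE} iff no configured filter
#' failed on element i; \code{reasons[i]} lists every failed filter as
#' \code{"name=observed<threshold"} (semicolon-separated, \code{""} when
#' none); \code{notEvaluable[i]} names filters skipped for missing data.
#'
#' @exportClass FilterVerdict
setClass("FilterVerdict",
         representation(passed = "logical", reasons = "character",
                        notEvaluable = "character"))

setValidity("FilterVerdict", function(object) {
    n <- length(object@passed)
    if (length(object@reasons) != n || length(object@notEvaluable) != n)
        return("passed/reasons/notEvaluable lengths differ")
    if (any(object@passed != (object@reasons == "")))
        return("passed must be TRUE exactly when reasons is empty")
    TRUE
})

## ---------------------------------------------------------------------------
## Results
## ---------------------------------------------------------------------------

#' Callable-genome estimate
#' @slot cgSites numeric count (count-based) or expected count
#'   (probabilistic) of callable sites among those examined.
#' @slot nExamined numeric number of sites examined.
#' @slot method \code{"count_based"} or \code{"probabilistic"}.
#' @slot perChrom data.frame breakdown (may be empty).
#' @slot genomeSites total genome size the examined sites were sampled from
#'   (\code{NA} when the input was exhaustive).
#' @slot cgExtrapolated \code{cgSites/nExamined * genomeSites} when
#'   \code{genomeSites} is known, else \code{NA}.
#' @slot filters list snapshot of the thresholds applied.
#' @exportClass CallableResult
setClass("CallableResult",
         representation(cgSites = "numeric", nExamined = "numeric",
                        method = "character", perChrom = "data.frame",
                        genomeSites = "numeric", cgExtrapolated = "numeric",
                        filters = "list"))

setValidity("CallableResult", function(object) {
    if (object@cgSites < 0) return("cgSites must be >= 0")
    if (object@method == "count_based" && object@cgSites > object@nExamined)
        return("cgSites cannot exceed the number of sites examined")
    TRUE
})

#' False-negative-rate estimate
#' @slot value proportion in [0,1] of true DNMs expected to be missed.
#' @slot method one of \code{"spike_in"}, \code{"ab_closed_form"},
#'   \code{"ab_empirical"}, \code{"site_filter_proportion"},
#'   \code{"combined"}, \code{"fixed"}.
#' @slot nBasis number of simulated DNMs / heterozygous sites the estimate
#'   rests on.
#' @exportClass FnrEstimate
setClass("FnrEstimate",
         representation(value = "numeric", method = "character",
                        nBasis = "numeric"))
setValidity("FnrEstimate", function(object) {
    if (object@value < 0 || object@value > 1) return("value must be in [0,1]")
    TRUE
})

#' False-discovery-rate estimate
#' @slot value proportion in [0,1] of candidates expected to be false.
#' @slot method one of \code{"validation"}, \code{"manual_curation"},
#'   \code{"transmission"}, \code{"twin_discordance_input"}, \code{"fixed"}.
#' @slot basis named numeric vector of the counts behind the estimate.
#' @exportClass FdrEstimate
setClass("FdrEstimate",
         representation(value = "numeric", method = "character",
                        basis = "numeric"))
setValidity("FdrEstimate", function(object) {
    if (object@value < 0 || object@value > 1) return("value must be in [0,1]")
    TRUE
})

#' Per-site per-generation mutation-rate estimate
#'
#' mu = n (1 - FDR) / (2 CG (1 - FNR)), with a binomial confidence interval
#' on the effective per-site proportion.
#'
#' @slot mu mutations per site per generation.
#' @slot nCandidates raw candidate count.
#' @slot fdr,fnr the corrections applied (numeric values).
#' @slot cgSites callable sites used in the denominator.
#' @slot ci numeric(2) lower/upper bound on mu.
#' @slot ciLevel confidence level.
#' @slot ciMethod \code{"wilson"} or \code{"clopper-pearson"}.
#' @slot components list holding the full FdrEstimate / CallableResult /
#'   FnrEstimate objects when available.
#' @exportClass RateEstimate
setClass("RateEstimate",
         representation(mu = "numeric", nCandidates = "numeric",
                        fdr = "numeric", fnr = "numeric", cgSites = "numeric",
                        ci = "numeric", ciLevel = "numeric",
                        ciMethod = "character", components = "list"))
setValidity("RateEstimate", function(object) {
    if (object@mu < 0) return("mu must be >= 0")
    if (length(object@ci) != 2) return("ci must be (low, high)")
    eps <- 1e-12
    if (object@ci[1] > object@mu + eps || object@ci[2] < object@mu - eps)
        return("ci must contain the point estimate")
    TRUE
})

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' Ground-truth ledger of a simulated pedigree
#'
#' @slot tab data.frame with columns \code{pos}, \code{kind} (one of
#'   \code{dnm}, \code{somatic}, \code{forced_het}, \code{alt_background}),
#'   \code{parent_of_origin}, \code{allele}, \code{cell_fraction},
#'   \code{transmitted}.
#' @slot genomeLength simulated genome length in sites.
#' @slot nBackgroundEmitted number of monomorphic hom-ref background sites
#'   materialized into records (a uniform sample of the non-variant genome).
#' @slot config list snapshot of the simulation parameters.
#' @exportClass SimTruth
setClass("SimTruth",
         representation(tab = "data.frame", genomeLength = "numeric",
                        nBackgroundEmitted = "numeric", config = "list"))

setValidity("SimTruth", function(object) {
    tb <- object@tab
    if (nrow(tb) > 0) {
        if (any(tb$pos < 1 | tb$pos > object@genomeLength))
            return("truth positions outside [1, genome_length]")
        dn <- tb$pos[tb$kind == "dnm"]
        so <- tb$pos[tb$kind == "somatic"]
        if (length(intersect(dn, so)) > 0)
            return("DNM and somatic positions must be distinct")
    }
    TRUE
})
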