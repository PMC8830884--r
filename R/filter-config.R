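## FilterConfig construction, named presets, YAML config files.

.GATK_SITE <- list(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0, sor_max = 3.0,
                   mq_rank_sum_window = c(-12.5, Inf),
                   read_pos_rank_sum_window = c(-8.0, Inf))

#' Build a fully materialized filter configuration
#'
#' Every threshold left unset disables the corresponding filter. Violations
#' are strict inequalities: a value exactly at a bound passes.
#'
#' @param site,depth,gq,parent_allele,ab,strand,cluster,exclusion lists of
#'   thresholds; see \code{\linkS4class{FilterConfig}} for the recognised
#'   keys.
#' @param violation_mode Mendelian-violation definition:
#'   \code{"homref_config"} (both parents 0/0, child 0/1; the usual
#'   restriction), \code{"all_configs"} (also 1/1 x 1/1 -> 0/1 and
#'   0/0 x 1/1 -> 0/0 or 1/1) or \code{"allele_absence"} (any child allele
#'   carried by neither parent; admits multi-allelic sites).
#' @param missing_policy what a filter does when its datum is missing:
#'   \code{"pass"} records the filter as not evaluable, \code{"fail"}
#'   removes the call.
#' @param exclude_chroms chromosomes dropped before detection; sex
#'   chromosomes by default.
#' @param preset name recorded for provenance.
#' @return a \code{\linkS4class{FilterConfig}}.
#' @export
filterConfig <- function(site = list(), depth = list(), gq = list(),
                         parent_allele = list(), ab = list(),
                         strand = list(), cluster = list(),
                         exclusion = list(),
                         violation_mode = "homref_config",
                         missing_policy = "pass",
                         exclude_chroms = c("X", "Y", "chrX", "chrY"),
                         preset = NA_character_) {
    if (is.null(ab$mode) && length(ab))
        ab$mode <- if (!is.null(ab$p_threshold)) "binomial" else "window"
    if (is.null(depth$poisson_direction) && !is.null(depth$poisson_p))
        depth$poisson_direction <- "low"
    new("FilterConfig", preset = as.character(preset), site = site,
        depth = depth, gq = gq, parent_allele = parent_allele, ab = ab,
        strand = strand, cluster = cluster, exclusion = exclusion,
        violation_mode = violation_mode, missing_policy = missing_policy,
        exclude_chroms = exclude_chroms)
}

#' Named filter presets of the five concordance-study pipelines
#'
#' Returns the fully materialized configuration used by each research group
#' in the five-pipeline rhesus-macaque comparison, plus the plain GATK
#' hard-filter recommendation (\code{"gatk_default"}: site filters only).
#'
#' \itemize{
#'   \item \code{CV}: GATK site set; depth 0.5x-2x the individual mean;
#'     GQ >= 40; parent alt AD <= 0; AB in (0.25, 0.75).
#'   \item \code{RW}: GATK site set; 20 <= DP <= 80; GQ >= 20; parent alt
#'     AD <= 0; AB >= 0.35; alternative allele required on both strands.
#'   \item \code{TT}: repeat/homopolymer/LCR masks; DP >= 10; GQ >= 20;
#'     parent alt AD <= 0; AB >= 0.25; allele-absence violation mode.
#'   \item \code{LB}: stringent site set (QD 2, FS 20, MQ 40, MQRankSum in
#'     (-2, 4), ReadPosRankSum in (-3, 3), SOR 3); depth 0.5x-2x individual
#'     mean; GQ >= 60; no AD filter; AB in (0.3, 0.7).
#'   \item \code{SB}: rank-sum site set (FS 30, MQRankSum (-10, 10),
#'     ReadPosRankSum (-2.5, 2.5), BaseQRankSum (-13, 13)); DP >= 10 and
#'     <= 2x individual mean; GQ >= 55; parent alt AD <= 0; AB >= 0.3;
#'     alternative allele on both strands; low-quality alt reads <= 1.
#' }
#'
#' @param name one of \code{"gatk_default"}, \code{"CV"}, \code{"RW"},
#'   \code{"TT"}, \code{"LB"}, \code{"SB"}.
#' @return a \code{\linkS4class{FilterConfig}}.
#' @examples
#' filterPreset("LB")@ab
#' @export
filterPreset <- function(name) {
    presets <- c("gatk_default", "CV", "RW", "TT", "LB", "SB")
    if (!name %in% presets)
        stop("unknown preset '", name, "'; available: ",
             paste(presets, collapse = ", "))
    cfg <- switch(name,
        gatk_default = filterConfig(site = .GATK_SITE),
        CV = filterConfig(
            site = .GATK_SITE,
            depth = list(low_mult = 0.5, high_mult = 2),
            gq = list(gq_min = c(parent = 40, child = 40)),
            parent_allele = list(parent_ad_max = 0),
            ab = list(mode = "window", ab_min = 0.25, ab_max = 0.75)),
        RW = filterConfig(
            site = .GATK_SITE,
            depth = list(dp_min = 20, dp_max = 80),
            gq = list(gq_min = c(parent = 20, child = 20)),
            parent_allele = list(parent_ad_max = 0),
            ab = list(mode = "window", ab_min = 0.35, ab_max = 1),
            strand = list(both_strands = TRUE)),
        TT = filterConfig(
            depth = list(dp_min = 10),
            gq = list(gq_min = c(parent = 20, child = 20)),
            parent_allele = list(parent_ad_max = 0),
            ab = list(mode = "window", ab_min = 0.25, ab_max = 1),
            exclusion = list(masks = c("repeat", "homopolymer", "LCR")),
            violation_mode = "allele_absence"),
        LB = filterConfig(
            site = list(qd_min = 2.0, fs_max = 20.0, mq_min = 40.0,
                        mq_rank_sum_window = c(-2.0, 4.0),
                        read_pos_rank_sum_window = c(-3.0, 3.0),
                        sor_max = 3.0),
            depth = list(low_mult = 0.5, high_mult = 2),
            gq = list(gq_min = c(parent = 60, child = 60)),
            parent_allele = list(),
            ab = list(mode = "window", ab_min = 0.3, ab_max = 0.7)),
        SB = filterConfig(
            site = list(fs_max = 30.0,
                        mq_rank_sum_window = c(-10, 10),
                        read_pos_rank_sum_window = c(-2.5, 2.5),
                        base_q_rank_sum_window = c(-13, 13)),
            depth = list(dp_min = 10, high_mult = 2),
            gq = list(gq_min = c(parent = 55, child = 55)),
            parent_allele = list(parent_ad_max = 0, lowq_ad_alt_max = 1),
            ab = list(mode = "window", ab_min = 0.3, ab_max = 1),
            strand = list(both_strands = TRUE)))
    cfg@preset <- name
    cfg
}

#' Read a filter configuration from a YAML file
#'
#' The file may name a \code{preset:}; explicit keys override the preset's
#' values section by section (key level, so e.g. setting only
#' \code{ab: {ab_min: 0.2}} keeps the preset's \code{ab_max}).
#'
#' @param path path to a YAML file with sections \code{site}, \code{depth},
#'   \code{gq}, \code{parent_allele}, \code{ab}, \code{strand},
#'   \code{cluster}, \code{exclusion}, and scalar keys
#'   \code{violation_mode}, \code{missing_policy}, \code{preset}.
#' @return a \code{\linkS4class{FilterConfig}}.
#' @export
readFilterConfig <- function(path) {
    y <- yaml::read_yaml(path)
    base <- if (!is.null(y$preset)) filterPreset(y$preset)
            else filterConfig()
    sect <- c("site", "depth", "gq", "parent_allele", "ab", "strand",
              "cluster", "exclusion")
    for (s in sect) {
        if (is.null(y[[s]])) next
        cur <- slot(base, s)
        for (k in names(y[[s]])) cur[[k]] <- .coerceCfgVal(s, k, y[[s]][[k]])
        slot(base, s) <- cur
    }
    for (s in c("violation_mode", "missing_policy"))
        if (!is.null(y[[s]])) slot(base, s) <- y[[s]]
    if (!is.null(y$exclude_chroms))
        base@exclude_chroms <- as.character(y$exclude_chroms)
    validObject(base)
    base
}

.coerceCfgVal <- function(section, key, val) {
    if (section == "gq" && key %in% c("gq_min", "pl_gap_min"))
        return(unlist(val))
    if (grepl("_window$", key)) return(as.numeric(unlist(val)))
    if (key == "masks") return(as.character(unlist(val)))
    val
}
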