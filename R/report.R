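## Concordance, spectrum, transmission and standardized-report utilities.

#' Membership-pattern overlap counts across call sets
#'
#' Exact count of candidate keys per nonempty membership pattern (the
#' numbers behind an upset plot). Patterns with zero count are omitted and
#' the counts sum to the size of the union.
#'
#' @param collection named list of character key vectors (e.g.
#'   \code{"chrom:pos:alt"}), one per pipeline.
#' @return data.frame with columns \code{pattern} (set names joined by
#'   \code{"+"}) and \code{count}, ordered by decreasing count.
#' @examples
#' overlapCounts(list(A = c("k1", "k2"), B = c("k2", "k3")))
#' @export
overlapCounts <- function(collection) {
    if (length(collection) < 2)
        stop("need at least two call sets")
    keys <- unique(unlist(collection))
    member <- vapply(collection, function(s) keys %in% s,
                     logical(length(keys)))
    if (is.null(dim(member))) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1, function(r)
        paste(names(collection)[r], collapse = "+"))
    tab <- table(pattern)
    out <- data.frame(pattern = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE)
    out[order(-out$count, out$pattern), , drop = FALSE]
}

#' Classify a single-nucleotide substitution
#'
#' A<->G and C<->T are transitions; every other change is a transversion.
#'
#' @param ref,alt single-nucleotide alleles.
#' @return character vector \code{"transition"} / \code{"transversion"}.
#' @export
classifySubstitution <- function(ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    if (!all(ref %in% .BASES) || !all(alt %in% .BASES))
        stop("alleles must be single A/C/G/T bases")
    if (any(ref == alt)) stop("ref and alt must differ")
    ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
        (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
    ifelse(ti, "transition", "transversion")
}

#' Transition-to-transversion ratio of a candidate set
#'
#' @param ref,alt substitution alleles.
#' @return count(transitions) / count(transversions); \code{NA} (with the
#'   raw counts as attributes) when there is no transversion.
#' @export
titvRatio <- function(ref, alt) {
    cls <- classifySubstitution(ref, alt)
    ti <- sum(cls == "transition"); tv <- sum(cls == "transversion")
    out <- if (tv == 0) NA_real_ else ti / tv
    attr(out, "ti") <- ti
    attr(out, "tv") <- tv
    out
}

#' Strand-collapsed mutation spectrum
#'
#' Counts substitutions in the six pyrimidine-rooted classes (purine-rooted
#' changes are mapped to their reverse complement). When 3-mer reference
#' contexts are supplied, C>* changes at CpG sites (and their G>* strand
#' mates preceded by C) are additionally counted.
#'
#' @param ref,alt substitution alleles.
#' @param context optional 3-mer reference context centred on the site.
#' @return list with \code{counts} (named integer, six classes),
#'   \code{cpg} (count of CpG-context mutations, or \code{NA} when no
#'   context given) and \code{cpg_fraction}.
#' @export
mutationSpectrum <- function(ref, alt, context = NULL) {
    ref <- toupper(ref); alt <- toupper(alt)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    isPur <- ref %in% c("A", "G")
    cref <- ifelse(isPur, comp[ref], ref)
    calt <- ifelse(isPur, comp[alt], alt)
    classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    cls <- paste0(cref, ">", calt)
    if (!all(cls %in% classes)) stop("invalid substitution")
    counts <- table(factor(cls, levels = classes))
    cpg <- NA_integer_; cpgFrac <- NA_real_
    if (!is.null(context)) {
        context <- toupper(context)
        isCpG <- (ref == "C" & substr(context, 3, 3) == "G") |
            (ref == "G" & substr(context, 1, 1) == "C")
        cpg <- sum(isCpG)
        cpgFrac <- cpg / length(ref)
    }
    list(counts = counts, cpg = cpg, cpg_fraction = cpgFrac)
}

#' Transmission statistics from counts
#'
#' Rate of transmission to the next generation with exact binomial
#' p-values against the Mendelian expectation of 50\% (both the one-sided
#' smaller tail and the doubled two-sided value are reported, since both
#' conventions appear in the literature).
#'
#' @param transmitted,total counts.
#' @return list: \code{transmitted}, \code{total}, \code{rate},
#'   \code{p_one_sided}, \code{p_two_sided}.
#' @export
transmissionStats <- function(transmitted, total) {
    if (total <= 0) stop("no candidates assessed for transmission")
    p1 <- min(stats::pbinom(transmitted, total, 0.5),
              stats::pbinom(transmitted - 1, total, 0.5,
                            lower.tail = FALSE))
    list(transmitted = transmitted, total = total,
         rate = transmitted / total,
         p_one_sided = p1,
         p_two_sided = binomTwoSidedP(transmitted, total))
}

#' Transmission of candidate DNMs to a third generation
#'
#' Counts how many candidates appear in the grandchild, either by genotype
#' (the grandchild is called heterozygous with the mutant allele) or by
#' read support (at least \code{minAltReads} grandchild reads carry it).
#'
#' @param candidates candidate data.frame from \code{\link{runPipeline}}.
#' @param records \code{TrioGenotypes} including the grandchild sample.
#' @param grandchild grandchild sample id.
#' @param definition \code{"genotype"} or \code{"read_support"}.
#' @param minAltReads read-support threshold.
#' @return as \code{\link{transmissionStats}}.
#' @export
transmissionSummary <- function(candidates, records,
                                grandchild = "grandchild",
                                definition = c("genotype", "read_support"),
                                minAltReads = 1L) {
    definition <- match.arg(definition)
    g <- sampleCalls(records, grandchild)
    row <- match(paste(candidates$chrom, candidates$pos),
                 paste(records@chrom, records@pos))
    ok <- !is.na(row)
    if (!any(ok)) stop("no candidate sites present in the grandchild records")
    row <- row[ok]
    aidx <- candidates$allele_index[ok]
    if (definition == "genotype") {
        hit <- (!is.na(g$gt1[row]) & g$gt1[row] == aidx) |
            (!is.na(g$gt2[row]) & g$gt2[row] == aidx)
    } else {
        adMut <- g$ad[cbind(row, aidx + 1L)]
        hit <- !is.na(adMut) & adMut >= minAltReads
    }
    transmissionStats(sum(hit), length(hit))
}

#' One-filter-at-a-time sweep
#'
#' Re-runs the pipeline varying one filter family at a time from a base
#' configuration and reports, per setting, the candidate count, false
#' positives against the simulation truth, the callable genome, the
#' AB-filter FNR and the resulting mutation rate.
#'
#' @param records simulated \code{TrioGenotypes}.
#' @param truth matching \code{SimTruth}.
#' @param trio trio id list.
#' @param baseConfig base \code{FilterConfig}.
#' @param grid named list: filter family (slot name) -> named list of
#'   settings, each the full replacement list for that section. A setting
#'   touching several families is rejected.
#' @param includeBase prepend a row for the unmodified base config.
#' @return data.frame (family, setting, n_candidates, n_false_positives,
#'   cg_sites, fnr, mu).
#' @export
filterSweep <- function(records, truth, trio, baseConfig, grid,
                        includeBase = TRUE) {
    fams <- c("site", "depth", "gq", "parent_allele", "ab", "strand",
              "cluster", "exclusion")
    if (!all(names(grid) %in% fams))
        stop("grid families must be filter sections: ",
             paste(setdiff(names(grid), fams), collapse = ", "))
    truthKeys <- with(truthTable(truth)[truthTable(truth)$kind == "dnm", ],
                      paste(pos, allele))
    tt <- truthTable(truth)
    het <- tt[tt$kind == "forced_het", , drop = FALSE]
    hetRow <- match(het$pos, records@pos)
    chAd <- sampleCalls(records, trio$child)$ad

    evalOne <- function(family, setting, cfg) {
        res <- runPipeline(records, trio, cfg)
        cand <- res$candidates
        nfp <- sum(!(paste(cand$pos, cand$alt) %in% truthKeys))
        cg <- callableGenomeCount(records, trio, cfg,
                                  genomeSites = genomeLength(truth))
        fnr <- if (length(hetRow) && length(cfg@ab))
            fnrAb(chAd[hetRow, 1], chAd[hetRow, 2], cfg)@value else 0
        n <- nrow(cand)
        mu <- if (cgSites(cg) > 0 && fnr < 1)
            mutationRate(n, fdr = if (n > 0) nfp / n else 0, cg = cg,
                         fnr = fnr)@mu else NA_real_
        data.frame(family = family, setting = setting, n_candidates = n,
                   n_false_positives = nfp, cg_sites = cgSites(cg),
                   fnr = fnr, mu = mu, stringsAsFactors = FALSE)
    }
    rows <- list()
    if (includeBase)
        rows[["base"]] <- evalOne("base", "base", baseConfig)
    for (fam in names(grid)) {
        for (s in names(grid[[fam]])) {
            cfg <- baseConfig
            slot(cfg, fam) <- grid[[fam]][[s]]
            validObject(cfg)
            rows[[paste(fam, s)]] <- evalOne(fam, s, cfg)
        }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Standardized run report
#'
#' Assembles the reporting checklist for a DNM study into one structured
#' document: filters and thresholds, per-stage candidate accounting, FDR /
#' callable-genome / FNR methods and values, ti/tv, spectrum, CpG
#' percentage, transmission, and AB distributions. Sections without data
#' read \code{"not reported"} rather than being omitted.
#'
#' @param pipeline result list of \code{\link{runPipeline}}.
#' @param config the \code{FilterConfig} used.
#' @param rate optional \code{RateEstimate}.
#' @param fdr,cg,fnr optional estimate objects (taken from \code{rate}'s
#'   components when present there).
#' @param transmission optional \code{\link{transmissionStats}} result.
#' @param abTrueHets optional numeric vector of AB at true heterozygous
#'   sites.
#' @param context optional 3-mer contexts for the final candidates (CpG
#'   reporting).
#' @return nested list (serialize with \code{\link{writeStandardizedReport}}).
#' @export
standardizedReport <- function(pipeline, config, rate = NULL, fdr = NULL,
                               cg = NULL, fnr = NULL, transmission = NULL,
                               abTrueHets = NULL, context = NULL) {
    nr <- "not reported"
    cand <- pipeline$candidates
    if (!is.null(rate)) {
        comp <- rate@components
        if (is.null(fdr)) fdr <- comp$fdr
        if (is.null(cg)) cg <- comp$cg
        if (is.null(fnr)) fnr <- comp$fnr
    }
    specOut <- if (nrow(cand) > 0) {
        sp <- mutationSpectrum(cand$ref, cand$alt, context)
        tv <- titvRatio(cand$ref, cand$alt)
        list(titv = if (is.na(tv)) "undefined (no transversion)"
             else as.numeric(tv),
             ti = attr(tv, "ti"), tv = attr(tv, "tv"),
             spectrum = as.list(sp$counts),
             cpg_percent = if (is.na(sp$cpg_fraction)) "not computed"
             else 100 * sp$cpg_fraction)
    } else list(titv = nr, spectrum = nr, cpg_percent = nr)
    list(
        filters = list(
            preset = config@preset, site = config@site,
            depth = config@depth, genotype_quality = config@gq,
            parent_allele = config@parent_allele, ab = config@ab,
            strand = config@strand, cluster = config@cluster,
            exclusion = config@exclusion,
            violation_mode = config@violation_mode,
            missing_policy = config@missing_policy),
        candidates_after_each_filter = pipeline$accounting,
        n_final_candidates = nrow(cand),
        fdr = if (is.null(fdr)) nr else
            list(method = fdr@method, value = fdr@value,
                 basis = as.list(fdr@basis)),
        callable_genome = if (is.null(cg)) nr else
            list(method = cg@method, cg_sites = cgSites(cg),
                 n_examined = cg@nExamined),
        fnr = if (is.null(fnr)) nr else
            list(method = fnr@method, value = fnr@value,
                 n_basis = fnr@nBasis),
        mutation_rate = if (is.null(rate)) nr else
            list(mu = rate@mu, ci = rate@ci, ci_level = rate@ciLevel,
                 ci_method = rate@ciMethod),
        spectrum = specOut,
        transmission = if (is.null(transmission)) nr else transmission,
        ab_distributions = list(
            true_heterozygotes = if (is.null(abTrueHets)) nr else
                summary(abTrueHets),
            final_candidates = if (nrow(cand) > 0)
                summary(cand$ab_child) else nr))
}

#' Serialize a standardized report
#'
#' @param report list from \code{\link{standardizedReport}}.
#' @param path output path.
#' @param format \code{"json"} or \code{"markdown"}.
#' @export
writeStandardizedReport <- function(report, path,
                                    format = c("json", "markdown")) {
    format <- match.arg(format)
    if (format == "json") {
        jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                             force = TRUE, null = "null", na = "string")
    } else {
        lines <- c("# DNM run report", "")
        dump <- function(x, depth = 0) {
            pre <- strrep("  ", depth)
            for (nm in names(x)) {
                v <- x[[nm]]
                if (is.list(v) && !is.data.frame(v)) {
                    lines <<- c(lines, paste0(pre, "- **", nm, "**:"))
                    dump(v, depth + 1)
                } else {
                    if (is.data.frame(v))
                        v <- paste(utils::capture.output(print(v)),
                                   collapse = "; ")
                    lines <<- c(lines, paste0(pre, "- ", nm, ": ",
                                              paste(format(v),
                                                    collapse = ", ")))
                }
            }
        }
        dump(report)
        writeLines(lines, path)
    }
    invisible(path)
}
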