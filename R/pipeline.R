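## Mendelian-violation detection and the ordered filter stack.

.altAlleleList <- function(x) strsplit(x@alt, ",", fixed = TRUE)

#' Detect Mendelian violations in trio genotype records
#'
#' Emits one candidate per record whose offspring genotype cannot be
#' explained by inheritance, under the configured violation mode:
#' \describe{
#'   \item{homref_config}{both parents 0/0 and child 0/1 (the usual
#'     restriction).}
#'   \item{all_configs}{additionally 1/1 x 1/1 -> 0/1 and 0/0 x 1/1 ->
#'     0/0 or 1/1.}
#'   \item{allele_absence}{any child allele carried by neither parent;
#'     handles multi-allelic sites.}
#' }
#' Records with a missing child genotype are skipped and counted (attribute
#' \code{n_skipped}); violations are only asserted where both parental
#' genotypes are present.
#'
#' @param records a \code{TrioGenotypes}.
#' @param trio list with \code{father}, \code{mother}, \code{child} ids
#'   (see \code{\link{resolveTrio}}).
#' @param config a \code{FilterConfig}.
#' @return data.frame of candidates: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (mutant allele), \code{allele_index} (0 = REF),
#'   \code{child}, \code{background}, \code{idx} (row in \code{records}).
#' @export
detectViolations <- function(records, trio, config) {
    f <- sampleCalls(records, trio$father)
    m <- sampleCalls(records, trio$mother)
    c_ <- sampleCalls(records, trio$child)
    n <- length(records)
    childMiss <- is.na(c_$gt1) | is.na(c_$gt2)
    parentMiss <- is.na(f$gt1) | is.na(f$gt2) | is.na(m$gt1) | is.na(m$gt2)
    ok <- !childMiss & !parentMiss

    mode <- config@violation_mode
    idx <- integer(0); aidx <- integer(0); bg <- character(0)
    isHomRef <- function(g) g$gt1 == 0L & g$gt2 == 0L
    isHomAlt <- function(g) g$gt1 == 1L & g$gt2 == 1L
    isHet01 <- function(g) g$gt1 == 0L & g$gt2 == 1L

    if (mode %in% c("homref_config", "all_configs")) {
        hit <- ok & isHomRef(f) & isHomRef(m) & isHet01(c_)
        idx <- which(hit); aidx <- rep(1L, length(idx))
        bg <- rep("homref", length(idx))
        if (mode == "all_configs") {
            hit2 <- ok & isHomAlt(f) & isHomAlt(m) & isHet01(c_)
            idx <- c(idx, which(hit2))
            aidx <- c(aidx, rep(0L, sum(hit2)))
            bg <- c(bg, rep("homalt", sum(hit2)))
            cross <- ok & ((isHomRef(f) & isHomAlt(m)) |
                           (isHomAlt(f) & isHomRef(m)))
            hit3 <- cross & isHomRef(c_)      # alt allele lost: mutant is REF
            hit4 <- cross & isHomAlt(c_)      # ref allele lost: mutant is ALT
            idx <- c(idx, which(hit3), which(hit4))
            aidx <- c(aidx, rep(0L, sum(hit3)), rep(1L, sum(hit4)))
            bg <- c(bg, rep("mixed", sum(hit3) + sum(hit4)))
        }
    } else {  # allele_absence
        parAll <- cbind(f$gt1, f$gt2, m$gt1, m$gt2)
        novel1 <- ok & !(c_$gt1 == parAll[, 1] | c_$gt1 == parAll[, 2] |
                         c_$gt1 == parAll[, 3] | c_$gt1 == parAll[, 4])
        novel2 <- ok & !(c_$gt2 == parAll[, 1] | c_$gt2 == parAll[, 2] |
                         c_$gt2 == parAll[, 3] | c_$gt2 == parAll[, 4])
        hit <- novel1 | novel2
        idx <- which(hit)
        aidx <- ifelse(novel1[idx], c_$gt1[idx], c_$gt2[idx])
        bg <- rep("allele_absence", length(idx))
    }

    ord <- order(records@chrom[idx], records@pos[idx])
    idx <- idx[ord]; aidx <- aidx[ord]; bg <- bg[ord]
    altList <- .altAlleleList(records)[idx]
    alleleStr <- mapply(function(al, a) {
        if (a == 0L) NA_character_ else al[a]
    }, altList, aidx, USE.NAMES = FALSE)
    if (length(idx)) {
        mut <- ifelse(aidx == 0L, records@ref[idx],
                      as.character(alleleStr))
    } else mut <- character(0)
    out <- data.frame(chrom = records@chrom[idx], pos = records@pos[idx],
                      ref = records@ref[idx], alt = mut,
                      allele_index = aidx,
                      child = rep(trio$child, length(idx)),
                      background = bg, idx = idx,
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- sum(childMiss)
    out
}

## join a member-prefixed verdict into the candidate verdict accumulator
.joinVerdict <- function(acc, v, prefix) {
    re <- v@reasons
    has <- re != ""
    if (any(has)) {
        tag <- paste0(prefix, ":", re[has])
        sep <- ifelse(acc$re[has] == "", "", ";")
        acc$re[has] <- paste0(acc$re[has], sep, tag)
    }
    ne <- v@notEvaluable
    hasNe <- ne != ""
    if (any(hasNe)) {
        tag <- paste0(prefix, ":", ne[hasNe])
        sep <- ifelse(acc$ne[hasNe] == "", "", ";")
        acc$ne[hasNe] <- paste0(acc$ne[hasNe], sep, tag)
    }
    acc
}

#' Run the full DNM-calling filter stack
#'
#' Applies, in a fixed order, chromosome/SNV restriction, the site filters,
#' Mendelian-violation detection, and the per-sample and auxiliary filters
#' (depth on all trio members; genotype quality on all members; parental
#' alternative-allele reads; offspring allelic balance; strand support;
#' exclusion against other samples / population SNPs / masks; and the
#' mutation-cluster filter last, on the survivors). Per-stage in/out counts
#' are recorded and every detected violation keeps full filter provenance.
#'
#' @param records a \code{TrioGenotypes}.
#' @param trio list with \code{father}, \code{mother}, \code{child} ids.
#' @param config a \code{FilterConfig}.
#' @param masks named list of \code{GRanges} masks.
#' @param populationSnps optional data.frame (\code{chrom}, \code{pos}).
#' @param depthStats optional named list per individual with elements
#'   \code{mean} and \code{sd}; computed from the input records when needed
#'   but not supplied.
#' @return list with elements \code{candidates} (surviving candidates,
#'   data.frame with provenance columns \code{pass_*} and \code{reasons}),
#'   \code{all} (every detected violation incl. removed ones, with
#'   \code{status} either \code{"candidate"} or \code{"removed:<stage>"}),
#'   and \code{accounting} (data.frame stage / n_in / n_out).
#' @export
runPipeline <- function(records, trio, config, masks = list(),
                        populationSnps = NULL, depthStats = NULL) {
    acct <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), stringsAsFactors = FALSE)
    note <- function(stage, nin, nout)
        rbind(acct, data.frame(stage = stage, n_in = nin, n_out = nout,
                               stringsAsFactors = FALSE))

    n0 <- length(records)
    ## chromosome policy + SNV restriction
    keep <- !(records@chrom %in% config@exclude_chroms)
    altL <- .altAlleleList(records)
    snv <- nchar(records@ref) == 1L & records@alt != "." &
        vapply(altL, function(a) all(nchar(a) == 1L), TRUE)
    keep <- keep & snv
    if (config@violation_mode != "allele_absence")
        keep <- keep & lengths(altL) == 1L
    rec <- records[keep]
    acct <- note("region_snv", n0, length(rec))

    ## site filters (per record, before violation detection)
    sv <- siteFilter(rec, config)
    rec2 <- rec[verdictPassed(sv)]
    acct <- note("site_filter", length(rec), length(rec2))

    ## Mendelian violations
    cand <- detectViolations(rec2, trio, config)
    acct <- note("mendelian_violation", length(rec2), nrow(cand))

    if (nrow(cand) == 0) {
        cand$status <- character(0)
        cand$reasons <- character(0)
        return(list(candidates = cand, all = cand, accounting = acct))
    }

    members <- c(father = trio$father, mother = trio$mother,
                 child = trio$child)
    needStats <- any(c("low_mult", "high_mult", "n_sigma", "poisson_p",
                       "trio_low_mult", "trio_high_mult") %in%
                     names(config@depth))
    if (is.null(depthStats) && needStats)
        depthStats <- lapply(records@geno[members], function(g)
            list(mean = mean(g$dp, na.rm = TRUE),
                 sd = stats::sd(g$dp, na.rm = TRUE)))
    trioMean <- if (needStats)
        mean(vapply(depthStats[members], `[[`, 0, "mean")) else NA_real_

    ci <- cand$idx
    aidx <- cand$allele_index
    acc <- list(re = character(nrow(cand)), ne = character(nrow(cand)))
    stagePass <- list()
    runStage <- function(stage, verdictFun) {
        ok <- rep(TRUE, nrow(cand))
        for (mem in names(members)) {
            v <- verdictFun(mem, members[[mem]])
            if (is.null(v)) next
            ok <- ok & v@passed
            acc <<- .joinVerdict(acc, v, mem)
        }
        stagePass[[stage]] <<- ok
        ok
    }

    calls <- lapply(members, function(id) {
        g <- sampleCalls(rec2, id)
        lapply(g, function(f) if (is.matrix(f)) f[ci, , drop = FALSE]
               else f[ci])
    })
    names(calls) <- names(members)

    ## depth on all members
    runStage("depth", function(mem, id)
        depthFilter(calls[[mem]]$dp, stats = depthStats[[id]],
                    trioStats = list(mean = trioMean), config))
    ## genotype quality on all members
    runStage("genotype_quality", function(mem, id) {
        g <- calls[[mem]]
        zyg <- ifelse(g$gt1 == g$gt2, "hom", "het")
        genotypeQualityFilter(g$gq, g$pl,
                              role = if (mem == "child") "child" else "parent",
                              zygosity = zyg, config)
    })
    ## parental alt reads
    runStage("parent_allele", function(mem, id) {
        if (mem == "child") return(NULL)
        g <- calls[[mem]]
        parentAlleleFilter(g$ad, aidx, g$lowq_ad_alt, config)
    })
    ## child allelic balance
    runStage("allelic_balance", function(mem, id) {
        if (mem != "child") return(NULL)
        abFilter(calls$child$ad, aidx, config)
    })
    ## strand support of the mutant allele in the child
    runStage("strand", function(mem, id) {
        if (mem != "child") return(NULL)
        g <- calls$child
        col <- cbind(seq_len(nrow(cand)), aidx + 1L)
        strandFilter(g$adf[col], g$adr[col], config)
    })
    ## exclusion resources
    otherIds <- setdiff(sampleIds(records), unname(members))
    otherCarriers <- NULL
    if (isTRUE(config@exclusion$use_other_samples) && length(otherIds)) {
        hits <- lapply(otherIds, function(id) {
            g <- sampleCalls(rec2, id)
            carries <- (!is.na(g$gt1[ci]) & g$gt1[ci] == aidx) |
                (!is.na(g$gt2[ci]) & g$gt2[ci] == aidx)
            which(carries)
        })
        hit <- sort(unique(unlist(hits)))
        otherCarriers <- data.frame(chrom = cand$chrom[hit],
                                    pos = cand$pos[hit])
    }
    pop <- if (isTRUE(config@exclusion$use_population_snps) ||
               (is.null(config@exclusion$use_population_snps) &&
                !is.null(populationSnps))) populationSnps else NULL
    runStage("exclusion", function(mem, id) {
        if (mem != "child") return(NULL)
        exclusionFilter(cand$chrom, cand$pos, cand$alt,
                        otherCarriers = otherCarriers,
                        populationSnps = pop, masks = masks, config = config)
    })

    ## assemble statuses in stage order; cluster runs last on survivors
    stageOrder <- c("depth", "genotype_quality", "parent_allele",
                    "allelic_balance", "strand", "exclusion")
    status <- rep("candidate", nrow(cand))
    alive <- rep(TRUE, nrow(cand))
    for (st in stageOrder) {
        nin <- sum(alive)
        died <- alive & !stagePass[[st]]
        status[died] <- paste0("removed:", st)
        alive <- alive & stagePass[[st]]
        acct <- note(st, nin, sum(alive))
    }
    nin <- sum(alive)
    survIdx <- which(alive)
    keptCl <- clusterFilter(cand$chrom[survIdx], cand$pos[survIdx], config)
    clDied <- survIdx[!keptCl]
    status[clDied] <- "removed:cluster"
    acc <- .vdFail(acc, seq_len(nrow(cand)) %in% clDied, "cluster")
    alive[clDied] <- FALSE
    acct <- note("cluster", nin, sum(alive))

    ## provenance columns
    cand$status <- status
    cand$reasons <- acc$re
    cand$not_evaluable <- acc$ne
    for (st in stageOrder) cand[[paste0("pass_", st)]] <- stagePass[[st]]
    cand$pass_cluster <- !(seq_len(nrow(cand)) %in% clDied)

    ## snapshot fields useful downstream
    for (mem in names(members)) {
        cand[[paste0("dp_", mem)]] <- calls[[mem]]$dp
        cand[[paste0("gq_", mem)]] <- calls[[mem]]$gq
    }
    cand$ab_child <- allelicBalance(calls$child$ad, aidx)

    list(candidates = cand[alive, , drop = FALSE], all = cand,
         accounting = acct)
}

#' Attach validation outcomes to candidates
#'
#' Updates candidate statuses from a validation table keyed by
#' (chrom, pos, allele): \code{validated} -> \code{validated},
#' \code{failed} -> \code{false_positive}, \code{not_amplified} ->
#' \code{not_amplified}; untested candidates keep status
#' \code{"candidate"}. Outcomes at unknown sites are ignored with a
#' warning.
#'
#' @param candidates candidate data.frame from \code{\link{runPipeline}}.
#' @param outcomes data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele}, \code{status}.
#' @return the candidates with updated \code{status}.
#' @export
attachValidation <- function(candidates, outcomes) {
    if (is.null(outcomes) || nrow(outcomes) == 0) return(candidates)
    ckey <- paste(candidates$chrom, candidates$pos, candidates$alt)
    okey <- paste(outcomes$chrom, outcomes$pos, outcomes$allele)
    unknown <- !(okey %in% ckey)
    if (any(unknown))
        warning(sum(unknown), " validation outcome(s) at non-candidate sites ignored")
    map <- c(validated = "validated", failed = "false_positive",
             not_amplified = "not_amplified")
    hit <- match(ckey, okey)
    has <- !is.na(hit) & outcomes$status[hit] %in% names(map)
    candidates$status[has] <- map[outcomes$status[hit[has]]]
    candidates
}
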