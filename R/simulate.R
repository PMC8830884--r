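## Synthetic trio (and three-generation) genotype-record simulator with a
## ground-truth ledger.
##
## The genome is materialized sparsely: only polymorphic sites, divergence
## (alt-background) sites, injected DNMs, somatic events and a uniform
## sample of monomorphic hom-ref background sites are emitted as records;
## the genome length is carried in the truth ledger so denominator
## estimates can extrapolate from the background sample.

#' Simulation parameters
#'
#' Builds the validated parameter list for \code{\link{simulateTrio}}. The
#' defaults emulate a deep-coverage primate trio: father at 40x and
#' mother/offspring at 70x mean depth, per-site heterozygosity 2e-3,
#' same-species reference (divergence 2e-3), per-base sequencing error
#' 1e-3, and a germline mutation probability of 1e-8 per site per haploid
#' transmission.
#'
#' @param genome_length genome size in sites (single simulated chromosome).
#' @param heterozygosity per-site probability that a parent is
#'   heterozygous. Sites are made polymorphic at rate
#'   \code{2 * heterozygosity} with Hardy-Weinberg genotypes at allele
#'   frequency 0.5, which yields exactly this per-parent heterozygosity.
#' @param divergence per-site probability of a fixed alternative background
#'   (both parents homozygous alt).
#' @param mean_depth named numeric: mean sequencing depth per individual
#'   (\code{father}, \code{mother}, \code{child}; a \code{grandchild}
#'   entry is used by \code{\link{simulateThirdGeneration}} and defaults to
#'   the child's).
#' @param sequencing_error per-base probability that a read shows the
#'   other allele.
#' @param mu_true DNM probability per site per haploid transmission (so
#'   the expected DNM count is \code{2 * genome_length * mu_true}).
#' @param n_somatic number of mosaic/somatic variants in the offspring.
#' @param cell_fraction cell fraction(s) of the somatic variants (recycled).
#' @param ti_fraction fraction of injected DNMs that are transitions.
#' @param n_background_sites monomorphic hom-ref sites to materialize (a
#'   uniform sample of the non-variant genome).
#' @param annotation_outlier_fraction per-annotation probability of
#'   drawing an outlying (filter-violating) site-annotation value; the
#'   annotation model is stylized, not a mapping simulation.
#' @param n_cluster_pairs optional number of DNM pairs placed within
#'   \code{cluster_distance} bp of each other (to exercise the cluster
#'   filter).
#' @param cluster_distance bp distance within an injected DNM pair.
#' @param gq_cap reported GQ cap (99, as in standard VCFs).
#' @param seed integer seed making the simulation reproducible.
#' @return a named list of validated parameters.
#' @export
simConfig <- function(genome_length = 1e6,
                      heterozygosity = 2e-3,
                      divergence = 2e-3,
                      mean_depth = c(father = 40, mother = 70, child = 70),
                      sequencing_error = 1e-3,
                      mu_true = 1e-8,
                      n_somatic = 0,
                      cell_fraction = 0.2,
                      ti_fraction = 0.73,
                      n_background_sites = 2e4,
                      annotation_outlier_fraction = 0.02,
                      n_cluster_pairs = 0,
                      cluster_distance = 5,
                      gq_cap = 99,
                      seed = 1L) {
    stopifnot(genome_length >= 1,
              heterozygosity >= 0, heterozygosity <= 1,
              divergence >= 0, divergence <= 1,
              all(mean_depth > 0),
              sequencing_error >= 0, sequencing_error <= 1,
              mu_true >= 0, mu_true <= 1,
              n_somatic >= 0,
              all(cell_fraction >= 0 & cell_fraction <= 1),
              ti_fraction >= 0, ti_fraction <= 1,
              annotation_outlier_fraction >= 0,
              annotation_outlier_fraction <= 1,
              gq_cap > 0)
    if (!all(c("father", "mother", "child") %in% names(mean_depth)))
        stop("mean_depth must name father, mother and child")
    if (!"grandchild" %in% names(mean_depth))
        mean_depth["grandchild"] <- mean_depth[["child"]]
    as.list(environment())
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

## draw alt bases: transitions with prob tiFrac, else one of the two
## transversion partners
.drawAlt <- function(ref, tiFrac) {
    n <- length(ref)
    isTi <- stats::runif(n) < tiFrac
    out <- character(n)
    out[isTi] <- .TRANSITION[ref[isTi]]
    if (any(!isTi)) {
        tvOpts <- rbind(A = c("C", "T"), C = c("A", "G"),
                        G = c("C", "T"), T = c("A", "G"))
        tv <- ref[!isTi]
        col <- sample.int(2L, length(tv), replace = TRUE)
        out[!isTi] <- tvOpts[cbind(match(tv, rownames(tvOpts)), col)]
    }
    out
}

## Per-read diploid likelihood model: P(read = alt | dosage) is eps, 0.5,
## 1 - eps for dosages 0, 1, 2. Returns called genotype, normalized PL and
## GQ from ref/alt read counts.
.callFromReads <- function(nref, nalt, eps, gqCap) {
    e <- max(eps, 1e-12)            # keep logs finite for error-free reads
    p <- c(e, 0.5, 1 - e)
    ll <- vapply(p, function(pa)
        nalt * log10(pa) + nref * log10(1 - pa), numeric(length(nref)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = length(nref))
    mx <- pmax(ll[, 1], ll[, 2], ll[, 3])
    pl <- -10 * (ll - mx)
    pl <- round(pl)                              # min PL = 0 at the max ll
    best <- max.col(-pl, ties.method = "first")
    nties <- rowSums(pl == 0)
    dp <- nref + nalt
    gt1 <- c(0L, 0L, 1L)[best]
    gt2 <- c(0L, 1L, 1L)[best]
    miss <- dp == 0 | nties > 1
    gt1[miss] <- NA_integer_
    gt2[miss] <- NA_integer_
    sorted2nd <- function(m) {                   # second-smallest per row
        a <- m[, 1]; b <- m[, 2]; cc <- m[, 3]
        (a + b + cc) - pmin(a, b, cc) - pmax(a, b, cc)
    }
    gq <- pmin(gqCap, sorted2nd(pl))
    list(gt1 = gt1, gt2 = gt2, pl = pl, gq = gq)
}

## reads for one individual at all sites given allele fraction f
.readsFor <- function(dp, f, eps) {
    pEff <- f * (1 - eps) + (1 - f) * eps
    nalt <- stats::rbinom(length(dp), dp, pEff)
    cbind(ref = dp - nalt, alt = nalt)
}

## stylized site annotations with an outlier fraction per annotation
.simAnnotations <- function(n, outlierFrac) {
    draw <- function(typical, outlier) {
        o <- stats::runif(n) < outlierFrac
        v <- typical(n)
        if (any(o)) v[o] <- outlier(sum(o))
        v
    }
    data.frame(
        qual = stats::runif(n, 100, 1000),
        qd = draw(function(k) stats::runif(k, 15, 35),
                  function(k) stats::runif(k, 0, 2)),
        mq = draw(function(k) stats::runif(k, 55, 60),
                  function(k) stats::runif(k, 10, 40)),
        fs = draw(function(k) stats::runif(k, 0, 10),
                  function(k) stats::runif(k, 60, 100)),
        sor = draw(function(k) stats::runif(k, 0.5, 2.5),
                   function(k) stats::runif(k, 3.5, 10)),
        mq_rank_sum = draw(function(k) stats::rnorm(k, 0, 1),
                           function(k) sample(c(-1, 1), k, TRUE) *
                               stats::runif(k, 13, 20)),
        read_pos_rank_sum = draw(function(k) stats::rnorm(k, 0, 1),
                                 function(k) sample(c(-1, 1), k, TRUE) *
                                     stats::runif(k, 8.5, 15)),
        base_q_rank_sum = draw(function(k) stats::rnorm(k, 0, 2),
                               function(k) sample(c(-1, 1), k, TRUE) *
                                   stats::runif(k, 13.5, 20)))
}

#' Simulate a sequenced trio with a ground-truth ledger
#'
#' Generates per-site genotype records for father, mother and offspring
#' under a sparse genome model: parental genotypes are drawn from the
#' polymorphism/divergence background, the offspring inherits by Mendelian
#' sampling, germline DNMs are injected at rate \code{mu_true} per haploid
#' transmission, somatic events are assigned their cell fractions, depths
#' are Poisson, allele reads binomial with symmetric sequencing error, and
#' genotypes/PL/GQ are called from the reads under the standard diploid
#' per-read likelihood. Identical config (incl. seed) gives byte-identical
#' output through \code{\link{writeTrioVcf}}.
#'
#' @param config parameter list from \code{\link{simConfig}}.
#' @return list with \code{records} (a \code{TrioGenotypes} with samples
#'   \code{father}, \code{mother}, \code{child}) and \code{truth} (a
#'   \code{\linkS4class{SimTruth}}).
#' @export
simulateTrio <- function(config = simConfig()) {
    set.seed(config$seed)
    L <- config$genome_length
    eps <- config$sequencing_error

    nPoly <- stats::rbinom(1, L, min(1, 2 * config$heterozygosity))
    nDiv <- stats::rbinom(1, L, config$divergence)
    nDnm <- stats::rpois(1, 2 * L * config$mu_true)
    nSom <- config$n_somatic
    nClu <- config$n_cluster_pairs
    nBg <- min(config$n_background_sites,
               max(0, L - nPoly - nDiv - nDnm - nSom - 2 * nClu))
    nTot <- nPoly + nDiv + nDnm + nSom + 2 * nClu + nBg
    if (nTot > L) stop("genome too small for the requested site counts")

    pos <- sort(sample(L, nTot))
    kind <- rep(c("poly", "div", "dnm", "somatic", "cluster", "bg"),
                c(nPoly, nDiv, nDnm, nSom, 2 * nClu, nBg))
    kind <- sample(kind)                 # kinds scattered across positions
    ## cluster pairs: re-place the second member next to the first
    cluIdx <- which(kind == "cluster")
    if (nClu > 0) {
        kind[cluIdx] <- "dnm"
        first <- cluIdx[seq_len(nClu)]
        second <- cluIdx[nClu + seq_len(nClu)]
        pos[second] <- pmin(L, pos[first] + config$cluster_distance)
        ord <- order(pos)
        pos <- pos[ord]; kind <- kind[ord]
        dup <- duplicated(pos)           # collisions from re-placement
        pos <- pos[!dup]; kind <- kind[!dup]
    }
    n <- length(pos)

    ref <- sample(.BASES, n, replace = TRUE)
    alt <- .drawAlt(ref, config$ti_fraction)   # designated alt per site
    isDnmKind <- kind == "dnm"

    ## true genotype dosages (count of alt alleles)
    dos <- matrix(0L, n, 3, dimnames = list(NULL, c("father", "mother",
                                                    "child")))
    poly <- which(kind == "poly")
    if (length(poly)) {
        hw <- function(k) sample(0:2, k, replace = TRUE,
                                 prob = c(0.25, 0.5, 0.25))
        dos[poly, "father"] <- hw(length(poly))
        dos[poly, "mother"] <- hw(length(poly))
        transmit <- function(d)   # allele passed on given parent dosage
            ifelse(d == 0L, 0L, ifelse(d == 2L, 1L,
                                       stats::rbinom(length(d), 1L, 0.5)))
        dos[poly, "child"] <- transmit(dos[poly, "father"]) +
            transmit(dos[poly, "mother"])
    }
    div <- which(kind == "div")
    dos[div, ] <- 2L
    dnm <- which(isDnmKind)
    dos[dnm, "child"] <- 1L             # parents stay hom-ref
    somatic <- which(kind == "somatic")
    cf <- rep_len(config$cell_fraction, length(somatic))

    ## reads, calls
    geno <- list()
    ids <- c("father", "mother", "child")
    for (id in ids) {
        dp <- stats::rpois(n, config$mean_depth[[id]])
        f <- dos[, id] / 2
        if (id == "child" && length(somatic)) f[somatic] <- cf
        rd <- .readsFor(dp, f, eps)
        call <- .callFromReads(rd[, "ref"], rd[, "alt"], eps, config$gq_cap)
        adf_alt <- stats::rbinom(n, rd[, "alt"], 0.5)
        adf_ref <- stats::rbinom(n, rd[, "ref"], 0.5)
        geno[[id]] <- list(
            gt1 = call$gt1, gt2 = call$gt2, dp = as.integer(dp),
            gq = call$gq, lowq_ad_alt = rep(0L, n),
            ad = cbind(rd[, "ref"], rd[, "alt"]),
            pl = call$pl,
            adf = cbind(adf_ref, adf_alt),
            adr = cbind(rd[, "ref"] - adf_ref, rd[, "alt"] - adf_alt))
    }

    info <- .simAnnotations(n, config$annotation_outlier_fraction)

    rec <- TrioGenotypes(chrom = rep("1", n), pos = pos, ref = ref,
                         alt = alt, info = info, geno = geno)

    ## truth ledger
    forcedHet <- which(kind == "poly" &
                       ((dos[, "father"] == 0L & dos[, "mother"] == 2L) |
                        (dos[, "father"] == 2L & dos[, "mother"] == 0L)))
    poOrigin <- rep(NA_character_, n)
    poOrigin[dnm] <- sample(c("father", "mother"), length(dnm),
                            replace = TRUE)
    truthRows <- function(idx, kindLabel, po = NA_character_,
                          cellFrac = NA_real_) {
        k <- length(idx)
        data.frame(pos = pos[idx], kind = rep(kindLabel, k),
                   parent_of_origin = rep_len(po, k),
                   allele = alt[idx],
                   cell_fraction = rep_len(cellFrac, k),
                   transmitted = rep(NA, k), stringsAsFactors = FALSE)
    }
    tt <- rbind(truthRows(dnm, "dnm", po = poOrigin[dnm]),
                truthRows(somatic, "somatic", cellFrac = cf),
                truthRows(forcedHet, "forced_het"),
                truthRows(div, "alt_background"))
    cfgSnap <- config
    cfgSnap$true_dosage <- data.frame(pos = pos, father = dos[, "father"],
                                      mother = dos[, "mother"],
                                      child = dos[, "child"])
    truth <- new("SimTruth", tab = tt, genomeLength = as.numeric(L),
                 nBackgroundEmitted = as.numeric(sum(kind == "bg")),
                 config = cfgSnap)
    list(records = rec, truth = truth)
}

#' Inject spike-in DNMs into simulated records
#'
#' Converts \code{nSpikes} uniformly chosen monomorphic parental-hom-ref
#' background sites into offspring heterozygotes: the child's alt reads
#' are resampled as Binomial(DP, 0.5) and PL/GQ/GT recomputed under the
#' same read model; the truth ledger is extended.
#'
#' @param records simulated \code{TrioGenotypes}.
#' @param truth matching \code{SimTruth}.
#' @param nSpikes number of spikes.
#' @param seed RNG seed for the injection.
#' @return list with updated \code{records} and \code{truth}.
#' @export
injectSpikes <- function(records, truth, nSpikes, seed = 1L) {
    if (nSpikes == 0) return(list(records = records, truth = truth))
    set.seed(seed)
    cfg <- truth@config
    eps <- cfg$sequencing_error
    usedPos <- truth@tab$pos
    f <- sampleCalls(records, "father")
    m <- sampleCalls(records, "mother")
    eligible <- which(!(records@pos %in% usedPos) &
                      !is.na(f$gt1) & f$gt1 == 0L & f$gt2 == 0L &
                      !is.na(m$gt1) & m$gt1 == 0L & m$gt2 == 0L &
                      cfg$true_dosage$child[match(records@pos,
                                                  cfg$true_dosage$pos)] == 0L)
    if (length(eligible) < nSpikes)
        stop("only ", length(eligible),
             " eligible background sites for ", nSpikes, " spikes")
    pick <- sort(sample(eligible, nSpikes))
    ch <- records@geno$child
    dp <- ch$dp[pick]
    nalt <- stats::rbinom(length(pick), dp, 0.5 * (1 - eps) +
                          0.5 * eps)
    call <- .callFromReads(dp - nalt, nalt, eps, cfg$gq_cap)
    ch$gt1[pick] <- call$gt1
    ch$gt2[pick] <- call$gt2
    ch$gq[pick] <- call$gq
    ch$ad[pick, ] <- cbind(dp - nalt, nalt)
    ch$pl[pick, ] <- call$pl
    adfAlt <- stats::rbinom(length(pick), nalt, 0.5)
    adfRef <- stats::rbinom(length(pick), dp - nalt, 0.5)
    ch$adf[pick, ] <- cbind(adfRef, adfAlt)
    ch$adr[pick, ] <- cbind(dp - nalt - adfRef, nalt - adfAlt)
    records@geno$child <- ch

    add <- data.frame(pos = records@pos[pick], kind = "dnm",
                      parent_of_origin = sample(c("father", "mother"),
                                                length(pick), replace = TRUE),
                      allele = records@alt[pick],
                      cell_fraction = NA_real_, transmitted = NA,
                      stringsAsFactors = FALSE)
    truth@tab <- rbind(truth@tab, add)
    truth@config$true_dosage$child[match(records@pos[pick],
                                         truth@config$true_dosage$pos)] <- 1L
    list(records = records, truth = truth)
}

#' Extend a simulated trio with a third generation
#'
#' Adds a \code{grandchild} sample: offspring of the trio's child and an
#' unrelated mate drawn from the same population background. Every true
#' child DNM is transmitted with probability \code{transmissionProb}
#' (recorded in the truth ledger); all other sites segregate by Mendelian
#' sampling. Grandchild reads/calls follow the same read model.
#'
#' @param records simulated \code{TrioGenotypes}.
#' @param truth matching \code{SimTruth}.
#' @param transmissionProb probability a child DNM passes to the
#'   grandchild (0.5 under Mendelian expectation).
#' @param seed RNG seed.
#' @return list with updated \code{records} and \code{truth}.
#' @export
simulateThirdGeneration <- function(records, truth, transmissionProb = 0.5,
                                    seed = 2L) {
    set.seed(seed)
    cfg <- truth@config
    eps <- cfg$sequencing_error
    n <- length(records)
    dosC <- cfg$true_dosage$child
    ## mate from the population background at polymorphic sites
    polyPos <- setdiff(cfg$true_dosage$pos[cfg$true_dosage$father > 0 |
                                           cfg$true_dosage$mother > 0],
                       truth@tab$pos[truth@tab$kind %in%
                                     c("dnm", "somatic")])
    isPoly <- records@pos %in% polyPos
    isDiv <- records@pos %in% truth@tab$pos[truth@tab$kind ==
                                            "alt_background"]
    dosMate <- integer(n)
    dosMate[isPoly] <- sample(0:2, sum(isPoly), replace = TRUE,
                              prob = c(0.25, 0.5, 0.25))
    dosMate[isDiv] <- 2L

    transmitFrom <- function(d)
        ifelse(d == 0L, 0L, ifelse(d == 2L, 1L,
                                   stats::rbinom(length(d), 1L, 0.5)))
    fromChild <- transmitFrom(dosC)
    ## DNM transmission is controlled explicitly
    dnmIdx <- which(truth@tab$kind == "dnm")
    dnmRow <- match(truth@tab$pos[dnmIdx], records@pos)
    tr <- stats::rbinom(length(dnmIdx), 1L, transmissionProb) == 1L
    fromChild[dnmRow] <- as.integer(tr)
    truth@tab$transmitted[dnmIdx] <- tr
    dosG <- fromChild + transmitFrom(dosMate)

    dp <- stats::rpois(n, cfg$mean_depth[["grandchild"]])
    rd <- .readsFor(dp, dosG / 2, eps)
    call <- .callFromReads(rd[, "ref"], rd[, "alt"], eps, cfg$gq_cap)
    adfAlt <- stats::rbinom(n, rd[, "alt"], 0.5)
    adfRef <- stats::rbinom(n, rd[, "ref"], 0.5)
    records@geno$grandchild <- list(
        gt1 = call$gt1, gt2 = call$gt2, dp = as.integer(dp), gq = call$gq,
        lowq_ad_alt = rep(0L, n),
        ad = cbind(rd[, "ref"], rd[, "alt"]), pl = call$pl,
        adf = cbind(adfRef, adfAlt),
        adr = cbind(rd[, "ref"] - adfRef, rd[, "alt"] - adfAlt))
    truth@config$true_dosage$grandchild <- dosG
    list(records = records, truth = truth)
}

#' Extract the monomorphic background sample from a simulation
#'
#' Returns the records at the uniformly sampled hom-ref background sites
#' (no polymorphism, no DNM, no somatic event). These stand in for
#' BP-resolution non-variant records: the callable fraction estimated on
#' them extrapolates to the whole genome via
#' \code{callableGenomeCount(..., genomeSites = genomeLength(truth))}.
#'
#' @param records simulated \code{TrioGenotypes}.
#' @param truth matching \code{SimTruth}.
#' @return a \code{TrioGenotypes} subset.
#' @export
backgroundRecords <- function(records, truth) {
    td <- truth@config$true_dosage
    bgPos <- td$pos[td$father == 0L & td$mother == 0L & td$child == 0L]
    bgPos <- setdiff(bgPos, truth@tab$pos)
    records[records@pos %in% bgPos]
}

#' Offspring read counts at forced-heterozygote sites
#'
#' Sites where one parent is truly 0/0 and the other 1/1, so the offspring
#' is an obligate heterozygote; their allelic-balance distribution feeds
#' the AB-based FNR estimate (\code{\link{fnrAb}}).
#'
#' @param records simulated \code{TrioGenotypes}.
#' @param truth matching \code{SimTruth}.
#' @param child offspring sample id.
#' @return data.frame with columns \code{pos}, \code{ad_ref},
#'   \code{ad_alt}.
#' @export
forcedHetReads <- function(records, truth, child = "child") {
    fh <- truth@tab$pos[truth@tab$kind == "forced_het"]
    row <- match(fh, records@pos)
    row <- row[!is.na(row)]
    ad <- sampleCalls(records, child)$ad
    data.frame(pos = records@pos[row], ad_ref = ad[row, 1],
               ad_alt = ad[row, 2])
}

#' Write a simulation truth ledger as TSV
#'
#' Columns: pos, kind (dnm / somatic / forced_het / alt_background),
#' parent_of_origin, allele, cell_fraction, transmitted.
#'
#' @param truth a \code{SimTruth}.
#' @param path output path.
#' @export
writeTruth <- function(truth, path) {
    utils::write.table(truthTable(truth), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
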