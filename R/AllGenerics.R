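## Generics and accessors for the core containers.

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("sampleCalls", function(x, id) standardGeneric("sampleCalls"))
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @export
setGeneric("trios", function(x) standardGeneric("trios"))
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))
#' @export
setGeneric("verdictPassed", function(x) standardGeneric("verdictPassed"))
#' @export
setGeneric("verdictReasons", function(x) standardGeneric("verdictReasons"))
#' @export
setGeneric("notEvaluable", function(x) standardGeneric("notEvaluable"))
#' @export
setGeneric("cgSites", function(x) standardGeneric("cgSites"))
#' @export
setGeneric("estimateValue", function(x) standardGeneric("estimateValue"))
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

## --- Pedigree --------------------------------------------------------------

#' @describeIn Pedigree full pedigree table
#' @export
setMethod("pedigreeTable", "Pedigree", function(x) x@tab)

#' Derivable trios of a pedigree
#'
#' Returns one row per offspring with at least one known parent; rows with
#' both parents known are complete trios.
#'
#' @param x a \code{Pedigree}.
#' @return data.frame with columns \code{father}, \code{mother},
#'   \code{child}, \code{complete}.
#' @export
setMethod("trios", "Pedigree", function(x) {
    tb <- x@tab
    kid <- tb[!is.na(tb$father) | !is.na(tb$mother), , drop = FALSE]
    data.frame(father = kid$father, mother = kid$mother, child = kid$id,
               complete = !is.na(kid$father) & !is.na(kid$mother),
               stringsAsFactors = FALSE)
})

setMethod("show", "Pedigree", function(object) {
    tb <- object@tab
    cat(sprintf("Pedigree: %d individuals, %d generations, %d derivable trio(s)\n",
                nrow(tb), length(unique(tb$generation)),
                nrow(trios(object))))
    print(tb, row.names = FALSE)
})

## --- TrioGenotypes ---------------------------------------------------------

setMethod("length", "TrioGenotypes", function(x) length(x@pos))

#' @describeIn TrioGenotypes sample ids present in the records
#' @export
setMethod("sampleIds", "TrioGenotypes", function(x) names(x@geno))

#' @describeIn TrioGenotypes per-sample call fields (list of vectors/matrices)
#' @param id sample id.
#' @export
setMethod("sampleCalls", "TrioGenotypes", function(x, id) {
    if (!id %in% names(x@geno))
        stop("no calls for sample '", id, "'")
    x@geno[[id]]
})

#' @describeIn TrioGenotypes site annotation data.frame
#' @export
setMethod("siteInfo", "TrioGenotypes", function(x) x@info)

#' @export
setMethod("[", "TrioGenotypes", function(x, i, j, ..., drop = FALSE) {
    if (is.logical(i)) i <- which(i)
    geno <- lapply(x@geno, function(g) {
        out <- lapply(g, function(f) {
            if (is.matrix(f)) f[i, , drop = FALSE] else f[i]
        })
        out
    })
    new("TrioGenotypes", chrom = x@chrom[i], pos = x@pos[i],
        ref = x@ref[i], alt = x@alt[i],
        info = x@info[i, , drop = FALSE], geno = geno)
})

setMethod("show", "TrioGenotypes", function(object) {
    cat(sprintf("TrioGenotypes: %d site(s), %d sample(s) [%s]\n",
                length(object), length(object@geno),
                paste(names(object@geno), collapse = ", ")))
    if (length(object) > 0) {
        n <- min(length(object), 5L)
        hd <- data.frame(chrom = object@chrom[seq_len(n)],
                         pos = object@pos[seq_len(n)],
                         ref = object@ref[seq_len(n)],
                         alt = object@alt[seq_len(n)])
        print(hd, row.names = FALSE)
        if (length(object) > n) cat("...\n")
    }
})

## --- FilterVerdict ---------------------------------------------------------

setMethod("length", "FilterVerdict", function(x) length(x@passed))

#' @describeIn FilterVerdict logical pass/fail per element
#' @export
setMethod("verdictPassed", "FilterVerdict", function(x) x@passed)

#' @describeIn FilterVerdict list of failed-filter descriptors per element
#' @export
setMethod("verdictReasons", "FilterVerdict", function(x)
    strsplit(x@reasons, ";", fixed = TRUE))

#' @describeIn FilterVerdict list of filters skipped for missing data
#' @export
setMethod("notEvaluable", "FilterVerdict", function(x)
    strsplit(x@notEvaluable, ";", fixed = TRUE))

setMethod("show", "FilterVerdict", function(object) {
    cat(sprintf("FilterVerdict: %d evaluated, %d passed, %d failed, %d with non-evaluable filters\n",
                length(object), sum(object@passed), sum(!object@passed),
                sum(object@notEvaluable != "")))
    if (length(object) <= 3 && any(!object@passed))
        cat("  reasons:", paste(object@reasons[!object@passed],
                                collapse = " | "), "\n")
})

## --- Results ---------------------------------------------------------------

#' @describeIn CallableResult callable-site count (or expected count)
#' @export
setMethod("cgSites", "CallableResult", function(x) {
    if (!is.na(x@cgExtrapolated)) x@cgExtrapolated else x@cgSites
})

setMethod("show", "CallableResult", function(object) {
    cat(sprintf("CallableResult (%s): %.6g callable of %.6g examined",
                object@method, object@cgSites, object@nExamined))
    if (!is.na(object@cgExtrapolated))
        cat(sprintf("; extrapolated to %.6g of %.6g genome sites",
                    object@cgExtrapolated, object@genomeSites))
    cat("\n")
})

#' @describeIn FnrEstimate numeric FNR value
#' @export
setMethod("estimateValue", "FnrEstimate", function(x) x@value)
#' @describeIn FdrEstimate numeric FDR value
#' @export
setMethod("estimateValue", "FdrEstimate", function(x) x@value)

setMethod("show", "FnrEstimate", function(object)
    cat(sprintf("FnrEstimate (%s): %.4g  [n basis = %g]\n",
                object@method, object@value, object@nBasis)))
setMethod("show", "FdrEstimate", function(object)
    cat(sprintf("FdrEstimate (%s): %.4g  [%s]\n", object@method, object@value,
                paste(names(object@basis), object@basis, sep = "=",
                      collapse = ", "))))

setMethod("show", "RateEstimate", function(object) {
    cat(sprintf("RateEstimate: mu = %.4g per site per generation\n", object@mu))
    cat(sprintf("  n = %g, FDR = %.4g, CG = %.6g, FNR = %.4g\n",
                object@nCandidates, object@fdr, object@cgSites, object@fnr))
    cat(sprintf("  %g%% CI (%s): [%.4g, %.4g]\n", 100 * object@ciLevel,
                object@ciMethod, object@ci[1], object@ci[2]))
})

## --- SimTruth --------------------------------------------------------------

#' @describeIn SimTruth the truth ledger data.frame
#' @export
setMethod("truthTable", "SimTruth", function(x) x@tab)

#' @describeIn SimTruth simulated genome length in sites
#' @export
setMethod("genomeLength", "SimTruth", function(x) x@genomeLength)

setMethod("show", "SimTruth", function(object) {
    kinds <- table(object@tab$kind)
    cat(sprintf("SimTruth: genome of %.6g sites; %s; %g background sites emitted\n",
                object@genomeLength,
                paste(names(kinds), as.integer(kinds), sep = "=",
                      collapse = ", "),
                object@nBackgroundEmitted))
})
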