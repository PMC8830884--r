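#' Read a 6-column PED pedigree file
#'
#' Parses the standard whitespace-separated PED dialect (family, individual,
#' father, mother, sex, phenotype). \code{"0"} denotes an unknown parent and
#' is stored as \code{NA}; an individual with only one known parent still
#' yields a (partial) trio. Generation indices are computed from the parent
#' links: founders are generation 0 and every other individual sits one
#' generation above its deepest known parent.
#'
#' @param path path to the PED file.
#' @param ages optional data.frame (or path to a 2+-column table) with
#'   columns \code{id} and \code{age_at_conception} supplying parental ages
#'   at conception in years.
#' @return a \code{\linkS4class{Pedigree}}.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 F 0 0 1 0", "FAM1 M 0 0 2 0", "FAM1 C F M 2 0"), ped)
#' trios(readPedigree(ped))
#' @export
readPedigree <- function(path, ages = NULL) {
    if (!file.exists(path))
        stop("pedigree file not found: ", path)
    tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character",
                            col.names = c("family", "id", "father", "mother",
                                          "sex", "phenotype"))
    if (nrow(tb) < 3)
        stop("pedigree must contain at least 3 rows forming one trio")
    tb$father[tb$father == "0"] <- NA_character_
    tb$mother[tb$mother == "0"] <- NA_character_
    if (any(tb$id == tb$father | tb$id == tb$mother, na.rm = TRUE))
        stop("structural error: individual listed as its own parent")
    unknown <- setdiff(c(tb$father, tb$mother), c(tb$id, NA))
    if (length(unknown))
        stop("parent id(s) not present in pedigree: ",
             paste(unknown, collapse = ", "))

    tb$generation <- .assignGenerations(tb$id, tb$father, tb$mother)
    if (anyNA(tb$generation))
        stop("structural error: cyclic parentage in pedigree")

    tb$age_at_conception <- NA_real_
    if (!is.null(ages)) {
        if (is.character(ages))
            ages <- utils::read.table(ages, header = TRUE,
                                      stringsAsFactors = FALSE)
        idx <- match(tb$id, ages$id)
        tb$age_at_conception <- as.numeric(ages$age_at_conception[idx])
    }
    ped <- new("Pedigree", tab = tb)
    if (!any(trios(ped)$complete) && nrow(trios(ped)) == 0)
        stop("no trio derivable from pedigree")
    ped
}

## Iterative generation assignment; returns NA for ids stuck in a cycle.
.assignGenerations <- function(id, father, mother) {
    gen <- ifelse(is.na(father) & is.na(mother), 0L, NA_integer_)
    names(gen) <- id
    repeat {
        todo <- which(is.na(gen))
        if (!length(todo)) break
        changed <- FALSE
        for (i in todo) {
            needed <- stats::na.omit(c(father[i], mother[i]))
            if (all(!is.na(gen[needed]))) {
                gen[i] <- max(gen[needed]) + 1L
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    unname(gen[id])
}

#' Resolve one focal trio from a pedigree
#'
#' @param pedigree a \code{Pedigree}.
#' @param child id of the focal offspring; defaults to the unique complete
#'   trio's child when there is exactly one.
#' @param requireComplete require both parents known.
#' @return list with \code{father}, \code{mother}, \code{child} ids
#'   (\code{NA} for an unknown parent when \code{requireComplete = FALSE}).
#' @export
resolveTrio <- function(pedigree, child = NULL, requireComplete = TRUE) {
    tt <- trios(pedigree)
    if (is.null(child)) {
        cand <- tt[tt$complete, , drop = FALSE]
        if (nrow(cand) != 1)
            stop("child must be given when the pedigree holds ",
                 nrow(cand), " complete trios")
        tt <- cand
    } else {
        tt <- tt[tt$child == child, , drop = FALSE]
        if (nrow(tt) == 0)
            stop("no trio with child '", child, "'")
    }
    if (requireComplete && !tt$complete[1])
        stop("trio for child '", tt$child[1], "' lacks a known parent")
    list(father = tt$father[1], mother = tt$mother[1], child = tt$child[1])
}
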