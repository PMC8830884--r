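## Input/output: VCF records, BED masks, candidate tables, validation tables.

.INFO_COLS <- c(qual = "QUAL", qd = "QD", mq = "MQ", fs = "FS", sor = "SOR",
                mq_rank_sum = "MQRankSum", read_pos_rank_sum = "ReadPosRankSum",
                base_q_rank_sum = "BaseQRankSum")

.emptyInfo <- function(n) {
    out <- as.data.frame(lapply(names(.INFO_COLS), function(x) rep(NA_real_, n)))
    names(out) <- names(.INFO_COLS)
    out
}

.emptySampleGeno <- function(n, nAllele = 2L) {
    nGeno <- nAllele * (nAllele + 1L) / 2L
    list(gt1 = rep(NA_integer_, n), gt2 = rep(NA_integer_, n),
         dp = rep(NA_integer_, n), gq = rep(NA_real_, n),
         lowq_ad_alt = rep(NA_integer_, n),
         ad = matrix(NA_real_, n, nAllele),
         pl = matrix(NA_real_, n, nGeno),
         adf = matrix(NA_real_, n, nAllele),
         adr = matrix(NA_real_, n, nAllele))
}

#' Construct per-site trio genotype records
#'
#' Low-level constructor used by the reader and the simulator. Any omitted
#' annotation or call field is stored as missing (\code{NA}); missingness is
#' never coerced to a default value.
#'
#' @param chrom,pos,ref,alt site columns (\code{pos} 1-based; \code{alt}
#'   comma-separated for multi-allelic sites).
#' @param info data.frame with any of the columns \code{qual}, \code{qd},
#'   \code{mq}, \code{fs}, \code{sor}, \code{mq_rank_sum},
#'   \code{read_pos_rank_sum}, \code{base_q_rank_sum}.
#' @param geno named list of per-sample call lists (see
#'   \code{\linkS4class{TrioGenotypes}}); missing fields are filled with
#'   \code{NA}.
#' @return a \code{\linkS4class{TrioGenotypes}}.
#' @export
TrioGenotypes <- function(chrom, pos, ref, alt, info = NULL, geno = list()) {
    n <- length(pos)
    full <- .emptyInfo(n)
    if (!is.null(info))
        for (cn in intersect(names(info), names(full)))
            full[[cn]] <- as.numeric(info[[cn]])
    nAllele <- if (n) max(1L + lengths(strsplit(alt, ",", fixed = TRUE))) else 2L
    geno <- lapply(geno, function(g) {
        tmpl <- .emptySampleGeno(n, nAllele)
        for (f in names(tmpl)) {
            if (is.null(g[[f]])) next
            v <- g[[f]]
            if (is.matrix(tmpl[[f]])) {
                v <- as.matrix(v)
                tmpl[[f]][, seq_len(ncol(v))] <- v
            } else tmpl[[f]] <- as.vector(v, mode = mode(tmpl[[f]]))
        }
        tmpl
    })
    new("TrioGenotypes", chrom = as.character(chrom), pos = as.integer(pos),
        ref = as.character(ref), alt = as.character(alt),
        info = full, geno = geno)
}

## pad a list of per-site integer vectors into an n x k NA matrix
.padMatrix <- function(lst, k) {
    out <- matrix(NA_real_, length(lst), k)
    len <- lengths(lst)
    for (j in seq_len(k)) {
        has <- len >= j
        out[has, j] <- vapply(lst[has], function(v) as.numeric(v[j]), 0)
    }
    out
}

#' Read a multi-sample VCF into trio genotype records
#'
#' Uses \pkg{VariantAnnotation} to parse VCF 4.x. Records are returned in
#' coordinate order; multi-allelic sites keep all ALT alleles; FORMAT
#' subfields absent from a record map to \code{NA}, never to defaults.
#' Per-allele strand depths are taken from \code{ADF}/\code{ADR} when
#' present, and the low-quality alternative-read count from the
#' non-standard \code{LQA} field written by this package's simulator.
#'
#' @param path path to a VCF file.
#' @param pedigree optional \code{Pedigree}; every pedigree member must be a
#'   sample of the VCF, otherwise a configuration error lists the missing
#'   ids.
#' @param region optional list/vector \code{(chrom, start, end)} restricting
#'   the records (1-based, closed).
#' @return a \code{\linkS4class{TrioGenotypes}}.
#' @export
readTrioVcf <- function(path, pedigree = NULL, region = NULL) {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    smp <- colnames(vcf)
    if (!is.null(pedigree)) {
        missing <- setdiff(pedigreeTable(pedigree)$id, smp)
        if (length(missing))
            stop("configuration error: pedigree sample(s) absent from VCF: ",
                 paste(missing, collapse = ", "))
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    altL <- lapply(rr$ALT, as.character)
    alt <- vapply(altL, paste, "", collapse = ",")
    n <- length(pos)
    nAllele <- if (n) max(1L + lengths(altL)) else 2L

    inf <- VariantAnnotation::info(vcf)
    infoDf <- .emptyInfo(n)
    infoDf$qual <- as.numeric(rr$QUAL)
    for (field in names(.INFO_COLS)[-1]) {
        vc <- .INFO_COLS[[field]]
        if (vc %in% names(inf)) infoDf[[field]] <- as.numeric(inf[[vc]])
    }

    g <- VariantAnnotation::geno(vcf)
    geno <- list()
    for (s in smp) {
        sg <- .emptySampleGeno(n, nAllele)
        if ("GT" %in% names(g)) {
            gt <- g$GT[, s]
            parts <- strsplit(gt, "[/|]")
            a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
            a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
                if (length(p) >= 2) p[2] else NA_character_, "")))
            sg$gt1 <- pmin(a1, a2)   # unphased: store sorted allele pair
            sg$gt2 <- pmax(a1, a2)
        }
        if ("DP" %in% names(g)) sg$dp <- as.integer(g$DP[, s])
        if ("GQ" %in% names(g)) sg$gq <- as.numeric(g$GQ[, s])
        if ("LQA" %in% names(g)) sg$lowq_ad_alt <- as.integer(g$LQA[, s])
        mfields <- c(ad = "AD", pl = "PL", adf = "ADF", adr = "ADR")
        for (nm in names(mfields)) {
            mf <- mfields[[nm]]
            if (!mf %in% names(g)) next
            arr <- g[[mf]]
            k <- if (mf == "PL") nAllele * (nAllele + 1L) / 2L else nAllele
            if (is.array(arr) && length(dim(arr)) == 3) {
                v <- arr[, s, , drop = FALSE]
                kk <- min(k, dim(arr)[3])
                sg[[nm]][, seq_len(kk)] <-
                    matrix(as.numeric(v), nrow = n)[, seq_len(kk)]
            } else {
                v <- arr[, s]
                if (is.list(v)) sg[[nm]] <- .padMatrix(v, k)
                else sg[[nm]][, 1] <- as.numeric(v)
            }
        }
        geno[[s]] <- sg
    }
    tg <- new("TrioGenotypes", chrom = chrom, pos = as.integer(pos),
              ref = ref, alt = alt, info = infoDf, geno = geno)
    ord <- order(tg@chrom, tg@pos)
    tg <- tg[ord]
    if (!is.null(region)) {
        keep <- tg@chrom == as.character(region[[1]]) &
            tg@pos >= as.integer(region[[2]]) &
            tg@pos <= as.integer(region[[3]])
        tg <- tg[keep]
    }
    tg
}

#' Read a BED mask into a labelled set of genomic intervals
#'
#' BED intervals are 0-based half-open; they are merged per chromosome. A
#' VCF position \code{p} lies inside the mask when \code{p - 1} is in
#' \code{[start, end)}. Rows with \code{start >= end} are rejected with a
#' warning reporting how many were dropped.
#'
#' @param path path to a 3+ column BED file.
#' @param label mask label (e.g. \code{"LCR"}, \code{"repeat"}).
#' @return a \code{GRanges} with metadata column \code{label}; empty input
#'   gives an empty mask.
#' @export
readMask <- function(path, label = "mask") {
    raw <- tryCatch(utils::read.table(path, header = FALSE,
                                      stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr)$label <- label
        return(gr)
    }
    bad <- raw[[2]] >= raw[[3]]
    if (any(bad))
        warning(sum(bad), " BED row(s) with start >= end rejected")
    raw <- raw[!bad, , drop = FALSE]
    gr <- GenomicRanges::GRanges(raw[[1]],
                                 IRanges::IRanges(start = raw[[2]] + 1L,
                                                  end = raw[[3]]))
    gr <- GenomicRanges::reduce(sort(gr))
    S4Vectors::metadata(gr)$label <- label
    gr
}

#' Test mask membership of 1-based positions
#'
#' @param mask a \code{GRanges} mask from \code{\link{readMask}}.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return logical vector.
#' @export
inMask <- function(mask, chrom, pos) {
    if (length(mask) == 0) return(rep(FALSE, length(pos)))
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    IRanges::overlapsAny(q, mask)
}

## ---------------------------------------------------------------------------
## Candidate tables
## ---------------------------------------------------------------------------

#' Write candidate DNMs to disk
#'
#' TSV output has one row per candidate with full filter provenance columns;
#' VCF output carries the provenance in INFO. A run with zero candidates
#' yields a header-only file.
#'
#' @param candidates candidate table (\code{DataFrame}/data.frame) as
#'   returned by \code{\link{runPipeline}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @export
writeCandidates <- function(candidates, path, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    df <- as.data.frame(candidates)
    if (format == "tsv") {
        utils::write.table(df, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        hdr <- c("##fileformat=VCFv4.2",
                 "##INFO=<ID=PROV,Number=1,Type=String,Description=\"Filter provenance\">",
                 "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Candidate status\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
        rows <- character(0)
        if (nrow(df) > 0) {
            prov <- .provenanceString(df)
            rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tPROV=%s;STATUS=%s",
                            df$chrom, df$pos, df$ref, df$alt, prov, df$status)
        }
        writeLines(c(hdr, rows), path)
    }
    invisible(path)
}

.provenanceString <- function(df) {
    vcols <- grep("^pass_", names(df), value = TRUE)
    if (!length(vcols)) return(rep(".", nrow(df)))
    apply(df[vcols], 1, function(r)
        paste(sub("^pass_", "", vcols), ifelse(as.logical(r), "P", "F"),
              sep = ":", collapse = "|"))
}

#' Read back a TSV candidate table written by \code{writeCandidates}
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readCandidates <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = NA, comment.char = "")
}

#' Read a validation-outcome table
#'
#' Expects columns \code{chrom}, \code{pos}, \code{allele}, \code{status}
#' with status in \code{validated}, \code{failed}, \code{not_amplified},
#' \code{untested}.
#'
#' @param path path to a TSV.
#' @return data.frame.
#' @export
readValidationOutcomes <- function(path) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ok <- c("validated", "failed", "not_amplified", "untested")
    if (!all(tb$status %in% ok))
        stop("invalid validation status values: ",
             paste(setdiff(tb$status, ok), collapse = ", "))
    tb
}

## ---------------------------------------------------------------------------
## VCF writer (deterministic layout; used by the simulator and candidate IO)
## ---------------------------------------------------------------------------

#' Write trio genotype records as a VCF 4.2 file
#'
#' Emits a fixed, deterministic field layout (GT:DP:AD:GQ:PL plus ADF/ADR
#' and LQA when populated) so that identical records always produce
#' byte-identical files.
#'
#' @param x a \code{\linkS4class{TrioGenotypes}}.
#' @param path output path.
#' @export
writeTrioVcf <- function(x, path) {
    smp <- sampleIds(x)
    hasStrand <- any(vapply(x@geno, function(g) any(!is.na(g$adf)), TRUE))
    hasLqa <- any(vapply(x@geno, function(g) any(!is.na(g$lowq_ad_alt)), TRUE))
    fmtIds <- c("GT", "DP", "AD", "GQ", "PL",
                if (hasStrand) c("ADF", "ADR"), if (hasLqa) "LQA")
    hdr <- c("##fileformat=VCFv4.2",
             "##source=trioDNM",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
             "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">")
    if (hasStrand)
        hdr <- c(hdr,
                 "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allelic depths, forward strand\">",
                 "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allelic depths, reverse strand\">")
    if (hasLqa)
        hdr <- c(hdr,
                 "##FORMAT=<ID=LQA,Number=1,Type=Integer,Description=\"Alternative-allele count among low-quality reads\">")
    infoIds <- c("##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
                 "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
                 "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
                 "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio\">",
                 "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
                 "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
                 "##INFO=<ID=BaseQRankSum,Number=1,Type=Float,Description=\"Base quality rank sum\">")
    hdr <- c(hdr, infoIds,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", smp), collapse = "\t"))

    n <- length(x)
    if (n == 0) { writeLines(hdr, path); return(invisible(path)) }

    num <- function(v) ifelse(is.na(v), NA,
                              trimws(formatC(v, format = "g", digits = 6)))
    infoParts <- mapply(function(field, vc) {
        v <- x@info[[field]]
        ifelse(is.na(v), NA_character_, paste0(vc, "=", num(v)))
    }, names(.INFO_COLS)[-1], .INFO_COLS[-1], SIMPLIFY = FALSE)
    infoStr <- apply(do.call(cbind, infoParts), 1, function(r) {
        r <- r[!is.na(r)]
        if (length(r)) paste(r, collapse = ";") else "."
    })
    qualStr <- ifelse(is.na(x@info$qual), ".", num(x@info$qual))

    matStr <- function(m) {
        if (all(is.na(m))) return(rep(".", nrow(m)))
        apply(m, 1, function(r) {
            r <- r[!is.na(r)]
            if (!length(r)) "." else paste(as.integer(round(r)), collapse = ",")
        })
    }
    fmt <- paste(fmtIds, collapse = ":")
    sampleStr <- lapply(smp, function(s) {
        g <- x@geno[[s]]
        gt <- ifelse(is.na(g$gt1) | is.na(g$gt2), "./.",
                     paste0(g$gt1, "/", g$gt2))
        cols <- list(gt,
                     ifelse(is.na(g$dp), ".", as.character(g$dp)),
                     matStr(g$ad),
                     ifelse(is.na(g$gq), ".", as.character(as.integer(round(g$gq)))),
                     matStr(g$pl))
        if (hasStrand) cols <- c(cols, list(matStr(g$adf), matStr(g$adr)))
        if (hasLqa) cols <- c(cols, list(ifelse(is.na(g$lowq_ad_alt), ".",
                                                as.character(g$lowq_ad_alt))))
        do.call(paste, c(cols, sep = ":"))
    })
    body <- do.call(paste, c(list(x@chrom, x@pos, ".", x@ref, x@alt, qualStr,
                                  "PASS", infoStr, fmt), sampleStr,
                             sep = "\t"))
    con <- file(path, "wb")   # fixed EOL for byte-identical output
    on.exit(close(con))
    writeLines(c(hdr, body), con, sep = "\n")
    invisible(path)
}
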