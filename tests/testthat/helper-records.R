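## Shared fixtures, all built in code.

TRIO <- list(father = "father", mother = "mother", child = "child")

## Compact builder: one biallelic site per row, calls given as
## "gt|dp|adref,adalt|gq" strings (NA fields allowed as ".").
toyRecords <- function(sites) {
    n <- nrow(sites)
    parseCalls <- function(txt) {
        parts <- strsplit(txt, "|", fixed = TRUE)
        gt <- vapply(parts, `[`, "", 1)
        gtp <- strsplit(gt, "/", fixed = TRUE)
        num <- function(i) suppressWarnings(as.numeric(
            vapply(parts, `[`, "", i)))
        ad <- strsplit(vapply(parts, `[`, "", 3), ",", fixed = TRUE)
        list(gt1 = suppressWarnings(as.integer(vapply(gtp, `[`, "", 1))),
             gt2 = suppressWarnings(as.integer(vapply(gtp, `[`, "", 2))),
             dp = as.integer(num(2)),
             ad = cbind(suppressWarnings(as.numeric(vapply(ad, `[`, "", 1))),
                        suppressWarnings(as.numeric(vapply(ad, function(x)
                            if (length(x) > 1) x[2] else NA_character_, "")))),
             gq = num(4))
    }
    geno <- list(father = parseCalls(sites$father),
                 mother = parseCalls(sites$mother),
                 child = parseCalls(sites$child))
    info <- sites[intersect(names(sites),
                            c("qual", "qd", "mq", "fs", "sor", "mq_rank_sum",
                              "read_pos_rank_sum", "base_q_rank_sum"))]
    TrioGenotypes(chrom = if (!is.null(sites$chrom)) sites$chrom
                  else rep("1", n),
                  pos = sites$pos, ref = sites$ref, alt = sites$alt,
                  info = if (ncol(info)) info else NULL, geno = geno)
}

## a site row with sensible defaults
site <- function(pos, father, mother, child, ref = "A", alt = "G",
                 chrom = "1", ...) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               father = father, mother = mother, child = child, ...,
               stringsAsFactors = FALSE)
}

## a completely permissive configuration (no filters, all chromosomes)
permissiveConfig <- function(...)
    filterConfig(exclude_chroms = character(0), ...)

candidateKeys <- function(cand) paste(cand$chrom, cand$pos, cand$alt)
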