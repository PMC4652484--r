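#' @include AllClasses.R
NULL

#' Describe repeat families to plant in a synthetic genome
#'
#' Builds the repeat specification consumed by [generateReference()]. Each
#' of the `n` families is an independently drawn block planted `copies`
#' times. `collapse = "ct"` makes the copies differ only at positions where
#' one copy has a C and the other a T, so the copies are distinguishable as
#' plain DNA but become identical after C-to-T bisulfite collapse (the
#' mechanism by which conversion creates ambiguous mappings); `"ga"` is the
#' strand-symmetric G/A analogue; `"none"` plants verbatim copies.
#'
#' @param n number of repeat families.
#' @param length block length in bp.
#' @param copies copies planted per family (>= 2).
#' @param collapse `"none"`, `"ct"` or `"ga"`.
#' @param gc GC fraction used to draw the block (`NA` = inherit the genome's).
#' @param nDiff for collapsing repeats, the number of diagnostic positions at
#'   which the copies differ before conversion.
#' @return a `data.frame` with one row per family, suitable for the
#'   `repeatSpec` argument of [generateReference()].
#' @examples
#' rbind(repeatSpec(2, 60), repeatSpec(1, 120, collapse = "ct"))
#' @export
repeatSpec <- function(n = 1L, length = 60L, copies = 2L,
                       collapse = c("none", "ct", "ga"), gc = NA_real_,
                       nDiff = 2L) {
    collapse <- match.arg(collapse)
    if (length < 1L || copies < 2L || nDiff < 1L)
        stop("malformed repeat specification")
    data.frame(length = as.integer(length), copies = as.integer(copies),
               collapse = collapse, gc = gc, nDiff = as.integer(nDiff))[
                   rep(1L, n), , drop = FALSE]
}

drawBases <- function(n, gc) {
    sample(BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic reference genome
#'
#' Draws a single random sequence with the requested GC fraction and
#' optionally plants repeat families (see [repeatSpec()]) so that ambiguous
#' mappings can occur. Planted copies are placed at non-overlapping
#' positions; their coordinates are recorded in
#' `S4Vectors::metadata(x)$repeats` (0-based half-open).
#'
#' @param length genome length in bp (>= 1).
#' @param gcFraction GC content in `[0, 1]`. Default 0.42, a typical
#'   mammalian value.
#' @param repeatSpec `NULL` or a `data.frame` from [repeatSpec()].
#' @param seed integer seed; identical seeds give identical genomes.
#' @param name sequence name.
#' @return a [ReferenceGenome-class] with one record.
#' @examples
#' generateReference(1000, seed = 1)
#' @export
generateReference <- function(length, gcFraction = 0.42, repeatSpec = NULL,
                              seed = NULL, name = "chr1") {
    if (!is.numeric(length) || length < 1)
        stop("'length' must be a positive number of bases")
    length <- as.integer(length)
    checkProb(gcFraction, "gcFraction")
    withSeed(seed, {
        v <- drawBases(length, gcFraction)
        repInfo <- NULL
        if (!is.null(repeatSpec)) {
            if (!is.data.frame(repeatSpec) ||
                !all(c("length", "copies", "collapse") %in% names(repeatSpec)))
                stop("'repeatSpec' must come from repeatSpec()")
            total <- sum(repeatSpec$length * repeatSpec$copies)
            if (any(repeatSpec$length > length) || total > length)
                stop("repeat specification does not fit in the genome")
            occupied <- logical(length)
            rows <- list()
            for (fam in seq_len(nrow(repeatSpec))) {
                spec <- repeatSpec[fam, ]
                gc <- if (is.na(spec$gc)) gcFraction else spec$gc
                block <- drawBases(spec$length, gc)
                copies <- replicate(spec$copies, block, simplify = FALSE)
                if (spec$collapse != "none") {
                    from <- if (spec$collapse == "ct") "C" else "G"
                    to <- if (spec$collapse == "ct") "T" else "A"
                    dpos <- sample(spec$length, min(spec$nDiff, spec$length))
                    block[dpos] <- from   # ensure diagnostic sites exist
                    copies <- lapply(seq_len(spec$copies), function(j) {
                        b <- block
                        # every copy after the first carries the converted
                        # base at the diagnostic sites
                        if (j > 1L) b[dpos] <- to
                        b
                    })
                }
                for (j in seq_len(spec$copies)) {
                    placed <- FALSE
                    for (try in seq_len(2000L)) {
                        st <- sample.int(length - spec$length + 1L, 1L)
                        span <- st:(st + spec$length - 1L)
                        if (!any(occupied[span])) {
                            v[span] <- copies[[j]]
                            occupied[span] <- TRUE
                            rows[[length(rows) + 1L]] <- data.frame(
                                family = fam, copy = j, start = st - 1L,
                                end = st - 1L + spec$length,
                                collapse = spec$collapse)
                            placed <- TRUE
                            break
                        }
                    }
                    if (!placed)
                        stop("could not place repeats without overlap; ",
                             "reduce repeat load or enlarge the genome")
                }
            }
            repInfo <- do.call(rbind, rows)
        }
        gen <- ReferenceGenome(setNames(paste(v, collapse = ""), name))
        S4Vectors::metadata(gen)$repeats <- repInfo
        gen
    })
}

#' Generate a methylome for a reference genome
#'
#' Assigns a methylation state to every cytosine on both strands. A cytosine
#' in CpG context is methylated with probability `pCpG`, any other cytosine
#' with probability `pCpH`. The Crick-strand partner of a Watson CpG copies
#' the Watson call except with probability `hemimethylationRate` (default 0:
#' fully symmetric CpG methylation).
#'
#' @param ref a [ReferenceGenome-class].
#' @param pCpG,pCpH methylation probabilities. Defaults 0.8 and 0.02, the
#'   rates typical of mammalian somatic genomes.
#' @param hemimethylationRate probability that a Crick CpG call disagrees
#'   with its Watson partner.
#' @param seed integer seed.
#' @return a [Methylome-class].
#' @examples
#' ref <- generateReference(500, seed = 1)
#' generateMethylome(ref, seed = 2)
#' @export
generateMethylome <- function(ref, pCpG = 0.8, pCpH = 0.02,
                              hemimethylationRate = 0, seed = NULL) {
    stopifnot(methods::is(ref, "ReferenceGenome"))
    checkProb(pCpG, "pCpG"); checkProb(pCpH, "pCpH")
    checkProb(hemimethylationRate, "hemimethylationRate")
    withSeed(seed, {
        states <- lapply(names(ref), function(nm) {
            v <- s1chars(as.character(ref[[nm]]))
            L <- length(v)
            isC <- v == "C"
            isG <- v == "G"
            nextG <- c(v[-1L] == "G", FALSE)
            prevC <- c(FALSE, v[-L] == "C")
            wPos <- which(isC)
            wCtx <- ifelse(nextG[wPos], "CpG", "CpH")
            cPos <- which(isG)
            cCtx <- ifelse(prevC[cPos], "CpG", "CpH")
            wMeth <- runif(length(wPos)) < ifelse(wCtx == "CpG", pCpG, pCpH)
            cMeth <- runif(length(cPos)) < pCpH
            cgIdx <- which(cCtx == "CpG")
            if (length(cgIdx)) {
                # partner Watson C sits one base to the left
                partner <- match(cPos[cgIdx] - 1L, wPos)
                flip <- runif(length(cgIdx)) < hemimethylationRate
                cMeth[cgIdx] <- xor(wMeth[partner], flip)
            }
            data.frame(
                seqname = rep(nm, length(wPos) + length(cPos)),
                pos = c(wPos, cPos) - 1L,
                strand = rep(c("watson", "crick"), c(length(wPos), length(cPos))),
                context = c(wCtx, cCtx),
                methylated = c(wMeth, cMeth))
        })
        methods::new("Methylome", states = do.call(rbind, states))
    })
}

normaliseLengthDist <- function(lengthDistribution) {
    lens <- as.integer(names(lengthDistribution))
    if (anyNA(lens) || any(lens < 1L))
        stop("'lengthDistribution' must be named by positive integer lengths")
    p <- as.numeric(lengthDistribution)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
        stop("'lengthDistribution' proportions must be non-negative and sum to 1")
    list(lens = lens, p = p / sum(p))
}

#' Sample genomic fragments
#'
#' Draws fragments uniformly over all valid start positions of the
#' reference, with lengths drawn from `lengthDistribution`. The default
#' length mix (100 bp : 63.4%, 75 bp : 20%, 50 bp : 16.6%) mirrors a
#' hairpin sequencing lane dominated by full-length reads.
#'
#' @param ref a [ReferenceGenome-class].
#' @param n number of fragments.
#' @param lengthDistribution named numeric vector mapping fragment length to
#'   proportion; proportions must sum to 1.
#' @param seed integer seed.
#' @return a [GenomicRanges::GRanges] (1-based closed coordinates, Watson
#'   strand) with metadata column `seq`, the Watson-strand fragment
#'   sequence.
#' @examples
#' ref <- generateReference(5000, seed = 1)
#' sampleFragments(ref, 5, c(`50` = 1), seed = 2)
#' @export
sampleFragments <- function(ref, n,
                            lengthDistribution = c(`100` = 0.634, `75` = 0.2,
                                                   `50` = 0.166),
                            seed = NULL) {
    stopifnot(methods::is(ref, "ReferenceGenome"))
    ld <- normaliseLengthDist(lengthDistribution)
    widths <- Biostrings::width(ref)
    if (max(ld$lens) > min(widths))
        stop("a requested fragment length exceeds the shortest reference record")
    withSeed(seed, {
        lens <- ld$lens[sample.int(length(ld$lens), n, replace = TRUE, prob = ld$p)]
        # weight sequences by their number of valid starts for each length
        seqIdx <- vapply(lens, function(l) {
            w <- pmax(widths - l + 1L, 0L)
            sample.int(length(widths), 1L, prob = w)
        }, integer(1))
        starts <- vapply(seq_len(n), function(i) {
            sample.int(widths[seqIdx[i]] - lens[i] + 1L, 1L)
        }, integer(1))
        seqs <- as.character(Biostrings::subseq(
            ref[seqIdx], start = starts, width = lens))
        gr <- GenomicRanges::GRanges(
            seqnames = names(ref)[seqIdx],
            ranges = IRanges::IRanges(start = starts, width = lens),
            strand = rep("+", n))
        S4Vectors::mcols(gr)$seq <- unname(seqs)
        gr
    })
}

# methylation lookup vectors for one reference sequence: NA where the strand
# carries no C, TRUE/FALSE methylation elsewhere (Watson coords, 1-based).
methLookup <- function(meth, seqname, L) {
    st <- meth@states[meth@states$seqname == seqname, ]
    w <- rep(NA, L); cr <- rep(NA, L)
    sw <- st[st$strand == "watson", ]
    sc <- st[st$strand == "crick", ]
    w[sw$pos + 1L] <- sw$methylated
    cr[sc$pos + 1L] <- sc$methylated
    list(watson = w, crick = cr)
}

substituteBases <- function(v, positions) {
    for (p in positions) {
        v[p] <- sample(setdiff(BASES, v[p]), 1L)
    }
    v
}

#' Simulate hairpin bisulfite read pairs
#'
#' Applies bisulfite conversion to both strands of each fragment and emits
#' the two mates sequenced from the hairpin construct. The T-enriched mate
#' is the converted Watson strand (each unmethylated Watson C read as T with
#' probability `conversionRate`); the A-enriched mate is the converted Crick
#' strand, which in Watson coordinates turns a Watson G into an A wherever
#' the paired Crick C is unmethylated, and is stored reverse-complemented
#' (the delivered paired-end orientation). Independent per-base substitution
#' errors are then applied to each mate.
#'
#' @param fragments a `GRanges` from [sampleFragments()].
#' @param meth a [Methylome-class] covering the fragments.
#' @param conversionRate probability that an unmethylated C is converted
#'   (default 1: complete conversion).
#' @param errorRate substitution error probability per base per mate.
#'   Default 0.002, which leaves roughly 68% of 100 bp pairs free of
#'   detectable errors.
#' @param seed integer seed.
#' @param idPrefix prefix for generated pair ids.
#' @return a [HairpinPairSet-class] with a truth table.
#' @examples
#' ref <- generateReference(2000, seed = 1)
#' meth <- generateMethylome(ref, seed = 2)
#' frags <- sampleFragments(ref, 3, c(`50` = 1), seed = 3)
#' makeHairpinPairs(frags, meth, seed = 4)
#' @export
makeHairpinPairs <- function(fragments, meth, conversionRate = 1,
                             errorRate = 0.002, seed = NULL,
                             idPrefix = "pair") {
    stopifnot(methods::is(fragments, "GRanges"), methods::is(meth, "Methylome"))
    checkProb(conversionRate, "conversionRate")
    checkProb(errorRate, "errorRate")
    n <- length(fragments)
    seqn <- as.character(GenomicRanges::seqnames(fragments))
    lookups <- list()
    seqLens <- integer()
    withSeed(seed, {
        tOut <- character(n); aOut <- character(n)
        tErr <- character(n); aErr <- character(n)
        methStr <- character(n)
        for (i in seq_len(n)) {
            nm <- seqn[i]
            if (is.null(lookups[[nm]])) {
                L <- max(GenomicRanges::end(fragments)[seqn == nm])
                st <- meth@states[meth@states$seqname == nm, ]
                if (nrow(st)) L <- max(L, max(st$pos) + 1L)
                lookups[[nm]] <- methLookup(meth, nm, L)
            }
            lk <- lookups[[nm]]
            from <- GenomicRanges::start(fragments)[i]
            to <- GenomicRanges::end(fragments)[i]
            v <- s1chars(S4Vectors::mcols(fragments)$seq[i])
            len <- length(v)
            w <- lk$watson[from:to]
            cr <- lk$crick[from:to]
            if (any(v == "C" & is.na(w)) || any(v == "G" & is.na(cr)))
                stop("methylome does not cover fragment ", i)
            tv <- v
            convW <- v == "C" & !is.na(w) & !w & runif(len) <= conversionRate
            tv[convW] <- "T"
            av <- v
            convC <- v == "G" & !is.na(cr) & !cr & runif(len) <= conversionRate
            av[convC] <- "A"
            aDel <- rev(complementChars(av))
            tErrPos <- which(runif(len) < errorRate)
            aErrPos <- which(runif(len) < errorRate)
            tv <- substituteBases(tv, tErrPos)
            aDel <- substituteBases(aDel, aErrPos)
            ms <- rep(".", len)
            ms[v == "C"] <- ifelse(w[v == "C"], "M", "U")
            ms[v == "G"] <- ifelse(cr[v == "G"], "m", "u")
            tOut[i] <- paste(tv, collapse = "")
            aOut[i] <- paste(aDel, collapse = "")
            tErr[i] <- paste(tErrPos - 1L, collapse = ";")
            aErr[i] <- paste(aErrPos - 1L, collapse = ";")
            methStr[i] <- paste(ms, collapse = "")
        }
        truth <- data.frame(
            pairId = sprintf("%s%05d", idPrefix, seq_len(n)),
            seqname = seqn,
            start = GenomicRanges::start(fragments) - 1L,
            end = GenomicRanges::end(fragments),
            strand = rep("watson", n),
            tErrorPos = tErr, aErrorPos = aErr, methString = methStr)
        HairpinPairSet(truth$pairId, tOut, aOut, truth)
    })
}

#' Inject detectable substitution errors into one side of the mates
#'
#' Places exactly `k` substitutions per pair into the chosen mate, confined
#' to overlap offsets below (`side = "left"`) or at/above (`side =
#' "right"`) the boundary, choosing replacement bases that land on the
#' error cell of the hairpin rule table so the recovery step flags them.
#' Used to construct the mismatch-location strata under controlled error
#' placement.
#'
#' @param pairs a [HairpinPairSet-class] (typically simulated error-free).
#' @param k number of errors per pair.
#' @param side `"left"` or `"right"` of the boundary.
#' @param boundary overlap offset (0-based) splitting the two sides;
#'   default 25.
#' @param mate which mate receives the substitutions (default the
#'   T-enriched one).
#' @param seed integer seed.
#' @return a new [HairpinPairSet-class]; truth (if present) is dropped.
#' @export
injectReadErrors <- function(pairs, k, side = c("left", "right"),
                             boundary = 25L, mate = c("t", "a"),
                             seed = NULL) {
    side <- match.arg(side); mate <- match.arg(mate)
    stopifnot(methods::is(pairs, "HairpinPairSet"), k >= 1L)
    withSeed(seed, {
        tv <- pairs@tRead; av <- pairs@aRead
        for (i in seq_along(tv)) {
            len <- min(nchar(tv[i]), nchar(av[i]))
            region <- if (side == "left") seq_len(min(boundary, len)) else
                seq.int(boundary + 1L, len)
            if (length(region) < k)
                stop("side region shorter than k for pair ", i)
            t1 <- s1chars(tv[i]); a1 <- s1chars(av[i])
            aw <- rev(complementChars(a1))[seq_len(len)]
            pos <- sample(region, k)
            for (p in pos) {
                if (mate == "t") {
                    cand <- setdiff(BASES, t1[p])
                    # pick a replacement that classifies as an error cell
                    ok <- cand[vapply(cand, function(b)
                        !(b == aw[p] || (b == "T" && aw[p] == "C") ||
                          (b == "G" && aw[p] == "A")), logical(1))]
                    t1[p] <- ok[1L]
                } else {
                    cand <- setdiff(BASES, aw[p])
                    ok <- cand[vapply(cand, function(b)
                        !(b == t1[p] || (t1[p] == "T" && b == "C") ||
                          (t1[p] == "G" && b == "A")), logical(1))]
                    aw[p] <- ok[1L]
                    a1 <- rev(complementChars(aw))
                }
            }
            tv[i] <- paste(t1, collapse = "")
            av[i] <- paste(a1, collapse = "")
        }
        HairpinPairSet(pairs@pairId, tv, av, NULL)
    })
}

#' Simulate single-end bisulfite reads
#'
#' Draws fragments, picks a strand uniformly at random for each
#' (non-directional library), applies bisulfite conversion according to the
#' methylome and substitution errors at `errorRate`, and returns the reads
#' with a truth table of origins. Crick-strand reads are delivered 5'-to-3'
#' on the Crick strand (i.e. reverse-complemented Watson coordinates).
#'
#' @inheritParams sampleFragments
#' @inheritParams makeHairpinPairs
#' @param errorRate substitution error probability per base. The simulation
#'   study uses 0.01 and 0.10.
#' @return list with elements `reads` (named character vector) and `truth`
#'   (`data.frame` with `readId`, `seqname`, `start`, `end` 0-based
#'   half-open, `strand`).
#' @examples
#' ref <- generateReference(2000, seed = 1)
#' meth <- generateMethylome(ref, seed = 2)
#' simulateBisulfiteReads(ref, meth, 4, c(`50` = 1), errorRate = 0.01, seed = 3)
#' @export
simulateBisulfiteReads <- function(ref, meth, n,
                                   lengthDistribution = c(`100` = 0.634,
                                                          `75` = 0.2,
                                                          `50` = 0.166),
                                   errorRate = 0.01, conversionRate = 1,
                                   seed = NULL, idPrefix = "simread") {
    stopifnot(methods::is(ref, "ReferenceGenome"), methods::is(meth, "Methylome"))
    checkProb(errorRate, "errorRate")
    checkProb(conversionRate, "conversionRate")
    withSeed(seed, {
        frags <- sampleFragments(ref, n, lengthDistribution, seed = NULL)
        seqn <- as.character(GenomicRanges::seqnames(frags))
        lookups <- lapply(setNames(names(ref), names(ref)), function(nm)
            methLookup(meth, nm, Biostrings::width(ref)[names(ref) == nm]))
        strand <- sample(c("watson", "crick"), n, replace = TRUE)
        reads <- character(n)
        for (i in seq_len(n)) {
            lk <- lookups[[seqn[i]]]
            from <- GenomicRanges::start(frags)[i]
            to <- GenomicRanges::end(frags)[i]
            v <- s1chars(S4Vectors::mcols(frags)$seq[i])
            len <- length(v)
            if (strand[i] == "watson") {
                w <- lk$watson[from:to]
                conv <- v == "C" & !is.na(w) & !w & runif(len) <= conversionRate
                v[conv] <- "T"
            } else {
                cr <- lk$crick[from:to]
                conv <- v == "G" & !is.na(cr) & !cr & runif(len) <= conversionRate
                v[conv] <- "A"
                v <- rev(complementChars(v))
            }
            v <- substituteBases(v, which(runif(len) < errorRate))
            reads[i] <- paste(v, collapse = "")
        }
        ids <- sprintf("%s%05d", idPrefix, seq_len(n))
        list(reads = setNames(reads, ids),
             truth = data.frame(readId = ids, seqname = seqn,
                                start = GenomicRanges::start(frags) - 1L,
                                end = GenomicRanges::end(frags),
                                strand = strand))
    })
}
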