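#' @include AllClasses.R
NULL

# Views of the reference searched by the mapper, in a fixed canonical order.
# Bisulfite mode: the C->T and G->A conversions of the Watson strand text
# and of its reverse complement; a non-directional bisulfite read matches
# exactly one of the four with no conversion-induced mismatches. Plain mode:
# the two unconverted strands. Crick-view texts are stored in Crick
# coordinates; positions are translated back to Watson starts when scoring.
genomeViews <- function(ref, mode) {
    seqs <- setNames(as.character(ref), names(ref))
    rc <- setNames(revComp(seqs), names(ref))
    if (mode == "bisulfite") {
        list(
            list(label = "CT_watson", strand = "watson", conversion = "CT",
                 seqs = convertCT(seqs)),
            list(label = "GA_watson", strand = "watson", conversion = "GA",
                 seqs = convertGA(seqs)),
            list(label = "CT_crick", strand = "crick", conversion = "CT",
                 seqs = convertCT(rc)),
            list(label = "GA_crick", strand = "crick", conversion = "GA",
                 seqs = convertGA(rc)))
    } else {
        list(
            list(label = "plain_watson", strand = "watson", conversion = "none",
                 seqs = seqs),
            list(label = "plain_crick", strand = "crick", conversion = "none",
                 seqs = rc))
    }
}

convertReads <- function(reads, conversion) {
    switch(conversion, CT = convertCT(reads), GA = convertGA(reads), reads)
}

#' Build a k-mer seed index over a reference genome
#'
#' Hashes every k-mer of every view (see [MapperIndex-class]) to its start
#' positions. In bisulfite mode the keys are drawn from the three-letter
#' alphabets ({A,G,T} after C-to-T, {A,C,T} after G-to-A).
#'
#' @param ref a [ReferenceGenome-class].
#' @param k seed length in bp; default 16 (the classic sliding-window width
#'   of hash-based bisulfite mappers).
#' @param mode `"bisulfite"` or `"plain"`.
#' @return a [MapperIndex-class].
#' @examples
#' idx <- buildMapperIndex(generateReference(200, seed = 1), k = 8)
#' @export
buildMapperIndex <- function(ref, k = 16L, mode = c("bisulfite", "plain")) {
    mode <- match.arg(mode)
    stopifnot(methods::is(ref, "ReferenceGenome"))
    k <- as.integer(k)
    widths <- Biostrings::width(ref)
    if (k < 2L) stop("'k' must be at least 2")
    if (k > min(widths))
        stop("'k' exceeds the shortest reference record")
    views <- genomeViews(ref, mode)
    cum <- c(0L, cumsum(widths))
    for (vi in seq_along(views)) {
        allKmers <- character(0)
        allPos <- integer(0)
        for (si in seq_along(views[[vi]]$seqs)) {
            txt <- views[[vi]]$seqs[[si]]
            L <- nchar(txt)
            st <- seq_len(L - k + 1L)
            allKmers <- c(allKmers, substring(txt, st, st + k - 1L))
            allPos <- c(allPos, cum[si] + st)
        }
        views[[vi]]$env <- list2env(split(allPos, allKmers), hash = TRUE,
                                    size = length(allPos))
    }
    methods::new("MapperIndex", k = k, mode = mode, seqnames = names(ref),
                 seqlengths = as.integer(widths), views = views)
}

# Non-overlapping seed starts across the first `region` bases of a read.
seedStarts <- function(n, k, region = NULL) {
    region <- if (is.null(region)) n else min(region, n)
    if (region < k)
        stop("seed region shorter than the seed length")
    st <- seq.int(1L, region - k + 1L, by = k)
    last <- region - k + 1L
    if (st[length(st)] != last) st <- c(st, last)
    st
}

# Reduce candidate vectors (parallel: seqIdx, pos0, strand, conversion,
# score, view rank) to the per-read result: deduplicate by genomic location
# keeping the minimum score (ties broken by canonical view order), then take
# all locations at the best score. Shared *definition* used by both the seed
# mapper and the oracle.
reduceCandidates <- function(cand, thr, tieCap) {
    if (length(cand$score) == 0L) {
        return(list(category = "unmapped", score = NA_integer_, nBest = 0L,
                    loc = NULL))
    }
    key <- paste(cand$seqIdx, cand$pos, cand$strand, sep = "\r")
    ord <- order(key, cand$score, cand$rank, method = "radix")
    keep <- ord[!duplicated(key[ord])]
    score <- cand$score[keep]
    best <- min(score)
    keep <- keep[score == best]
    o2 <- order(cand$seqIdx[keep], cand$pos[keep], cand$strand[keep],
                method = "radix")
    keep <- keep[o2]
    nBest <- length(keep)
    if (nBest > tieCap) keep <- keep[seq_len(tieCap)]
    list(category = if (nBest == 1L) "unique" else "ambiguous",
         score = as.integer(best), nBest = as.integer(nBest),
         loc = list(seqIdx = cand$seqIdx[keep], pos = cand$pos[keep],
                    strand = cand$strand[keep],
                    conversion = cand$conversion[keep]))
}

# Assemble the per-read reductions into a MapResults object.
assembleResults <- function(readIds, reductions, seqnames, params) {
    if (is.null(readIds)) readIds <- character(0)
    readDf <- data.frame(
        readId = readIds,
        category = vapply(reductions, `[[`, character(1), "category"),
        score = vapply(reductions, `[[`, integer(1), "score"),
        nBest = vapply(reductions, `[[`, integer(1), "nBest"))
    locs <- lapply(reductions, `[[`, "loc")
    hasLoc <- !vapply(locs, is.null, logical(1))
    locDf <- if (any(hasLoc)) {
        nLoc <- vapply(locs[hasLoc], function(l) length(l$pos), integer(1))
        data.frame(
            readId = rep(readIds[hasLoc], nLoc),
            seqname = seqnames[unlist(lapply(locs[hasLoc], `[[`, "seqIdx"),
                                      use.names = FALSE)],
            pos = unlist(lapply(locs[hasLoc], `[[`, "pos"),
                         use.names = FALSE),
            strand = unlist(lapply(locs[hasLoc], `[[`, "strand"),
                            use.names = FALSE),
            conversion = unlist(lapply(locs[hasLoc], `[[`, "conversion"),
                                use.names = FALSE))
    } else emptyLocations()
    rownames(readDf) <- NULL; rownames(locDf) <- NULL
    methods::new("MapResults", reads = readDf, locations = locDf,
                 params = params)
}

emptyLocations <- function() {
    data.frame(readId = character(), seqname = character(), pos = integer(),
               strand = character(), conversion = character())
}

#' Map a batch of reads with the seed-and-extend mapper
#'
#' For each read, candidate locations are collected from exact hits of
#' non-overlapping k-mer seeds against every index view, scored by Hamming
#' mismatch count between the converted read and the converted reference
#' window, and categorised as unique / ambiguous / unmapped. A location
#' reachable under both conversions counts once (the minimum score is
#' kept). `N` in a read mismatches everything. The mismatch threshold is
#' `floor(maxMismatchFraction * length)`.
#'
#' With default full-read seeding, any location with fewer mismatches than
#' the number of seeds is guaranteed to be found (pigeonhole). `seedRegion`
#' restricts seeding to the first so-many bases of the read, emulating
#' end-anchored seed heuristics of production aligners; sensitivity then
#' depends on the 5' end being error-free.
#'
#' @param index a [MapperIndex-class].
#' @param reads named character vector of reads (each at least `k` long).
#' @param maxMismatchFraction mismatch threshold as a fraction of read
#'   length; default 0.1.
#' @param seedRegion `NULL` (seed across the whole read) or the number of
#'   5' bases seeds are drawn from.
#' @param tieCap best locations retained per read; reads with more
#'   equal-best locations are ambiguous with `nBest` recording the full
#'   count.
#' @return a [MapResults-class].
#' @examples
#' ref <- generateReference(500, seed = 1)
#' idx <- buildMapperIndex(ref, k = 12, mode = "plain")
#' mapReads(idx, c(r1 = substr(as.character(ref[[1]]), 11, 60)))
#' @export
mapReads <- function(index, reads, maxMismatchFraction = 0.1,
                     seedRegion = NULL, tieCap = 100L) {
    stopifnot(methods::is(index, "MapperIndex"))
    if (is.null(names(reads)) && length(reads))
        names(reads) <- sprintf("read%05d", seq_along(reads))
    reads <- toupper(reads)
    k <- index@k
    if (any(nchar(reads) < k))
        stop("every read must be at least as long as the seed length k")
    lens <- index@seqlengths
    cum <- c(0L, cumsum(lens))
    nviews <- length(index@views)
    qcache <- lapply(index@views, function(v) convertReads(reads, v$conversion))
    reductions <- vector("list", length(reads))
    for (i in seq_along(reads)) {
        n <- nchar(reads[[i]])
        thr <- floor(maxMismatchFraction * n)
        starts <- seedStarts(n, k, seedRegion)
        cSeq <- integer(0); cPos <- integer(0); cStr <- character(0)
        cConv <- character(0); cScore <- integer(0); cRank <- integer(0)
        for (vi in seq_len(nviews)) {
            view <- index@views[[vi]]
            q <- qcache[[vi]][[i]]
            kmers <- substring(q, starts, starts + k - 1L)
            hits <- mget(kmers, envir = view$env, ifnotfound = list(integer(0)))
            cand <- unlist(hits, use.names = FALSE) -
                rep(starts - 1L, lengths(hits))
            if (!length(cand)) next
            cand <- unique(cand[cand >= 1L])
            if (!length(cand)) next
            seqIdx <- findInterval(cand - 0.5, cum)
            local <- cand - cum[seqIdx]
            ok <- local + n - 1L <= lens[seqIdx]
            seqIdx <- seqIdx[ok]; local <- local[ok]
            if (!length(local)) next
            scores <- integer(length(local))
            for (si in unique(seqIdx)) {
                sel <- seqIdx == si
                scores[sel] <- .hammingAt(view$seqs[[si]], q, local[sel], thr)
            }
            keep <- scores <= thr
            if (!any(keep)) next
            local <- local[keep]; seqIdx <- seqIdx[keep]
            scores <- scores[keep]
            pos0 <- if (view$strand == "watson") local - 1L
                    else lens[seqIdx] - local - n + 1L
            m <- length(pos0)
            cSeq <- c(cSeq, seqIdx); cPos <- c(cPos, pos0)
            cStr <- c(cStr, rep(view$strand, m))
            cConv <- c(cConv, rep(view$conversion, m))
            cScore <- c(cScore, scores); cRank <- c(cRank, rep(vi, m))
        }
        reductions[[i]] <- reduceCandidates(
            list(seqIdx = cSeq, pos = cPos, strand = cStr, conversion = cConv,
                 score = cScore, rank = cRank), thr, tieCap)
    }
    assembleResults(names(reads), reductions, index@seqnames,
                    list(mode = index@mode, k = k,
                         maxMismatchFraction = maxMismatchFraction,
                         seedRegion = seedRegion, tieCap = tieCap))
}

#' Map a single read
#'
#' Convenience wrapper around [mapReads()] for one read.
#'
#' @inheritParams mapReads
#' @param read a single read sequence.
#' @param readId identifier used in the result.
#' @return a [MapResults-class] with one row.
#' @export
mapRead <- function(index, read, maxMismatchFraction = 0.1, seedRegion = NULL,
                    tieCap = 100L, readId = "read1") {
    mapReads(index, setNames(read, readId), maxMismatchFraction,
             seedRegion, tieCap)
}

#' Brute-force mapping oracle
#'
#' Scores the read at every position of every strand and conversion view of
#' the reference, with the same scoring and category rules as [mapReads()]
#' but no seeding heuristic. Quadratic cost; intended as the correctness
#' oracle for the seed mapper and for resolving genuinely repeated origins.
#'
#' @param ref a [ReferenceGenome-class].
#' @param read a single read sequence (no longer than any reference
#'   record).
#' @param mode `"bisulfite"` or `"plain"`.
#' @inheritParams mapReads
#' @param readId identifier used in the result.
#' @return a [MapResults-class] with one row.
#' @export
bruteForceMap <- function(ref, read, mode = c("bisulfite", "plain"),
                          maxMismatchFraction = 0.1, tieCap = 100L,
                          readId = "read1") {
    bruteForceMapReads(ref, setNames(read, readId), mode,
                       maxMismatchFraction, tieCap)
}

#' Brute-force mapping oracle, batch form
#'
#' [bruteForceMap()] over a read vector, computing the genome views once.
#'
#' @inheritParams bruteForceMap
#' @param reads named character vector of reads.
#' @return a [MapResults-class].
#' @export
bruteForceMapReads <- function(ref, reads, mode = c("bisulfite", "plain"),
                               maxMismatchFraction = 0.1, tieCap = 100L) {
    mode <- match.arg(mode)
    stopifnot(methods::is(ref, "ReferenceGenome"))
    if (is.null(names(reads)) && length(reads))
        names(reads) <- sprintf("read%05d", seq_along(reads))
    reads <- toupper(reads)
    lens <- Biostrings::width(ref)
    if (length(reads) && max(nchar(reads)) > min(lens))
        stop("read is longer than a reference record")
    views <- genomeViews(ref, mode)
    qcache <- lapply(views, function(v) convertReads(reads, v$conversion))
    reductions <- vector("list", length(reads))
    for (i in seq_along(reads)) {
        n <- nchar(reads[[i]])
        thr <- floor(maxMismatchFraction * n)
        cSeq <- integer(0); cPos <- integer(0); cStr <- character(0)
        cConv <- character(0); cScore <- integer(0); cRank <- integer(0)
        for (vi in seq_along(views)) {
            view <- views[[vi]]
            q <- qcache[[vi]][[i]]
            for (si in seq_along(lens)) {
                hit <- .hammingScan(view$seqs[[si]], q, thr)
                if (!length(hit$start)) next
                pos0 <- if (view$strand == "watson") hit$start - 1L
                        else lens[si] - hit$start - n + 1L
                m <- length(pos0)
                cSeq <- c(cSeq, rep(si, m)); cPos <- c(cPos, pos0)
                cStr <- c(cStr, rep(view$strand, m))
                cConv <- c(cConv, rep(view$conversion, m))
                cScore <- c(cScore, hit$score); cRank <- c(cRank, rep(vi, m))
            }
        }
        reductions[[i]] <- reduceCandidates(
            list(seqIdx = cSeq, pos = cPos, strand = cStr, conversion = cConv,
                 score = cScore, rank = cRank), thr, tieCap)
    }
    assembleResults(names(reads), reductions, names(ref),
                    list(mode = mode, k = NA_integer_,
                         maxMismatchFraction = maxMismatchFraction,
                         seedRegion = NULL, tieCap = tieCap))
}
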