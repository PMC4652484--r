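#' @include AllClasses.R
NULL

# The hairpin rule table. Rows: T-enriched base, columns: A-enriched base
# (both in Watson orientation). A (T,C) column pair marks a converted
# unmethylated Watson C; (G,A) the converted unmethylated Crick C; equal
# bases agree; every other combination can only arise from PCR or
# sequencing error.
classifyCell <- function(t, a) {
    ifelse(t == a, "match",
    ifelse(t == "T" & a == "C", "bisulfite_C",
    ifelse(t == "G" & a == "A", "bisulfite_G", "error")))
}

#' Orient a mate pair into Watson coordinates
#'
#' Reverse-complements the delivered A-enriched mate and truncates both
#' mates to their common length from the shared 5' anchor.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param swapMates set `TRUE` if the input files had the mates mislabeled
#'   (the A-enriched read in R1); the roles are exchanged before orienting.
#' @return list with character vectors `t` and `a`, both in Watson
#'   orientation and of equal per-pair length.
#' @export
orientPairs <- function(pairs, swapMates = FALSE) {
    stopifnot(methods::is(pairs, "HairpinPairSet"))
    t <- pairs@tRead
    a <- pairs@aRead
    if (swapMates) { tmp <- t; t <- a; a <- tmp }
    if (any(nchar(t) == 0L) || any(nchar(a) == 0L))
        stop("empty mate sequence")
    aw <- revComp(a)
    len <- pmin(nchar(t), nchar(aw))
    list(t = setNames(substr(t, 1L, len), pairs@pairId),
         a = setNames(substr(aw, 1L, len), pairs@pairId))
}

#' Classify every overlap position of an oriented mate pair
#'
#' @param tSeq,aSeq equal-length sequences in Watson orientation (the
#'   T-enriched mate and the reverse-complemented A-enriched mate).
#' @return character vector of per-offset labels among `match`,
#'   `bisulfite_C` (T over C), `bisulfite_G` (G over A) and `error`.
#' @examples
#' classifyPositions("ATGT", "ATAC")
#' @export
classifyPositions <- function(tSeq, aSeq) {
    if (length(tSeq) != 1L || length(aSeq) != 1L)
        stop("classifyPositions works on a single oriented pair")
    if (nchar(tSeq) != nchar(aSeq))
        stop("oriented mates must have equal length")
    classifyCell(s1chars(tSeq), s1chars(aSeq))
}

#' Recover original sequences from hairpin mate pairs
#'
#' Applies the hairpin rule table position by position: matching bases are
#' kept, a T over a C recovers an (unmethylated Watson) C, a G over an A
#' recovers an (unmethylated Crick partner) G, and any other disagreement is
#' flagged as an error. Methylation is called wherever a cytosine survives
#' or is recovered: (C,C) a methylated Watson C, (T,C) unmethylated Watson,
#' (G,G) methylated Crick, (G,A) unmethylated Crick.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param errorBase base written at flagged error positions: `"N"`
#'   (default, keeps downstream mapping honest) or `"t"` to take the
#'   T-enriched mate's base.
#' @param swapMates passed to [orientPairs()].
#' @return a [RecoveredReadSet-class].
#' @examples
#' p <- HairpinPairSet("p1", "ATGT", revComp("ATAC"))
#' recoveredSeqs(recoverPairs(p))
#' @export
recoverPairs <- function(pairs, errorBase = c("N", "t"), swapMates = FALSE) {
    errorBase <- match.arg(errorBase)
    ori <- orientPairs(pairs, swapMates = swapMates)
    n <- length(ori$t)
    seqs <- character(n)
    errs <- vector("list", n)
    callList <- vector("list", n)
    tChars <- strsplit(ori$t, "", fixed = TRUE)
    aChars <- strsplit(ori$a, "", fixed = TRUE)
    for (i in seq_len(n)) {
        tv <- tChars[[i]]; av <- aChars[[i]]
        out <- tv
        isErr <- !(tv == av | (tv == "T" & av == "C") | (tv == "G" & av == "A"))
        out[tv == "T" & av == "C"] <- "C"
        # (G,A) already reads G from the T-enriched mate
        out[isErr] <- if (errorBase == "N") "N" else tv[isErr]
        errs[[i]] <- which(isErr) - 1L
        watson <- (tv == "C" & av == "C") | (tv == "T" & av == "C")
        crick <- (tv == "G" & av == "G") | (tv == "G" & av == "A")
        off <- c(which(watson), which(crick)) - 1L
        if (length(off)) {
            callList[[i]] <- data.frame(
                pairId = pairs@pairId[i],
                offset = off,
                strand = rep(c("watson", "crick"),
                             c(sum(watson), sum(crick))),
                status = c(ifelse(tv[watson] == "C", "methylated", "unmethylated"),
                           ifelse(av[crick] == "G", "methylated", "unmethylated")))
        }
        seqs[i] <- paste(out, collapse = "")
    }
    callList <- callList[!vapply(callList, is.null, logical(1))]
    calls <- if (length(callList)) do.call(rbind, callList) else
        data.frame(pairId = character(), offset = integer(),
                   strand = character(), status = character())
    methods::new("RecoveredReadSet", pairId = pairs@pairId, sequence = seqs,
                 errorPositions = errs, methCalls = calls)
}

#' Keep only exactly-aligning pairs
#'
#' Returns the subset of pairs whose oriented mates satisfy the rule table
#' at every overlap position (zero error labels), i.e. pairs with no
#' detectable PCR or sequencing error. Order is preserved.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param recovered optionally, a precomputed [recoverPairs()] result for
#'   `pairs` (avoids recomputation).
#' @return the exactly-aligning subset, a [HairpinPairSet-class].
#' @export
filterExact <- function(pairs, recovered = NULL) {
    if (is.null(recovered)) recovered <- recoverPairs(pairs)
    stopifnot(identical(pairIds(recovered), pairIds(pairs)))
    pairs[lengths(recovered@errorPositions) == 0L]
}

#' Split pairs by the side of the read their errors fall on
#'
#' Selects pairs with exactly `k` flagged error positions and splits them by
#' whether all errors fall left of the boundary (offsets `< boundary`) or at
#' or beyond it. Pairs with errors on both sides belong to neither set. With
#' `k = 0` the zero-mismatch pairs have no side and are returned once as the
#' `exact` stratum.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param k exact number of error labels per pair (0-3 in the stock
#'   analysis).
#' @param boundary 0-based overlap offset splitting the sides; default 25.
#' @param recovered optional precomputed [recoverPairs()] result.
#' @return for `k > 0`, list with `HairpinPairSet`s `left` and `right`; for
#'   `k = 0`, list with the single element `exact`.
#' @export
mismatchWindowSplit <- function(pairs, k, boundary = 25L, recovered = NULL) {
    stopifnot(k >= 0L)
    if (is.null(recovered)) recovered <- recoverPairs(pairs)
    errs <- recovered@errorPositions
    if (k == 0L)
        return(list(exact = pairs[lengths(errs) == 0L]))
    hasK <- lengths(errs) == k
    allLeft <- hasK & vapply(errs, function(e) all(e < boundary), logical(1))
    allRight <- hasK & vapply(errs, function(e) all(e >= boundary), logical(1))
    list(left = pairs[allLeft], right = pairs[allRight])
}
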