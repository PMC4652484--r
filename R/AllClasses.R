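#' @include AllGenerics.R
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Reference genome container
#'
#' A set of named nucleotide sequences over the strict alphabet A/C/G/T that
#' the simulator samples from and the mapper indexes. Extends
#' [Biostrings::DNAStringSet]; all `DNAStringSet` methods apply.
#'
#' @slot .Data see [Biostrings::DNAStringSet].
#' @seealso [generateReference()], [readReference()]
#' @export
setClass("ReferenceGenome", contains = "DNAStringSet")

setValidity("ReferenceGenome", function(object) {
    if (length(object) == 0L)
        return("a ReferenceGenome must contain at least one sequence")
    nm <- names(object)
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        return("every sequence must be named")
    if (anyDuplicated(nm))
        return("sequence names must be unique")
    if (any(Biostrings::width(object) < 1L))
        return("every sequence must be non-empty")
    af <- Biostrings::alphabetFrequency(object)
    bad <- rowSums(af) - rowSums(af[, BASES, drop = FALSE])
    if (any(bad > 0))
        return(paste0("sequence '", nm[which(bad > 0)[1L]],
                      "' contains characters outside {A,C,G,T}"))
    TRUE
})

#' Construct a ReferenceGenome
#'
#' @param x a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet]. Character input is upper-cased.
#' @return a [ReferenceGenome-class] object.
#' @examples
#' ReferenceGenome(c(chr1 = "ACGTACGT"))
#' @export
ReferenceGenome <- function(x) {
    if (is.character(x)) {
        x <- Biostrings::DNAStringSet(toupper(x))
    } else if (!methods::is(x, "DNAStringSet")) {
        stop("'x' must be a named character vector or a DNAStringSet")
    }
    methods::new("ReferenceGenome", x)
}

#' Per-cytosine methylation states
#'
#' Holds one row per cytosine of a reference genome, on both strands, in
#' Watson coordinates: for `strand = "crick"` the `pos` column is the 0-based
#' Watson position of the G whose paired Crick-strand base is the cytosine.
#'
#' @slot states `data.frame` with columns `seqname`, `pos` (0-based),
#'   `strand` (`"watson"`/`"crick"`), `context` (`"CpG"`/`"CpH"`) and
#'   `methylated` (logical).
#' @seealso [generateMethylome()]
#' @export
setClass("Methylome", representation(states = "data.frame"))

setValidity("Methylome", function(object) {
    st <- object@states
    need <- c("seqname", "pos", "strand", "context", "methylated")
    if (!all(need %in% names(st)))
        return(paste("states must have columns", paste(need, collapse = ", ")))
    if (nrow(st) && !all(st$strand %in% c("watson", "crick")))
        return("strand must be 'watson' or 'crick'")
    if (nrow(st) && !all(st$context %in% c("CpG", "CpH")))
        return("context must be 'CpG' or 'CpH'")
    if (!is.logical(st$methylated))
        return("methylated must be logical")
    TRUE
})

#' @describeIn Methylome-class the per-cytosine state table.
#' @param x a `Methylome`.
#' @export
setMethod("methStates", "Methylome", function(x) x@states)

setMethod("show", "Methylome", function(object) {
    st <- object@states
    cat("Methylome with", nrow(st), "cytosine states on",
        length(unique(st$seqname)), "sequence(s)\n")
    if (nrow(st)) {
        for (ctx in c("CpG", "CpH")) {
            sel <- st$context == ctx
            if (any(sel))
                cat(sprintf("  %s: %d sites, %.1f%% methylated\n", ctx,
                            sum(sel), 100 * mean(st$methylated[sel])))
        }
    }
})

#' Hairpin bisulfite read pairs
#'
#' One entry per sequenced DNA duplex: the T-enriched mate (`tRead`, stored
#' in Watson orientation) and the A-enriched mate (`aRead`, stored in the
#' delivered orientation, i.e. reverse-complemented relative to Watson), plus
#' an optional truth table when the pairs were simulated.
#'
#' @slot pairId character, unique pair identifiers.
#' @slot tRead,aRead character vectors of mate sequences.
#' @slot truth `NULL` or a `data.frame` with columns `pairId`, `seqname`,
#'   `start`, `end` (0-based half-open), `strand`, `tErrorPos`, `aErrorPos`
#'   (semicolon-separated 0-based offsets in each mate's delivered
#'   orientation) and `methString` (per-position codes: `.` non-cytosine,
#'   `M`/`U` methylated/unmethylated Watson C, `m`/`u` the same for the
#'   paired Crick C under a Watson G).
#' @seealso [makeHairpinPairs()], [recoverPairs()]
#' @export
setClass("HairpinPairSet",
         representation(pairId = "character", tRead = "character",
                        aRead = "character", truth = "data.frameOrNULL"))

setValidity("HairpinPairSet", function(object) {
    n <- length(object@pairId)
    if (length(object@tRead) != n || length(object@aRead) != n)
        return("pairId, tRead and aRead must have equal length")
    if (anyDuplicated(object@pairId))
        return("pair ids must be unique")
    if (n && (any(nchar(object@tRead) == 0L) || any(nchar(object@aRead) == 0L)))
        return("both mates must be non-empty")
    if (!is.null(object@truth)) {
        if (nrow(object@truth) != n || !identical(object@truth$pairId, object@pairId))
            return("truth rows must match pairId one-to-one")
    }
    TRUE
})

#' Construct a HairpinPairSet
#'
#' @param pairId unique pair identifiers.
#' @param tRead T-enriched mates (Watson orientation).
#' @param aRead A-enriched mates (delivered orientation).
#' @param truth optional truth table (see the class description).
#' @return a [HairpinPairSet-class].
#' @export
HairpinPairSet <- function(pairId, tRead, aRead, truth = NULL) {
    methods::new("HairpinPairSet", pairId = as.character(pairId),
                 tRead = toupper(tRead), aRead = toupper(aRead), truth = truth)
}

#' @describeIn HairpinPairSet-class pair identifiers.
#' @param x a `HairpinPairSet`.
#' @export
setMethod("pairIds", "HairpinPairSet", function(x) x@pairId)
#' @describeIn HairpinPairSet-class T-enriched mates (Watson orientation).
#' @export
setMethod("tReads", "HairpinPairSet", function(x) setNames(x@tRead, x@pairId))
#' @describeIn HairpinPairSet-class A-enriched mates (delivered orientation).
#' @export
setMethod("aReads", "HairpinPairSet", function(x) setNames(x@aRead, x@pairId))
#' @describeIn HairpinPairSet-class truth table (or `NULL`).
#' @export
setMethod("truthInfo", "HairpinPairSet", function(x) x@truth)

#' @export
setMethod("length", "HairpinPairSet", function(x) length(x@pairId))

#' @export
setMethod("[", "HairpinPairSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@pairId)
    HairpinPairSet(x@pairId[i], x@tRead[i], x@aRead[i],
                   if (is.null(x@truth)) NULL else x@truth[i, , drop = FALSE])
})

setMethod("show", "HairpinPairSet", function(object) {
    cat("HairpinPairSet with", length(object), "pairs",
        if (is.null(object@truth)) "(no truth)" else "(with truth)", "\n")
    if (length(object)) {
        i <- seq_len(min(3L, length(object)))
        cat(paste0("  ", object@pairId[i], ": T=",
                   substr(object@tRead[i], 1, 20), "... A=",
                   substr(object@aRead[i], 1, 20), "...", collapse = "\n"), "\n")
    }
})

#' Recovered original sequences
#'
#' Result of applying the hairpin rule table to oriented mate pairs: the
#' reconstructed pre-bisulfite sequence (errors as `N`), the offsets flagged
#' as PCR/sequencing errors, and the per-strand methylation calls.
#'
#' @slot pairId character identifiers.
#' @slot sequence recovered sequences over A/C/G/T/N.
#' @slot errorPositions list of integer vectors of 0-based error offsets.
#' @slot methCalls `data.frame` with columns `pairId`, `offset` (0-based),
#'   `strand` (`"watson"`/`"crick"`) and `status`
#'   (`"methylated"`/`"unmethylated"`).
#' @seealso [recoverPairs()]
#' @export
setClass("RecoveredReadSet",
         representation(pairId = "character", sequence = "character",
                        errorPositions = "list", methCalls = "data.frame"))

setValidity("RecoveredReadSet", function(object) {
    n <- length(object@pairId)
    if (length(object@sequence) != n || length(object@errorPositions) != n)
        return("slot lengths disagree")
    need <- c("pairId", "offset", "strand", "status")
    if (!all(need %in% names(object@methCalls)))
        return(paste("methCalls must have columns", paste(need, collapse = ", ")))
    TRUE
})

#' @describeIn RecoveredReadSet-class recovered sequences, named by pair id.
#' @param x a `RecoveredReadSet`.
#' @export
setMethod("recoveredSeqs", "RecoveredReadSet",
          function(x) setNames(x@sequence, x@pairId))
#' @describeIn RecoveredReadSet-class list of 0-based error offsets.
#' @export
setMethod("errorPositions", "RecoveredReadSet",
          function(x) setNames(x@errorPositions, x@pairId))
#' @describeIn RecoveredReadSet-class methylation call table.
#' @export
setMethod("methCalls", "RecoveredReadSet", function(x) x@methCalls)
#' @describeIn RecoveredReadSet-class pair identifiers.
#' @export
setMethod("pairIds", "RecoveredReadSet", function(x) x@pairId)

#' @export
setMethod("length", "RecoveredReadSet", function(x) length(x@pairId))

#' @export
setMethod("[", "RecoveredReadSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, x@pairId)
    ids <- x@pairId[i]
    methods::new("RecoveredReadSet", pairId = ids, sequence = x@sequence[i],
                 errorPositions = x@errorPositions[i],
                 methCalls = x@methCalls[x@methCalls$pairId %in% ids, , drop = FALSE])
})

setMethod("show", "RecoveredReadSet", function(object) {
    nerr <- sum(lengths(object@errorPositions) > 0L)
    cat("RecoveredReadSet with", length(object), "reads;",
        nerr, "carry flagged errors;",
        nrow(object@methCalls), "methylation calls\n")
})

#' Seed index of a reference genome
#'
#' A k-mer hash over one or more "views" of the reference. In bisulfite mode
#' the views are the C-to-T and G-to-A conversions of the Watson strand and
#' of its reverse complement (so a non-directional read matches one of the
#' four strand/conversion combinations with zero bisulfite-induced
#' mismatches); in plain mode the views are the two unconverted strands.
#'
#' @slot k integer seed length.
#' @slot mode `"bisulfite"` or `"plain"`.
#' @slot seqnames,seqlengths the indexed sequences.
#' @slot views list of views; each holds the converted sequence text, the
#'   strand and conversion labels, and an environment hashing every k-mer to
#'   its start positions.
#' @seealso [buildMapperIndex()], [mapReads()]
#' @export
setClass("MapperIndex",
         representation(k = "integer", mode = "character",
                        seqnames = "character", seqlengths = "integer",
                        views = "list"))

setMethod("show", "MapperIndex", function(object) {
    cat("MapperIndex (", object@mode, " mode, k = ", object@k, ") over ",
        length(object@seqnames), " sequence(s), ",
        sum(object@seqlengths), " bp; ", length(object@views),
        " view(s)\n", sep = "")
})

#' Mapping results
#'
#' Per-read mapping category and best location(s). A read is `unique` when a
#' single location attains the best mismatch score within the threshold,
#' `ambiguous` when several tie at the best score, and `unmapped` when no
#' location scores within the threshold.
#'
#' @slot reads `data.frame` with one row per read: `readId`, `category`,
#'   `score` (best mismatch count; `NA` when unmapped) and `nBest`.
#' @slot locations `data.frame` of best locations (capped at `tieCap` per
#'   read): `readId`, `seqname`, `pos` (0-based Watson start), `strand`
#'   (`"watson"`/`"crick"`), `conversion` (`"CT"`/`"GA"`/`"none"`).
#' @slot params list recording mode, k, and mismatch threshold settings.
#' @seealso [mapReads()], [bruteForceMap()]
#' @export
setClass("MapResults",
         representation(reads = "data.frame", locations = "data.frame",
                        params = "list"))

setValidity("MapResults", function(object) {
    need <- c("readId", "category", "score", "nBest")
    if (!all(need %in% names(object@reads)))
        return(paste("reads must have columns", paste(need, collapse = ", ")))
    if (nrow(object@reads) &&
        !all(object@reads$category %in% c("unique", "ambiguous", "unmapped")))
        return("category must be unique/ambiguous/unmapped")
    TRUE
})

#' @describeIn MapResults-class one row per read.
#' @param x a `MapResults`.
#' @export
setMethod("readInfo", "MapResults", function(x) x@reads)
#' @describeIn MapResults-class best locations table.
#' @export
setMethod("bestLocations", "MapResults", function(x) x@locations)
#' @describeIn MapResults-class named category vector.
#' @export
setMethod("mapCategories", "MapResults",
          function(x) setNames(x@reads$category, x@reads$readId))

#' @export
setMethod("length", "MapResults", function(x) nrow(x@reads))

setMethod("show", "MapResults", function(object) {
    cat("MapResults for", nrow(object@reads), "reads (",
        object@params$mode, "mode )\n")
    if (nrow(object@reads)) {
        tab <- categorySummary(object)
        cat(paste(sprintf("  %-9s %6d  %6.2f%%", tab$category, tab$n,
                          tab$percent), collapse = "\n"), "\n")
    }
})

#' @describeIn MapResults-class category counts and percentages. With zero
#'   reads all percentages are reported as 0 and the `n` column makes the
#'   empty input explicit.
#' @export
setMethod("categorySummary", "MapResults", function(x) {
    cats <- c("unique", "ambiguous", "unmapped")
    n <- vapply(cats, function(ct) sum(x@reads$category == ct), integer(1))
    total <- nrow(x@reads)
    data.frame(category = cats, n = as.integer(n),
               percent = if (total) 100 * n / total else rep(0, 3L),
               row.names = NULL)
})
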