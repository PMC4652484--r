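#' @include AllClasses.R
NULL

#' Shannon entropy of base composition
#'
#' Computes, for each sequence, the base-2 Shannon entropy of its A/C/G/T
#' frequencies: `-sum(f_b * log2(f_b))` over bases with `f_b > 0`. Ranges
#' from 0 (homopolymer) to 2 (uniform composition). `N` characters (e.g.
#' flagged recovery errors) are excluded from the frequencies; a sequence
#' with no A/C/G/T content is an error.
#'
#' @param x character vector of sequences (or a `DNAStringSet`).
#' @return numeric vector of entropies in bits.
#' @examples
#' sequenceEntropy(c("TTTTTTTT", "ACGTACGT", "AATT"))
#' @export
sequenceEntropy <- function(x) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    if (!length(x)) return(numeric(0))
    if (any(!nzchar(x)) || anyNA(x))
        stop("entropy is undefined for empty sequences")
    counts <- Biostrings::letterFrequency(
        Biostrings::DNAStringSet(toupper(x)), BASES)
    tot <- rowSums(counts)
    if (any(tot == 0))
        stop("entropy is undefined for sequences with no A/C/G/T content")
    f <- counts / tot
    lf <- ifelse(f > 0, log2(f), 0)
    unname(-rowSums(f * lf))
}

#' Entropy distribution by mapping category
#'
#' Buckets per-read entropies within each mapping category. Bucket `x`
#' (`x` in 1..20) covers entropies in `((x-1)/10, x/10]`; exactly-zero
#' entropies get their own bucket 0.
#'
#' @param reads named character vector of the mapped sequences.
#' @param results a [MapResults-class] for those reads.
#' @return list with `summary` (`data.frame`: category, n, meanEntropy) and
#'   `buckets` (`data.frame`: category, bucket, count, proportion;
#'   proportions sum to 1 within each non-empty category).
#' @export
entropyByCategory <- function(reads, results) {
    stopifnot(methods::is(results, "MapResults"))
    info <- readInfo(results)
    if (!all(info$readId %in% names(reads)))
        stop("every mapped readId must have a read sequence")
    H <- sequenceEntropy(reads[info$readId])
    cat3 <- c("unique", "ambiguous", "unmapped")
    summ <- do.call(rbind, lapply(cat3, function(ct) {
        h <- H[info$category == ct]
        data.frame(category = ct, n = length(h),
                   meanEntropy = if (length(h)) mean(h) else NA_real_)
    }))
    bucket <- ifelse(H == 0, 0L, as.integer(ceiling(H * 10 - 1e-9)))
    buckets <- do.call(rbind, lapply(cat3, function(ct) {
        b <- bucket[info$category == ct]
        if (!length(b)) return(NULL)
        tab <- table(factor(b, levels = 0:20))
        data.frame(category = ct, bucket = 0:20,
                   count = as.integer(tab),
                   proportion = as.numeric(tab) / length(b))
    }))
    rownames(summ) <- rownames(buckets) <- NULL
    list(summary = summ, buckets = buckets)
}

# Kolmogorov distribution tail, asymptotic two-sample approximation.
ksAsymptoticP <- function(D, n1, n2) {
    m <- n1 * n2 / (n1 + n2)
    lambda <- (sqrt(m) + 0.12 + 0.11 / sqrt(m)) * D
    if (lambda <= 0) return(1)
    j <- seq_len(100)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum absolute difference between the two empirical CDFs
#' (computed exactly, ties included); the p-value uses the standard
#' asymptotic approximation.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `D`, `pValue`, `n1`, `n2`.
#' @examples
#' ksTwoSample(c(1, 2, 3), c(4, 5, 6))
#' @export
ksTwoSample <- function(a, b) {
    if (!length(a) || !length(b)) stop("both samples must be non-empty")
    v <- sort(unique(c(a, b)))
    Fa <- findInterval(v, sort(a)) / length(a)
    Fb <- findInterval(v, sort(b)) / length(b)
    D <- max(abs(Fa - Fb))
    list(D = D, pValue = ksAsymptoticP(D, length(a), length(b)),
         n1 = length(a), n2 = length(b))
}

#' Pairwise KS distances between category entropy distributions
#'
#' Computes the two-sample KS statistic `D` between the per-category
#' entropy samples for each pair of mapping categories (the "maximum
#' difference" between the distributions).
#'
#' @inheritParams entropyByCategory
#' @return `data.frame` with columns `pair`, `D`, `pValue`. Pairs
#'   involving an empty category are omitted with a warning.
#' @export
maxCategoryDifferences <- function(reads, results) {
    info <- readInfo(results)
    H <- sequenceEntropy(reads[info$readId])
    samples <- lapply(c(unique = "unique", ambiguous = "ambiguous",
                        unmapped = "unmapped"),
                      function(ct) H[info$category == ct])
    pairs <- list(c("unmapped", "ambiguous"), c("unmapped", "unique"),
                  c("unique", "ambiguous"))
    rows <- lapply(pairs, function(p) {
        if (!length(samples[[p[1]]]) || !length(samples[[p[2]]])) {
            warning("category '", p[which.min(lengths(samples[p]))],
                    "' is empty; pair omitted")
            return(NULL)
        }
        ks <- ksTwoSample(samples[[p[1]]], samples[[p[2]]])
        data.frame(pair = paste(p, collapse = "-"), D = ks$D,
                   pValue = ks$pValue)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Mapping category percentages stratified by read length
#'
#' @inheritParams entropyByCategory
#' @param minN lengths with fewer reads than this are flagged
#'   `lowSupport`.
#' @return `data.frame` with one row per observed length: `length`, `n`,
#'   `pctUnique`, `pctAmbiguous`, `pctUnmapped`, `lowSupport`.
#' @export
categoriesByLength <- function(reads, results, minN = 20L) {
    info <- readInfo(results)
    len <- nchar(reads[info$readId])
    out <- do.call(rbind, lapply(sort(unique(len)), function(l) {
        ct <- info$category[len == l]
        data.frame(length = l, n = length(ct),
                   pctUnique = 100 * mean(ct == "unique"),
                   pctAmbiguous = 100 * mean(ct == "ambiguous"),
                   pctUnmapped = 100 * mean(ct == "unmapped"),
                   lowSupport = length(ct) < minN)
    }))
    rownames(out) <- NULL
    out
}

#' Unique-mapping efficiency by mismatch location
#'
#' For each mismatch count `k`, selects the pairs whose flagged errors are
#' confined to the first `boundary` bases (left) or to the remainder
#' (right), maps their T-enriched converted reads in bisulfite mode, and
#' reports percent uniquely mapped per side.
#'
#' The reads are mapped with seeds confined to the first `seedRegion`
#' bases (default: the boundary itself), emulating the end-anchored seed
#' heuristic of production aligners whose behaviour this analysis
#' characterises; errors in the seed region can then abolish candidate
#' generation while errors elsewhere only raise the score.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param index a bisulfite-mode [MapperIndex-class].
#' @param kValues mismatch counts to stratify on.
#' @param boundary 0-based offset separating the sides; default 25.
#' @param maxMismatchFraction passed to [mapReads()].
#' @param seedRegion seed confinement for the mapped reads.
#' @param recovered optional precomputed [recoverPairs()] result.
#' @return `data.frame` with columns `k`, `side`, `n`, `pctUnique`
#'   (`NA` when a stratum is empty).
#' @export
mismatchLocationEffect <- function(pairs, index, kValues = 1:3,
                                   boundary = 25L,
                                   maxMismatchFraction = 0.1,
                                   seedRegion = boundary,
                                   recovered = NULL) {
    stopifnot(methods::is(pairs, "HairpinPairSet"))
    if (is.null(recovered)) recovered <- recoverPairs(pairs)
    rows <- list()
    for (k in kValues) {
        split <- mismatchWindowSplit(pairs, k, boundary, recovered)
        for (side in names(split)) {
            sub <- split[[side]]
            pct <- NA_real_
            if (length(sub)) {
                res <- mapReads(index, tReads(sub), maxMismatchFraction,
                                seedRegion = seedRegion)
                pct <- categorySummary(res)$percent[1L]
            }
            rows[[length(rows) + 1L]] <- data.frame(
                k = k, side = side, n = length(sub), pctUnique = pct)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

uniquePct <- function(categories) 100 * mean(categories == "unique")

#' Bootstrap comparison of converted vs recovered unique mapping
#'
#' Replicates the recovery-benefit analysis: each bootstrap replicate
#' samples pairs with replacement, keeps the exactly-aligning subset, maps
#' the T-enriched and A-enriched mates in bisulfite mode and the recovered
#' original reads in plain mode (same thresholds), and records the
#' improvement `unique%(recovered) - mean(unique%(T), unique%(A))`. The
#' one-sided p-value is the fraction of replicates with non-positive
#' improvement.
#'
#' Mapping is deterministic per read, so each distinct pair is mapped once
#' and replicates resample the per-pair categories; results are identical
#' to remapping within every replicate.
#'
#' @param pairs a [HairpinPairSet-class].
#' @param bisIndex bisulfite-mode [MapperIndex-class].
#' @param plainIndex plain-mode [MapperIndex-class] over the same
#'   reference.
#' @param B number of bootstrap replicates; default 50.
#' @param replicateSize pairs drawn per replicate (with replacement);
#'   default the input size.
#' @param maxMismatchFraction shared mapping threshold.
#' @param seed integer seed.
#' @return list of class `bootstrapSummary`: `B`, `replicateSize`,
#'   `improvements` (percentage points per replicate), `meanImprovement`,
#'   `variance`, `pValue`, `meanExactFraction`, and the pooled
#'   `uniquePct` per read set.
#' @export
bootstrapImprovement <- function(pairs, bisIndex, plainIndex, B = 50L,
                                 replicateSize = NULL,
                                 maxMismatchFraction = 0.1, seed = NULL) {
    stopifnot(methods::is(pairs, "HairpinPairSet"), B >= 1L)
    n <- length(pairs)
    if (is.null(replicateSize)) replicateSize <- n
    rec <- recoverPairs(pairs)
    exact <- lengths(rec@errorPositions) == 0L
    catT <- mapCategories(mapReads(bisIndex, tReads(pairs), maxMismatchFraction))
    catA <- mapCategories(mapReads(bisIndex, aReads(pairs), maxMismatchFraction))
    catR <- mapCategories(mapReads(plainIndex, recoveredSeqs(rec),
                                   maxMismatchFraction))
    withSeed(seed, {
        improvements <- rep(NA_real_, B)
        exactFrac <- rep(NA_real_, B)
        for (b in seq_len(B)) {
            idx <- sample.int(n, replicateSize, replace = TRUE)
            keep <- idx[exact[idx]]
            exactFrac[b] <- length(keep) / replicateSize
            if (!length(keep)) {
                warning("replicate ", b, " contained no exactly-aligning ",
                        "pairs; recorded as missing")
                next
            }
            improvements[b] <- uniquePct(catR[keep]) -
                (uniquePct(catT[keep]) + uniquePct(catA[keep])) / 2
        }
        ok <- !is.na(improvements)
        vr <- if (sum(ok) > 1L) var(improvements[ok]) else 0
        structure(list(
            B = B, replicateSize = replicateSize,
            improvements = improvements,
            meanImprovement = mean(improvements[ok]),
            variance = vr,
            singleReplicate = sum(ok) <= 1L,
            pValue = mean(improvements[ok] <= 0),
            meanExactFraction = mean(exactFrac, na.rm = TRUE),
            uniquePct = c(t = uniquePct(catT[exact]),
                          a = uniquePct(catA[exact]),
                          recovered = uniquePct(catR[exact]))),
            class = "bootstrapSummary")
    })
}

#' @export
print.bootstrapSummary <- function(x, ...) {
    cat(sprintf(paste0("Bootstrap recovery comparison: B = %d, replicate ",
                       "size = %d\n  mean improvement = %.3f pp, variance = ",
                       "%.3g, one-sided p = %.3g\n"),
                x$B, x$replicateSize, x$meanImprovement, x$variance,
                x$pValue))
    invisible(x)
}

#' Cross-strand unique-mapping rescue
#'
#' For hairpin pairs mapped separately by mate: among reads uniquely mapped
#' in one strand, the percentage whose partner is not uniquely mapped (each
#' direction), plus the combined unique percentage when a unique partner's
#' position is transferred to the other mate.
#'
#' @param resultsT,resultsA [MapResults-class] objects for the T-enriched
#'   and A-enriched mates, sharing read ids.
#' @return list with `pctTUniqueANot`, `pctAUniqueTNot`, `pctUniqueT`,
#'   `pctUniqueA`, `pctUniqueCombined`.
#' @export
crossStrandRescue <- function(resultsT, resultsA) {
    ct <- mapCategories(resultsT)
    ca <- mapCategories(resultsA)
    if (!setequal(names(ct), names(ca)))
        stop("the two result sets must cover the same read ids")
    ca <- ca[names(ct)]
    uT <- ct == "unique"; uA <- ca == "unique"
    list(pctTUniqueANot = if (any(uT)) 100 * mean(!uA[uT]) else NA_real_,
         pctAUniqueTNot = if (any(uA)) 100 * mean(!uT[uA]) else NA_real_,
         pctUniqueT = 100 * mean(uT),
         pctUniqueA = 100 * mean(uA),
         pctUniqueCombined = 100 * mean(uT | uA))
}

#' Union of two mappers' unique mappings
#'
#' A read counts as union-unique when either result maps it uniquely (an OR
#' operation over mappers).
#'
#' @param results1,results2 [MapResults-class] objects over the same read
#'   ids.
#' @return list with `pctUnique1`, `pctUnique2`, `pctUnion`, `increment1`,
#'   `increment2` (union minus each alone, percentage points).
#' @export
mapperUnion <- function(results1, results2) {
    c1 <- mapCategories(results1)
    c2 <- mapCategories(results2)
    if (!setequal(names(c1), names(c2)))
        stop("the two result sets must cover the same read ids")
    c2 <- c2[names(c1)]
    u1 <- c1 == "unique"; u2 <- c2 == "unique"
    un <- 100 * mean(u1 | u2)
    list(pctUnique1 = 100 * mean(u1), pctUnique2 = 100 * mean(u2),
         pctUnion = un, increment1 = un - 100 * mean(u1),
         increment2 = un - 100 * mean(u2))
}

#' Estimate methylation rates from recovery calls
#'
#' Pools the per-position methylation calls of a [RecoveredReadSet-class],
#' assigns each call its CpG/CpH context from the recovered sequence (a
#' Watson call at offset i is CpG when position i+1 reads G; a Crick call
#' when position i-1 reads C), and estimates the methylated fraction per
#' context with a Wilson score interval. Calls whose context base falls
#' outside the read or on a flagged error are excluded.
#'
#' @param recovered a [RecoveredReadSet-class].
#' @param conf confidence level for the Wilson intervals.
#' @return `data.frame` with one row per context: `context`, `nMethylated`,
#'   `nCalls`, `rate`, `lower`, `upper`.
#' @export
estimateMethylation <- function(recovered, conf = 0.95) {
    stopifnot(methods::is(recovered, "RecoveredReadSet"))
    calls <- recovered@methCalls
    if (!nrow(calls)) stop("no methylation calls to estimate from")
    seqs <- recoveredSeqs(recovered)
    rl <- nchar(seqs)[calls$pairId]
    nbOff <- ifelse(calls$strand == "watson", calls$offset + 1L,
                    calls$offset - 1L)
    valid <- nbOff >= 0L & nbOff < rl
    nb <- rep(NA_character_, nrow(calls))
    nb[valid] <- substr(seqs[calls$pairId[valid]], nbOff[valid] + 1L,
                        nbOff[valid] + 1L)
    ctx <- ifelse(calls$strand == "watson",
                  ifelse(nb == "G", "CpG", "CpH"),
                  ifelse(nb == "C", "CpG", "CpH"))
    ctx[is.na(nb) | nb == "N"] <- NA
    out <- do.call(rbind, lapply(c("CpG", "CpH"), function(cc) {
        sel <- !is.na(ctx) & ctx == cc
        nTot <- sum(sel)
        if (!nTot)
            return(data.frame(context = cc, nMethylated = 0L, nCalls = 0L,
                              rate = NA_real_, lower = NA_real_,
                              upper = NA_real_))
        nMeth <- sum(calls$status[sel] == "methylated")
        ci <- wilsonInterval(nMeth, nTot, conf)
        data.frame(context = cc, nMethylated = nMeth, nCalls = nTot,
                   rate = nMeth / nTot, lower = ci["lower"],
                   upper = ci["upper"])
    }))
    rownames(out) <- NULL
    out
}
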