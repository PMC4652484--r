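# Independent oracles and small fixture builders used across the suite.
# All oracles avoid the code paths they check.

# Reverse complement by explicit per-character table (independent of the
# Biostrings-based implementation in the package).
revcompOracle <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    vapply(x, function(s) {
        paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# Direct entropy computation from a base count table.
entropyOracle <- function(s) {
    v <- strsplit(s, "")[[1]]
    v <- v[v %in% c("A", "C", "G", "T")]
    f <- table(v) / length(v)
    -sum(f * log2(f))
}

# Exhaustive sup-CDF-difference scan over every sample point.
ksOracle <- function(a, b) {
    pts <- c(a, b)
    max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# The hairpin rule table, written out in full (16 combinations).
ruleTableOracle <- function() {
    grid <- expand.grid(t = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                        stringsAsFactors = FALSE)
    grid$label <- "error"
    grid$label[grid$t == grid$a] <- "match"
    grid$label[grid$t == "T" & grid$a == "C"] <- "bisulfite_C"
    grid$label[grid$t == "G" & grid$a == "A"] <- "bisulfite_G"
    grid
}

# Pre-error oriented mates of a simulated pair, reconstructed from the truth
# sidecar (complete conversion assumed: methString U -> converted Watson C,
# u -> converted Crick C seen through the Watson G).
preErrorMates <- function(ref, truth, i) {
    frag <- substr(as.character(ref[[truth$seqname[i]]]),
                   truth$start[i] + 1L, truth$end[i])
    v <- strsplit(frag, "")[[1]]
    ms <- strsplit(truth$methString[i], "")[[1]]
    tv <- v; tv[ms == "U"] <- "T"
    av <- v; av[ms == "u"] <- "A"
    list(t = paste(tv, collapse = ""), a = paste(av, collapse = ""))
}

# Probability that a pair survives filterExact under per-base substitution
# error rate e on each mate, enumerating the 4x4 substitution table at every
# position (some substitutions land on valid rule-table cells and are
# silently miscalled rather than flagged).
retentionOracle <- function(tPre, aPreWatson, e) {
    rule <- ruleTableOracle()
    valid <- matrix(rule$label != "error", 4, 4,
                    dimnames = list(c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")))
    tv <- strsplit(tPre, "")[[1]]
    av <- strsplit(aPreWatson, "")[[1]]
    bases <- c("A", "C", "G", "T")
    pKeep <- vapply(seq_along(tv), function(i) {
        pt <- ifelse(bases == tv[i], 1 - e, e / 3)
        pa <- ifelse(bases == av[i], 1 - e, e / 3)
        sum(outer(pt, pa) * valid)
    }, numeric(1))
    prod(pKeep)
}

# A MapResults object with prescribed categories, for the analyses that only
# consume categories.
fakeResults <- function(ids, categories) {
    methods::new("MapResults",
                 reads = data.frame(readId = ids, category = categories,
                                    score = ifelse(categories == "unmapped",
                                                   NA_integer_, 0L),
                                    nBest = ifelse(categories == "ambiguous",
                                                   2L, ifelse(categories ==
                                                   "unique", 1L, 0L))),
                 locations = data.frame(readId = character(),
                                        seqname = character(),
                                        pos = integer(), strand = character(),
                                        conversion = character()),
                 params = list(mode = "fake"))
}

# Full equality of two MapResults (categories, scores, tie counts and the
# ordered best-location tables).
expectSameMapping <- function(a, b) {
    ra <- readInfo(a); rb <- readInfo(b)
    expect_identical(ra$category, rb$category)
    expect_identical(ra$score, rb$score)
    expect_identical(ra$nBest, rb$nBest)
    la <- bestLocations(a); lb <- bestLocations(b)
    expect_identical(la[order(la$readId, la$pos, la$strand), -1],
                     lb[order(lb$readId, lb$pos, lb$strand), -1])
}

# Small simulation bundle shared by several tests.
simBundle <- function(genomeLen = 20000L, nPairs = 300L, errorRate = 0,
                      seed = 1L, gc = 0.42, repeats = NULL,
                      lengths = c(`100` = 0.634, `75` = 0.2, `50` = 0.166),
                      pCpG = 0.8, pCpH = 0.02) {
    ref <- generateReference(genomeLen, gc, repeatSpec = repeats, seed = seed)
    meth <- generateMethylome(ref, pCpG, pCpH, seed = seed + 1L)
    frags <- sampleFragments(ref, nPairs, lengths, seed = seed + 2L)
    pairs <- makeHairpinPairs(frags, meth, errorRate = errorRate,
                              seed = seed + 3L)
    list(ref = ref, meth = meth, frags = frags, pairs = pairs)
}
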