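test_that("sequenceEntropy matches closed forms and the counting oracle", {
    expect_identical(sequenceEntropy("TTTTTTTT"), 0)
    expect_identical(sequenceEntropy("ACGTACGT"), 2)
    expect_equal(sequenceEntropy("AATT"), 1)
    # -(3/4 log2 3/4 + 1/4 log2 1/4), frozen from the counting oracle
    expect_equal(sequenceEntropy("AAAT"), 0.811278124459133, tolerance = 1e-12)
    expect_equal(sequenceEntropy("AAAT"), entropyOracle("AAAT"))

    set.seed(221)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
                   collapse = "")
        expect_equal(sequenceEntropy(s), entropyOracle(s))
        h <- sequenceEntropy(s)
        expect_gte(h, 0); expect_lte(h, 2)
        perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
        expect_equal(sequenceEntropy(perm), h)
    }

    # N is excluded from the frequencies
    expect_equal(sequenceEntropy("AATTNN"), 1)
    expect_error(sequenceEntropy(""), "empty")
    expect_error(sequenceEntropy("NNNN"), "no A/C/G/T")
})

test_that("degrading a sequence toward a homopolymer lowers entropy", {
    # enumerate all length-8 composition vectors; moving one count from a
    # minority base to the majority base must not raise entropy (strictly
    # lowers it when the counts differ)
    comps <- expand.grid(a = 0:8, c = 0:8, g = 0:8)
    comps$t <- 8 - comps$a - comps$c - comps$g
    comps <- comps[comps$t >= 0, ]
    mkSeq <- function(n) paste(rep(c("A", "C", "G", "T"), n), collapse = "")
    for (i in seq_len(nrow(comps))) {
        n <- as.integer(comps[i, c("a", "c", "g", "t")])
        minority <- which(n == min(n[n > 0]))[1]
        majority <- which.max(n)
        if (minority == majority) next
        n2 <- n; n2[minority] <- n2[minority] - 1L
        n2[majority] <- n2[majority] + 1L
        h1 <- sequenceEntropy(mkSeq(n))
        h2 <- sequenceEntropy(mkSeq(n2))
        expect_lte(h2, h1)
        if (n[minority] != n[majority]) expect_lt(h2, h1)
    }
})

test_that("bisulfite conversion does not raise mean read-set entropy", {
    bundle <- simBundle(20000L, 1000L, errorRate = 0, seed = 231)
    original <- S4Vectors::mcols(bundle$frags)$seq
    expect_lte(mean(sequenceEntropy(tReads(bundle$pairs))),
               mean(sequenceEntropy(original)))
    expect_lte(mean(sequenceEntropy(aReads(bundle$pairs))),
               mean(sequenceEntropy(original)))
})

test_that("ksTwoSample computes the exact sup-CDF distance", {
    expect_identical(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$D, 0)
    expect_identical(ksTwoSample(c(1, 2), c(5, 6, 7))$D, 1)

    set.seed(241)
    for (i in 1:20) {
        a <- sample(seq(0, 2, 0.1), sample(2:10, 1), replace = TRUE)
        b <- sample(seq(0, 2, 0.1), sample(2:10, 1), replace = TRUE)
        mine <- ksTwoSample(a, b)
        expect_equal(mine$D, ksOracle(a, b))
        # independent cross-check against the stock implementation
        expect_equal(mine$D,
                     unname(suppressWarnings(stats::ks.test(a, b))$statistic))
    }
    expect_error(ksTwoSample(numeric(0), 1), "non-empty")
})

test_that("entropy-by-category summaries follow the bucket convention", {
    ids <- paste0("r", 1:6)
    reads <- setNames(c("ACGTACGT", "ACGTACGT", "AAAA", "AATT", "TTTT",
                        "AAAT"), ids)
    res <- fakeResults(ids, c("unique", "unique", "ambiguous", "ambiguous",
                              "unmapped", "unmapped"))
    ent <- entropyByCategory(reads, res)
    s <- ent$summary
    expect_identical(s$n, c(2L, 2L, 2L))
    expect_equal(s$meanEntropy[s$category == "unique"], 2)
    expect_equal(s$meanEntropy[s$category == "ambiguous"], 0.5)
    b <- ent$buckets
    # proportions sum to one per category
    for (ct in unique(b$category))
        expect_equal(sum(b$proportion[b$category == ct]), 1)
    # point mass: both unique reads have entropy exactly 2 -> bucket 20
    expect_equal(b$proportion[b$category == "unique" & b$bucket == 20], 1)
    # entropy exactly 0 goes to the dedicated zero bucket
    expect_equal(b$proportion[b$category == "unmapped" & b$bucket == 0], 0.5)
    # 0.811 falls in bucket 9 (0.8, 0.9]
    expect_equal(b$proportion[b$category == "unmapped" & b$bucket == 9], 0.5)
    expect_error(entropyByCategory(reads[1:3], res), "read sequence")
})

test_that("maxCategoryDifferences agrees with ksTwoSample pair by pair", {
    set.seed(251)
    ids <- paste0("r", 1:90)
    cats <- rep(c("unique", "ambiguous", "unmapped"), each = 30)
    seqs <- vapply(1:90, function(i)
        paste(sample(c("A", "C", "G", "T"), 40, TRUE,
                     prob = c(0.25 + 0.15 * (i > 60), 0.25, 0.25,
                              0.25 - 0.15 * (i > 60))), collapse = ""),
        character(1))
    reads <- setNames(seqs, ids)
    res <- fakeResults(ids, cats)
    md <- maxCategoryDifferences(reads, res)
    expect_identical(md$pair, c("unmapped-ambiguous", "unmapped-unique",
                                "unique-ambiguous"))
    H <- sequenceEntropy(reads)
    expect_equal(md$D[1], ksTwoSample(H[cats == "unmapped"],
                                      H[cats == "ambiguous"])$D)
    expect_equal(md$D[2], ksTwoSample(H[cats == "unmapped"],
                                      H[cats == "unique"])$D)
    # identical samples give zero distance
    resSame <- fakeResults(ids, rep(c("unique", "ambiguous", "unmapped"), 30))
    readsSame <- setNames(rep("ACGTAACC", 90), ids)
    mdSame <- maxCategoryDifferences(readsSame, resSame)
    expect_true(all(mdSame$D == 0))
    # an empty category drops its pairs with a warning
    resEmpty <- fakeResults(ids, rep(c("unique", "ambiguous"), 45))
    # both pairs involving the empty category warn
    expect_warning(expect_warning(
        mdE <- maxCategoryDifferences(reads, resEmpty), "empty"), "empty")
    expect_identical(mdE$pair, "unique-ambiguous")
})

test_that("categoriesByLength recounts the per-read records", {
    ids <- paste0("r", 1:30)
    reads <- setNames(c(strrep("ACGT", 10)[rep(1, 10)],
                        rep(strrep("ACGTA", 4), 10),
                        rep(strrep("AC", 25), 10)), ids)
    cats <- c(rep("unique", 8), rep("unmapped", 2),
              rep("unique", 5), rep("ambiguous", 5),
              rep("unique", 10))
    res <- fakeResults(ids, cats)
    out <- categoriesByLength(reads, res, minN = 15)
    expect_identical(out$length, c(20L, 40L, 50L))
    expect_equal(out$pctUnique, c(50, 80, 100))
    expect_equal(out$pctAmbiguous, c(50, 0, 0))
    expect_equal(out$pctUnique + out$pctAmbiguous + out$pctUnmapped,
                 rep(100, 3))
    expect_identical(out$lowSupport, c(TRUE, TRUE, TRUE))
})

test_that("a null configuration yields zero bootstrap improvement", {
    # an A/T-only genome is untouched by bisulfite conversion, so converted,
    # mate and recovered reads are all identical to the fragment
    ref <- generateReference(10000, gcFraction = 0, seed = 261)
    meth <- generateMethylome(ref, seed = 262)
    frags <- sampleFragments(ref, 150, seed = 263)
    pairs <- makeHairpinPairs(frags, meth, errorRate = 0, seed = 264)
    bisIdx <- buildMapperIndex(ref, mode = "bisulfite")
    plainIdx <- buildMapperIndex(ref, mode = "plain")
    b <- bootstrapImprovement(pairs, bisIdx, plainIdx, B = 12, seed = 265)
    expect_true(all(b$improvements == 0))
    expect_identical(b$pValue, 1)
    expect_identical(b$meanImprovement, 0)

    # B = 1: variance 0 by convention, flagged
    b1 <- bootstrapImprovement(pairs, bisIdx, plainIdx, B = 1, seed = 266)
    expect_identical(b1$variance, 0)
    expect_true(b1$singleReplicate)

    # seeded determinism
    b2 <- bootstrapImprovement(pairs, bisIdx, plainIdx, B = 12, seed = 265)
    expect_identical(b$improvements, b2$improvements)
})

test_that("cross-strand rescue and mapper union follow their set algebra", {
    ids <- paste0("p", 1:10)
    same <- fakeResults(ids, rep(c("unique", "unmapped"), 5))
    r0 <- crossStrandRescue(same, same)
    expect_equal(r0$pctTUniqueANot, 0)
    expect_equal(r0$pctAUniqueTNot, 0)
    expect_equal(r0$pctUniqueCombined, r0$pctUniqueT)

    allT <- fakeResults(ids, rep("unique", 10))
    noneA <- fakeResults(ids, rep("unmapped", 10))
    r1 <- crossStrandRescue(allT, noneA)
    expect_equal(r1$pctTUniqueANot, 100)
    expect_equal(r1$pctUniqueCombined, 100)
    expect_gte(r1$pctUniqueCombined, max(r1$pctUniqueT, r1$pctUniqueA))

    u0 <- mapperUnion(same, same)
    expect_equal(u0$increment1, 0)
    expect_equal(u0$increment2, 0)
    # disjoint unique sets of sizes 3 and 4 over 10 reads
    m1 <- fakeResults(ids, c(rep("unique", 3), rep("unmapped", 7)))
    m2 <- fakeResults(ids, c(rep("unmapped", 3), rep("unique", 4),
                             rep("unmapped", 3)))
    u <- mapperUnion(m1, m2)
    expect_equal(u$pctUnion, 70)
    expect_gte(u$pctUnion, u$pctUnique1)
    expect_gte(u$pctUnion, u$pctUnique2)
    expect_error(mapperUnion(m1, fakeResults(paste0("x", 1:10),
                                             rep("unique", 10))), "same read")
})

test_that("estimateMethylation recounts calls and brackets the truth", {
    # all-CpG methylated construction: CGCG with both strands methylated
    p <- HairpinPairSet("p1", "CGCG", revcompOracle("CGCG"))
    est <- estimateMethylation(recoverPairs(p))
    cg <- est[est$context == "CpG", ]
    expect_equal(cg$rate, 1)
    # every call has an in-read context base here: 4 CpG calls
    expect_identical(cg$nCalls, 4L)
    expect_true(cg$lower <= 1 & cg$upper == 1)

    # low-coverage design: call-level clustering (re-covered sites, paired
    # strand calls) is kept small so the call-count interval is honest
    bundle <- simBundle(400000L, 1200L, errorRate = 0, seed = 271)
    rec <- recoverPairs(bundle$pairs)
    est <- estimateMethylation(rec, conf = 0.99)
    cpg <- est[est$context == "CpG", ]
    cph <- est[est$context == "CpH", ]
    expect_gt(cpg$nCalls, 5000L)
    expect_true(cpg$lower <= 0.8 && 0.8 <= cpg$upper)
    expect_true(cph$lower <= 0.02 && 0.02 <= cph$upper)
    # recount identity
    expect_equal(cpg$rate, cpg$nMethylated / cpg$nCalls)
})

test_that("mismatch-location strata behave as constructed", {
    bundle <- simBundle(20000L, 90L, errorRate = 0, seed = 281,
                        lengths = c(`100` = 1))
    idx <- buildMapperIndex(bundle$ref, mode = "bisulfite")
    left <- injectReadErrors(bundle$pairs[1:30], 1, "left", seed = 282)
    clean <- bundle$pairs[31:60]
    combined <- HairpinPairSet(c(paste0("L", pairIds(left)),
                                 paste0("C", pairIds(clean))),
                               c(tReads(left), tReads(clean)),
                               c(aReads(left), aReads(clean)))
    out <- mismatchLocationEffect(combined, idx, kValues = 1)
    expect_identical(out$n[out$side == "left"], 30L)
    expect_identical(out$n[out$side == "right"], 0L)
    expect_true(is.na(out$pctUnique[out$side == "right"]))
    # errors in the seed region cannot raise unique mapping
    exact <- mapReads(idx, tReads(clean), seedRegion = 25)
    expect_lte(out$pctUnique[out$side == "left"],
               categorySummary(exact)$percent[1])
})
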