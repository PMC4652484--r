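test_that("generateReference respects length, alphabet, GC and determinism", {
    g0 <- generateReference(8, gcFraction = 0, seed = 1)
    expect_identical(nchar(as.character(g0[[1]])), 8L)
    expect_true(grepl("^[AT]+$", as.character(g0[[1]])))

    g1 <- generateReference(3000, 0.42, seed = 7)
    g2 <- generateReference(3000, 0.42, seed = 7)
    g3 <- generateReference(3000, 0.42, seed = 8)
    expect_identical(as.character(g1), as.character(g2))
    expect_false(identical(as.character(g1), as.character(g3)))

    # binomial bound: sd of observed GC at n = 1e5 is ~0.0016
    big <- generateReference(100000, 0.42, seed = 3)
    obsGC <- sum(Biostrings::letterFrequency(big, c("C", "G"))) / 100000
    expect_lt(abs(obsGC - 0.42), 3 * sqrt(0.42 * 0.58 / 100000))

    expect_error(generateReference(0), "positive")
    expect_error(generateReference(100, repeatSpec = repeatSpec(1, 200)),
                 "fit")
})

test_that("planted repeats appear verbatim and collapse only as designed", {
    g <- generateReference(1000, 0.5, repeatSpec = repeatSpec(1, 60), seed = 5)
    reps <- S4Vectors::metadata(g)$repeats
    expect_identical(nrow(reps), 2L)
    block <- substr(as.character(g[[1]]), reps$start[1] + 1, reps$end[1])
    hits <- gregexpr(block, as.character(g[[1]]), fixed = TRUE)[[1]]
    expect_gte(length(hits), 2L)

    gct <- generateReference(2000, 0.5, repeatSpec = repeatSpec(1, 80,
                             collapse = "ct"), seed = 6)
    reps <- S4Vectors::metadata(gct)$repeats
    s <- as.character(gct[[1]])
    c1 <- substr(s, reps$start[1] + 1, reps$end[1])
    c2 <- substr(s, reps$start[2] + 1, reps$end[2])
    expect_false(c1 == c2)
    expect_identical(chartr("C", "T", c1), chartr("C", "T", c2))
    expect_false(identical(chartr("G", "A", c1), chartr("G", "A", c2)))

    gga <- generateReference(2000, 0.5, repeatSpec = repeatSpec(1, 80,
                             collapse = "ga"), seed = 6)
    reps <- S4Vectors::metadata(gga)$repeats
    s <- as.character(gga[[1]])
    c1 <- substr(s, reps$start[1] + 1, reps$end[1])
    c2 <- substr(s, reps$start[2] + 1, reps$end[2])
    expect_identical(chartr("G", "A", c1), chartr("G", "A", c2))
    expect_false(identical(chartr("C", "T", c1), chartr("C", "T", c2)))
})

test_that("generateMethylome covers every cytosine with the right contexts", {
    ref <- generateReference(4000, 0.5, seed = 11)
    v <- strsplit(as.character(ref[[1]]), "")[[1]]

    m1 <- generateMethylome(ref, pCpG = 1, pCpH = 0, seed = 12)
    st <- methStates(m1)
    # one state per C (watson) and per G (crick)
    expect_identical(sum(st$strand == "watson"), sum(v == "C"))
    expect_identical(sum(st$strand == "crick"), sum(v == "G"))
    # context labels match a direct scan of the sequence
    wCpG <- which(v == "C" & c(v[-1] == "G", FALSE)) - 1L
    sw <- st[st$strand == "watson", ]
    expect_setequal(sw$pos[sw$context == "CpG"], wCpG)
    cCpG <- which(v == "G" & c(FALSE, v[-length(v)] == "C")) - 1L
    sc <- st[st$strand == "crick", ]
    expect_setequal(sc$pos[sc$context == "CpG"], cCpG)
    # degenerate probabilities
    expect_true(all(st$methylated[st$context == "CpG"]))
    expect_false(any(st$methylated[st$context == "CpH"]))
    m0 <- generateMethylome(ref, pCpG = 0, pCpH = 0, seed = 12)
    expect_false(any(methStates(m0)$methylated))
})

test_that("methylation rates and strand symmetry follow the configuration", {
    ref <- generateReference(30000, 0.5, seed = 21)
    m <- generateMethylome(ref, pCpG = 0.8, pCpH = 0.02, seed = 22)
    st <- methStates(m)
    cpg <- st[st$context == "CpG", ]
    cph <- st[st$context == "CpH", ]
    expect_gt(nrow(cpg), 1000L)
    for (dat in list(list(d = cpg, p = 0.8), list(d = cph, p = 0.02))) {
        n <- nrow(dat$d)
        expect_lt(abs(mean(dat$d$methylated) - dat$p),
                  3 * sqrt(dat$p * (1 - dat$p) / n))
    }
    # hemimethylationRate = 0: crick CpG call equals its watson partner
    sw <- st[st$strand == "watson" & st$context == "CpG", ]
    sc <- st[st$strand == "crick" & st$context == "CpG", ]
    expect_identical(sc$methylated,
                     sw$methylated[match(sc$pos - 1L, sw$pos)])
    # hemimethylation flips approximately the configured fraction
    mh <- generateMethylome(ref, 0.8, 0.02, hemimethylationRate = 0.3,
                            seed = 23)
    sth <- methStates(mh)
    swh <- sth[sth$strand == "watson" & sth$context == "CpG", ]
    sch <- sth[sth$strand == "crick" & sth$context == "CpG", ]
    flip <- mean(sch$methylated != swh$methylated[match(sch$pos - 1L, swh$pos)])
    expect_lt(abs(flip - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(sch)))
})

test_that("sampleFragments honours lengths, positions and the distribution", {
    ref <- generateReference(5000, seed = 31)
    f50 <- sampleFragments(ref, 4, c(`50` = 1), seed = 32)
    expect_identical(GenomicRanges::width(f50), rep(50L, 4))

    fr <- sampleFragments(ref, 200, seed = 33)
    s <- as.character(ref[[1]])
    expect_identical(S4Vectors::mcols(fr)$seq,
                     substr(rep(s, 200), GenomicRanges::start(fr),
                            GenomicRanges::end(fr)))

    # multinomial 3-sigma bound on the stock mix at n = 10000
    p <- c(`100` = 0.634, `75` = 0.2, `50` = 0.166)
    fbig <- sampleFragments(ref, 10000, p, seed = 34)
    w <- GenomicRanges::width(fbig)
    for (len in names(p)) {
        obs <- sum(w == as.integer(len))
        expect_lt(abs(obs - 10000 * p[[len]]),
                  3 * sqrt(10000 * p[[len]] * (1 - p[[len]])))
    }
    expect_error(sampleFragments(ref, 5, c(`9999` = 1)), "exceeds")
})

test_that("makeHairpinPairs applies the conversion chemistry of both strands", {
    # worked example: fragment ATGC, everything unmethylated, complete
    # conversion. Watson C -> T gives t = ATGT; the Crick C under the
    # Watson G converts, read back through PCR as A: a (Watson) = ATAC.
    ref <- ReferenceGenome(c(chr1 = "ATGC"))
    meth <- generateMethylome(ref, pCpG = 0, pCpH = 0, seed = 1)
    frag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4), "+")
    S4Vectors::mcols(frag)$seq <- "ATGC"
    p <- makeHairpinPairs(frag, meth, conversionRate = 1, errorRate = 0,
                          seed = 2)
    expect_identical(unname(tReads(p)), "ATGT")
    expect_identical(revcompOracle(unname(aReads(p))), "ATAC")

    # no conversion, no error: both mates reproduce the fragment
    p0 <- makeHairpinPairs(frag, meth, conversionRate = 0, errorRate = 0,
                           seed = 3)
    expect_identical(unname(tReads(p0)), "ATGC")
    expect_identical(revcompOracle(unname(aReads(p0))), "ATGC")

    # fully methylated: nothing converts
    methAll <- generateMethylome(ref, pCpG = 1, pCpH = 1, seed = 4)
    pm <- makeHairpinPairs(frag, methAll, conversionRate = 1, errorRate = 0,
                           seed = 5)
    expect_identical(unname(tReads(pm)), "ATGC")
    expect_identical(revcompOracle(unname(aReads(pm))), "ATGC")
})

test_that("injected error counts match the binomial expectation", {
    bundle <- simBundle(10000L, 1000L, errorRate = 0.1, seed = 41,
                        lengths = c(`50` = 1))
    truth <- truthInfo(bundle$pairs)
    nErr <- sum(lengths(strsplit(truth$tErrorPos[truth$tErrorPos != ""], ";"))) +
        sum(lengths(strsplit(truth$aErrorPos[truth$aErrorPos != ""], ";")))
    nBases <- 2L * sum(truth$end - truth$start)
    expect_identical(nBases, 100000L)
    expect_lt(abs(nErr - nBases * 0.1), 3 * sqrt(nBases * 0.1 * 0.9))
})

test_that("conversion completeness: t reads keep C only at methylated sites", {
    bundle <- simBundle(20000L, 400L, errorRate = 0, seed = 51)
    truth <- truthInfo(bundle$pairs)
    for (i in seq_len(50)) {
        tv <- strsplit(unname(tReads(bundle$pairs))[i], "")[[1]]
        ms <- strsplit(truth$methString[i], "")[[1]]
        expect_identical(which(tv == "C"), which(ms == "M"))
    }
})

test_that("simulateBisulfiteReads follows the methylome and length mix", {
    ref <- generateReference(20000, 0.5, seed = 61)
    # degenerate: full CpG methylation, nothing else
    meth <- generateMethylome(ref, pCpG = 1, pCpH = 0, seed = 62)
    sim <- simulateBisulfiteReads(ref, meth, 60, c(`80` = 1), errorRate = 0,
                                  seed = 63)
    v <- strsplit(as.character(ref[[1]]), "")[[1]]
    for (i in seq_len(60)) {
        tr <- sim$truth[i, ]
        if (tr$start < 1 || tr$end >= length(v)) next  # context off the end
        fragV <- v[(tr$start + 1):tr$end]
        rd <- strsplit(sim$reads[[i]], "")[[1]]
        if (tr$strand == "crick") rd <- strsplit(revcompOracle(
            sim$reads[[i]]), "")[[1]]
        if (tr$strand == "watson") {
            genomicCpG <- fragV == "C" &
                v[(tr$start + 2):(tr$end + 1)] == "G"
            expect_identical(rd == "C", genomicCpG)
        } else {
            genomicCrickCpG <- fragV == "G" & v[tr$start:(tr$end - 1)] == "C"
            expect_identical(rd == "G", genomicCrickCpG)
        }
    }
    # length mix at the simulation-study proportions
    meth2 <- generateMethylome(ref, seed = 64)
    p <- c(`100` = 0.634, `75` = 0.2, `50` = 0.166)
    sim2 <- simulateBisulfiteReads(ref, meth2, 1000, p, errorRate = 0.01,
                                   seed = 65)
    for (len in names(p)) {
        obs <- sum(nchar(sim2$reads) == as.integer(len))
        expect_lt(abs(obs - 1000 * p[[len]]),
                  3 * sqrt(1000 * p[[len]] * (1 - p[[len]])))
    }
    expect_lt(abs(mean(sim2$truth$strand == "watson") - 0.5),
              3 * sqrt(0.25 / 1000))
})

test_that("identical configuration and seed give byte-identical outputs", {
    b1 <- simBundle(8000L, 100L, errorRate = 0.01, seed = 71)
    b2 <- simBundle(8000L, 100L, errorRate = 0.01, seed = 71)
    expect_identical(tReads(b1$pairs), tReads(b2$pairs))
    expect_identical(aReads(b1$pairs), aReads(b2$pairs))
    expect_identical(truthInfo(b1$pairs), truthInfo(b2$pairs))
    d1 <- file.path(tempdir(), "sim_det1"); d2 <- file.path(tempdir(), "sim_det2")
    dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
    writeHairpinPairs(b1$pairs, file.path(d1, "x"))
    writeHairpinPairs(b2$pairs, file.path(d2, "x"))
    for (f in c("x_R1.fastq", "x_R2.fastq", "x_truth.tsv"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))))
})
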