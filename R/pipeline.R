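#' @include AllClasses.R
NULL

configTemplate <- function() {
    list(
        global = list(seed = 1L, out_dir = "hairpinbs_run"),
        simulate = list(
            genome_length = 100000L, gc = 0.42,
            repeat_families_ct = 15L, repeat_families_ga = 15L,
            repeat_families_none = 8L, repeat_length = 150L,
            repeat_copies = 2L, repeat_gc = 0.15,
            p_cpg = 0.8, p_cph = 0.02, hemimethylation_rate = 0,
            conversion_rate = 1.0, error_rate = 0.002,
            n_pairs = 10000L, lengths = "100:0.634,75:0.2,50:0.166",
            n_offtarget = 500L, offtarget_gc = 0.06),
        map = list(k = 16L, k_alt = 12L, max_mm_frac = 0.1),
        analyze = list(bootstrap_b = 50L, replicate_size = 0L,
                       boundary = 25L, min_length_n = 20L))
}

#' Default pipeline configuration
#'
#' The stock study conditions: a 100 kb synthetic genome at 42% GC with
#' planted repeat families (including conversion-collapsing ones), CpG
#' methylation 80%, CpH 2%, complete conversion, 0.002 per-base error,
#' 10,000 hairpin pairs with the stock length mix, a small off-target
#' low-complexity read admixture, 16-mer seeds, 10% mismatch threshold and
#' 50 bootstrap replicates.
#'
#' @return nested named list of stage parameters.
#' @export
defaultRunConfig <- function() configTemplate()

parseLengthDist <- function(spec) {
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    vals <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    setNames(vals, vapply(parts, `[`, character(1), 1L))
}

#' Write a pipeline configuration file
#'
#' Plain-text `key = value` format with one `[section]` per stage.
#'
#' @param config nested list as from [defaultRunConfig()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
    lines <- character(0)
    for (sec in names(config)) {
        lines <- c(lines, paste0("[", sec, "]"))
        for (key in names(config[[sec]]))
            lines <- c(lines, paste(key, "=", config[[sec]][[key]]))
        lines <- c(lines, "")
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a pipeline configuration file
#'
#' Unknown sections or keys are rejected; values are coerced to the types
#' of the default configuration.
#'
#' @param path file written by [writeRunConfig()] (or by hand).
#' @return nested named list.
#' @export
readRunConfig <- function(path) {
    template <- configTemplate()
    config <- template
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    sec <- NULL
    for (ln in lines) {
        if (grepl("^\\[.+\\]$", ln)) {
            sec <- sub("^\\[(.+)\\]$", "\\1", ln)
            if (!sec %in% names(template))
                stop("unknown config section '", sec, "'")
            next
        }
        if (is.null(sec)) stop("config entry before any [section]: ", ln)
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("malformed config line: ", ln)
        key <- trimws(kv[1]); val <- trimws(kv[2])
        if (!key %in% names(template[[sec]]))
            stop("unknown config key '", key, "' in section [", sec, "]")
        proto <- template[[sec]][[key]]
        config[[sec]][[key]] <- if (is.integer(proto)) as.integer(val)
            else if (is.numeric(proto)) as.numeric(val) else val
    }
    config
}

configHash <- function(config) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeRunConfig(config, tmp)
    unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Simulate, recover, map (T-enriched and A-enriched mates in bisulfite
#' mode, recovered reads in plain mode) and analyze, writing all outputs
#' plus a JSON summary and manifest under `outDir`. Identical configuration
#' and seed give byte-identical data outputs (the manifest additionally
#' records wall-clock timestamps).
#'
#' @param config nested list as from [defaultRunConfig()] or
#'   [readRunConfig()].
#' @param outDir output directory (created if needed); defaults to the
#'   configured `global$out_dir`.
#' @param seed optional override of the configured seed.
#' @return the manifest, invisibly (a nested list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        seed = NULL) {
    template <- configTemplate()
    for (sec in names(config)) {
        if (!sec %in% names(template)) stop("unknown config section '", sec, "'")
        bad <- setdiff(names(config[[sec]]), names(template[[sec]]))
        if (length(bad)) stop("unknown config key '", bad[1], "'")
    }
    if (!is.null(seed)) config$global$seed <- as.integer(seed)
    if (is.null(outDir)) outDir <- config$global$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    cfg <- config$simulate
    base <- config$global$seed
    out <- function(f) file.path(outDir, f)

    # --- simulate -------------------------------------------------------
    reps <- do.call(rbind, list(
        if (cfg$repeat_families_ct > 0)
            repeatSpec(cfg$repeat_families_ct, cfg$repeat_length,
                       cfg$repeat_copies, "ct", gc = cfg$repeat_gc),
        if (cfg$repeat_families_ga > 0)
            repeatSpec(cfg$repeat_families_ga, cfg$repeat_length,
                       cfg$repeat_copies, "ga", gc = cfg$repeat_gc),
        if (cfg$repeat_families_none > 0)
            repeatSpec(cfg$repeat_families_none, cfg$repeat_length,
                       cfg$repeat_copies, "none", gc = cfg$repeat_gc)))
    ref <- generateReference(cfg$genome_length, cfg$gc, repeatSpec = reps,
                             seed = deriveSeed(base, 1L))
    meth <- generateMethylome(ref, cfg$p_cpg, cfg$p_cph,
                              cfg$hemimethylation_rate,
                              seed = deriveSeed(base, 2L))
    lengthDist <- parseLengthDist(cfg$lengths)
    frags <- sampleFragments(ref, cfg$n_pairs, lengthDist,
                             seed = deriveSeed(base, 3L))
    pairs <- makeHairpinPairs(frags, meth, cfg$conversion_rate,
                              cfg$error_rate, seed = deriveSeed(base, 4L))
    writeReference(ref, out("genome.fasta"))
    writeHairpinPairs(pairs, out("pairs"))
    offReads <- NULL
    if (cfg$n_offtarget > 0) {
        offRef <- generateReference(
            max(1000L, 20L * max(as.integer(names(lengthDist)))),
            cfg$offtarget_gc, seed = deriveSeed(base, 5L),
            name = "offtarget")
        offMeth <- generateMethylome(offRef, cfg$p_cpg, cfg$p_cph,
                                     seed = deriveSeed(base, 6L))
        offReads <- simulateBisulfiteReads(offRef, offMeth, cfg$n_offtarget,
                                           lengthDist,
                                           errorRate = cfg$error_rate,
                                           seed = deriveSeed(base, 7L),
                                           idPrefix = "offtarget")$reads
        writeReadsFastq(offReads, out("offtarget.fastq"))
    }

    # --- recover --------------------------------------------------------
    rec <- recoverPairs(pairs)
    writeRecovered(rec, out("recovered"))

    # --- map ------------------------------------------------------------
    mmf <- config$map$max_mm_frac
    bisIdx <- buildMapperIndex(ref, config$map$k, "bisulfite")
    plainIdx <- buildMapperIndex(ref, config$map$k, "plain")
    tSet <- c(tReads(pairs), offReads)
    resT <- mapReads(bisIdx, tSet, mmf)
    resA <- mapReads(bisIdx, aReads(pairs), mmf)
    resR <- mapReads(plainIdx, recoveredSeqs(rec), mmf)
    writeMapResults(resT, out("map_t.tsv"))
    writeMapResults(resA, out("map_a.tsv"))
    writeMapResults(resR, out("map_recovered.tsv"))

    # --- analyze --------------------------------------------------------
    acfg <- config$analyze
    ent <- entropyByCategory(tSet, resT)
    writeTsv(ent$summary, out("entropy_summary.tsv"))
    writeTsv(ent$buckets, out("entropy_buckets.tsv"))
    maxDiff <- tryCatch(maxCategoryDifferences(tSet, resT),
                        warning = function(w) NULL)
    byLen <- categoriesByLength(tSet, resT, acfg$min_length_n)
    writeTsv(byLen, out("categories_by_length.tsv"))
    mloc <- mismatchLocationEffect(pairs, bisIdx, 1:3, acfg$boundary, mmf,
                                   recovered = rec)
    writeTsv(mloc, out("mismatch_location.tsv"))
    repSize <- if (acfg$replicate_size > 0) acfg$replicate_size else
        length(pairs)
    boot <- bootstrapImprovement(pairs, bisIdx, plainIdx, acfg$bootstrap_b,
                                 repSize, mmf, seed = deriveSeed(base, 8L))
    writeTsv(data.frame(replicate = seq_len(boot$B),
                        improvement = boot$improvements),
             out("bootstrap_replicates.tsv"))
    resTpairs <- mapReads(bisIdx, tReads(pairs), mmf)
    rescue <- crossStrandRescue(resTpairs, resA)
    altIdx <- buildMapperIndex(ref, config$map$k_alt, "bisulfite")
    unionRes <- mapperUnion(resTpairs, mapReads(altIdx, tReads(pairs), mmf))
    methEst <- estimateMethylation(rec, conf = 0.95)
    writeTsv(methEst, out("methylation_estimates.tsv"))
    summary <- list(
        categoryPercent = list(
            tReads = setNames(as.list(categorySummary(resTpairs)$percent),
                              categorySummary(resTpairs)$category),
            aReads = setNames(as.list(categorySummary(resA)$percent),
                              categorySummary(resA)$category),
            recovered = setNames(as.list(categorySummary(resR)$percent),
                                 categorySummary(resR)$category)),
        entropyMeans = setNames(as.list(ent$summary$meanEntropy),
                                ent$summary$category),
        ksMaxDifferences = if (is.null(maxDiff)) NULL else
            setNames(as.list(maxDiff$D), maxDiff$pair),
        bootstrap = list(B = boot$B, meanImprovement = boot$meanImprovement,
                         variance = boot$variance, pValue = boot$pValue,
                         meanExactFraction = boot$meanExactFraction),
        crossStrandRescue = rescue,
        mapperUnion = unionRes,
        methylation = setNames(as.list(methEst$rate), methEst$context))
    jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")

    files <- list.files(outDir, full.names = TRUE)
    files <- files[!basename(files) %in% "manifest.json"]
    manifest <- list(
        tool = "hairpinBS",
        version = as.character(packageVersion("hairpinBS")),
        configHash = configHash(config),
        started = started,
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        counts = list(nPairs = length(pairs), nRecovered = length(rec),
                      nOfftarget = length(offReads),
                      nMappedT = length(resT), nMappedA = length(resA),
                      nMappedRecovered = length(resR)),
        checksums = as.list(setNames(unname(tools::md5sum(files)),
                                     basename(files))))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}
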