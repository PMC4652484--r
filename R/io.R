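#' @include AllClasses.R
NULL

#' Read a reference genome from FASTA
#'
#' Accepts wrapped or unwrapped FASTA; sequences are upper-cased. Records
#' with duplicate names, empty sequences or characters outside A/C/G/T are
#' rejected (N is rejected too: reference genomes in this package are
#' strictly four-letter).
#'
#' @param path FASTA file.
#' @return a [ReferenceGenome-class].
#' @export
readReference <- function(path) {
    # readDNAStringSet silently drops invalid letters (with a warning), so
    # promote that warning to an error that names the record and line
    x <- withCallingHandlers(
        Biostrings::readDNAStringSet(path, format = "fasta"),
        warning = function(w) {
            if (grepl("invalid one-letter sequence", conditionMessage(w))) {
                lines <- readLines(path)
                isSeq <- !startsWith(lines, ">")
                badLine <- which(isSeq &
                                 grepl("[^ACGTacgt[:space:]]", lines))[1L]
                headers <- which(startsWith(lines, ">"))
                rec <- sub("^>\\s*(\\S+).*$", "\\1",
                           lines[max(headers[headers < badLine])])
                stop("record '", rec, "' (line ", badLine,
                     ") contains characters outside {A,C,G,T}",
                     call. = FALSE)
            }
        })
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate record names in ", path)
    if (any(Biostrings::width(x) == 0L))
        stop("empty record in ", path)
    seqs <- toupper(as.character(x))
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad))
        stop("record '", names(x)[bad][1L],
             "' contains characters outside {A,C,G,T}")
    ReferenceGenome(setNames(seqs, names(x)))
}

#' Write a reference genome to FASTA
#'
#' @param ref a [ReferenceGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReference <- function(ref, path) {
    stopifnot(methods::is(ref, "ReferenceGenome"))
    Biostrings::writeXStringSet(methods::as(ref, "DNAStringSet"), path,
                                format = "fasta")
    invisible(path)
}

constQuality <- function(x) {
    Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
}

readFastqNamed <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    names(x) <- sub("\\s.*$", "", names(x))
    x
}

stripMateSuffix <- function(ids) sub("/[12]$", "", ids)

#' Write hairpin pairs as paired FASTQ plus a truth sidecar
#'
#' Writes `<prefix>_R1.fastq` (T-enriched mates, ids suffixed `/1`),
#' `<prefix>_R2.fastq` (A-enriched mates in delivered orientation, `/2`)
#' and, when the pairs carry truth, `<prefix>_truth.tsv`. Qualities are
#' constant (no quality model is simulated).
#'
#' @param pairs a [HairpinPairSet-class].
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
writeHairpinPairs <- function(pairs, prefix) {
    stopifnot(methods::is(pairs, "HairpinPairSet"))
    r1 <- Biostrings::DNAStringSet(setNames(pairs@tRead,
                                            paste0(pairs@pairId, "/1")))
    r2 <- Biostrings::DNAStringSet(setNames(pairs@aRead,
                                            paste0(pairs@pairId, "/2")))
    f1 <- paste0(prefix, "_R1.fastq")
    f2 <- paste0(prefix, "_R2.fastq")
    Biostrings::writeXStringSet(r1, f1, format = "fastq",
                                qualities = constQuality(r1))
    Biostrings::writeXStringSet(r2, f2, format = "fastq",
                                qualities = constQuality(r2))
    files <- c(R1 = f1, R2 = f2)
    if (!is.null(pairs@truth)) {
        ft <- paste0(prefix, "_truth.tsv")
        writeTsv(pairs@truth, ft,
                 comment = "hairpin truth sidecar; start/end 0-based half-open; error positions 0-based in delivered mate orientation")
        files <- c(files, truth = ft)
    }
    invisible(files)
}

#' Read hairpin pairs from paired FASTQ
#'
#' Mates are paired by file position; ids (after stripping `/1`, `/2` or
#' whitespace suffixes) must agree at every position. An optional truth
#' sidecar written by [writeHairpinPairs()] is re-attached.
#'
#' @param r1Path,r2Path FASTQ files (R1 = T-enriched, R2 = A-enriched).
#' @param truthPath optional truth TSV.
#' @return a [HairpinPairSet-class].
#' @export
readHairpinPairs <- function(r1Path, r2Path, truthPath = NULL) {
    r1 <- readFastqNamed(r1Path)
    r2 <- readFastqNamed(r2Path)
    if (length(r1) != length(r2))
        stop("mate files differ in record count (", length(r1), " vs ",
             length(r2), ")")
    id1 <- stripMateSuffix(names(r1))
    id2 <- stripMateSuffix(names(r2))
    bad <- which(id1 != id2)
    if (length(bad))
        stop("mate id mismatch at record ", bad[1L], ": '", id1[bad[1L]],
             "' vs '", id2[bad[1L]], "'")
    truth <- NULL
    if (!is.null(truthPath)) {
        truth <- readTsv(truthPath)
        truth$pairId <- as.character(truth$pairId)
        if (!identical(truth$pairId, id1))
            stop("truth sidecar does not match the FASTQ pair ids")
        for (col in c("tErrorPos", "aErrorPos", "methString"))
            truth[[col]] <- ifelse(is.na(truth[[col]]), "",
                                   as.character(truth[[col]]))
    }
    HairpinPairSet(id1, as.character(r1), as.character(r2), truth)
}

#' Write single-end reads to FASTQ
#'
#' @param reads named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = constQuality(x))
    invisible(path)
}

#' Read single-end reads from FASTQ
#'
#' @param path FASTQ file.
#' @return named character vector.
#' @export
readReadsFastq <- function(path) {
    x <- readFastqNamed(path)
    setNames(as.character(x), names(x))
}

# Headered TSV with leading '#' comment lines.
writeTsv <- function(df, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment))
        writeLines(paste0("# ", comment), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readTsv <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write mapping results as TSV
#'
#' One row per best location (several for ambiguous reads, capped at the
#' mapper's tie cap; one all-`NA` location row for unmapped reads).
#' Positions are 0-based Watson starts.
#'
#' @param results a [MapResults-class].
#' @param path output file.
#' @param comment optional extra comment line.
#' @return `path`, invisibly.
#' @export
writeMapResults <- function(results, path, comment = NULL) {
    stopifnot(methods::is(results, "MapResults"))
    info <- readInfo(results)
    loc <- bestLocations(results)
    merged <- merge(info, loc, by = "readId", all.x = TRUE, sort = FALSE)
    merged <- merged[order(match(merged$readId, info$readId)), ]
    merged <- merged[, c("readId", "category", "seqname", "pos", "strand",
                         "conversion", "score", "nBest")]
    writeTsv(merged, path,
             comment = c("mapper results; pos 0-based Watson start",
                         comment))
    invisible(path)
}

#' Read mapping results from TSV
#'
#' @param path file written by [writeMapResults()].
#' @return a [MapResults-class] (params are not recorded in the file and
#'   come back empty).
#' @export
readMapResults <- function(path) {
    df <- readTsv(path)
    df$readId <- as.character(df$readId)
    ids <- unique(df$readId)
    first <- df[!duplicated(df$readId), ]
    reads <- data.frame(readId = first$readId, category = first$category,
                        score = as.integer(first$score),
                        nBest = as.integer(first$nBest))
    loc <- df[!is.na(df$seqname),
              c("readId", "seqname", "pos", "strand", "conversion")]
    rownames(reads) <- rownames(loc) <- NULL
    methods::new("MapResults", reads = reads, locations = loc,
                 params = list(mode = NA_character_))
}

#' Write mapped reads as minimal SAM
#'
#' Emits only mapped reads, with flag 0 (Watson) or 16 (Crick,
#' reverse-complemented SEQ), 1-based POS, full-length match CIGAR and an
#' `NM` tag carrying the mismatch score. Ambiguous reads report their first
#' best location with `NH` giving the tie count.
#'
#' @param results a [MapResults-class].
#' @param reads named character vector of the read sequences.
#' @param ref the [ReferenceGenome-class] mapped against (for `@SQ`
#'   headers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(results, reads, ref, path) {
    stopifnot(methods::is(results, "MapResults"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref),
                       Biostrings::width(ref)), con)
    info <- readInfo(results)
    loc <- bestLocations(results)
    first <- loc[!duplicated(loc$readId), ]
    mapped <- merge(info[info$category != "unmapped", ], first,
                    by = "readId", sort = FALSE)
    if (nrow(mapped)) {
        seqs <- unname(reads[mapped$readId])
        flag <- ifelse(mapped$strand == "crick", 16L, 0L)
        seqOut <- ifelse(flag == 16L, revComp(seqs), seqs)
        writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tNH:i:%d",
                           mapped$readId, flag, mapped$seqname,
                           mapped$pos + 1L,
                           ifelse(mapped$category == "unique", 30L, 0L),
                           nchar(seqOut), seqOut,
                           strrep("I", nchar(seqOut)), mapped$score,
                           mapped$nBest), con)
    }
    invisible(path)
}

#' Write recovered reads (FASTA plus calls TSV)
#'
#' Writes `<prefix>.fasta` with the recovered sequences (errors as `N`) and
#' `<prefix>_calls.tsv` with one row per methylation call.
#'
#' @param recovered a [RecoveredReadSet-class].
#' @param prefix output path prefix.
#' @return named character vector of files written, invisibly.
#' @export
writeRecovered <- function(recovered, prefix) {
    stopifnot(methods::is(recovered, "RecoveredReadSet"))
    fa <- paste0(prefix, ".fasta")
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(recoveredSeqs(recovered)), fa)
    ct <- paste0(prefix, "_calls.tsv")
    writeTsv(recovered@methCalls, ct,
             comment = "methylation calls; offset 0-based in the recovered read")
    invisible(c(fasta = fa, calls = ct))
}
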