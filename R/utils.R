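# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the ambient
# RNG state is restored afterwards. seed = NULL leaves the ambient stream in
# place (and advances it).
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a per-stage stream from a master seed; kept below 2^31 - 1.
deriveSeed <- function(seed, offset) {
    if (is.null(seed)) return(NULL)
    (as.integer(seed) %% 2000000000L) + as.integer(offset)
}

# Vectorised reverse complement on character vectors (A/C/G/T/N).
revComp <- function(x) {
    if (length(x) == 0L) return(character(0))
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complementChars <- function(v) {
    unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v])
}

convertCT <- function(x) chartr("C", "T", x)
convertGA <- function(x) chartr("G", "A", x)

s1chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

checkProb <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        stop("'", what, "' must be a probability in [0, 1]")
    p
}

# Wilson score interval for a binomial proportion.
wilsonInterval <- function(x, n, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(lower = max(0, centre - half), upper = min(1, centre + half))
}
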