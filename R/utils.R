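# Internal helpers: seed derivation and RNG hygiene.

# Derive a child seed from a master seed and an offset; stays within 32-bit
# integer range so it is always a legal set.seed() argument.
.deriveSeed <- function(seed, offset) {
    s <- (as.numeric(seed) * 48271 + as.numeric(offset) * 16807) %% 2147483647
    as.integer(s)
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

# Deterministic 31-bit polynomial string hash (exact in double arithmetic).
.hashString <- function(x) {
    h <- 7
    for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483629
    h
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
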