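# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user
# randomness.
withLocalSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Canonical unordered pair key "a|b" with a <= b lexicographically.
pairKey <- function(a, b) {
    swap <- a > b
    key <- paste(a, b, sep = "|")
    key[swap] <- paste(b[swap], a[swap], sep = "|")
    key
}

# Truncate a percentage to one decimal place (the reporting convention used
# for interface-overlap ratios; see the methods vignette).
truncPct1 <- function(x) floor(x * 10 + 1e-9) / 10
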