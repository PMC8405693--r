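.checkCount <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
        stop(sprintf("'%s' must be a single integer >= 1", name))
    invisible(TRUE)
}

.checkFrac <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
        stop(sprintf("'%s' must be a fraction in [0, 1]", name))
    invisible(TRUE)
}

.checkPos <- function(x, name) {
    if (length(x) != 1L || is.na(x) || x <= 0)
        stop(sprintf("'%s' must be a positive number", name))
    invisible(TRUE)
}

.checkSeed <- function(x) {
    if (length(x) != 1L || is.na(x) || x != floor(x))
        stop("'seed' must be a single integer")
    invisible(TRUE)
}

# row-wise sd ignoring NAs, fully vectorised
.rowSdNA <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    ss <- rowSums(m^2, na.rm = TRUE) - n * mu^2
    out <- sqrt(pmax(ss, 0) / pmax(n - 1, 1))
    out[n < 2] <- NA_real_
    out
}

# derive per-round child seeds from one master seed, all below 2^31
.childSeeds <- function(seed, n) {
    set.seed(as.integer(seed))
    sample.int(2147483646L, n)
}
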