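# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# derive a child seed from (seed, index) staying below .Machine$integer.max
childSeed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + index * 7919 + salt * 104729) %% 2147483587)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# per-column alternate-allele frequency over non-missing calls
alleleFreqs <- function(d) colMeans(d, na.rm = TRUE) / 2

# centre and scale columns by training statistics; zero-variance columns are
# centred only
standardizeTrain <- function(X, scale = TRUE) {
  n <- nrow(X)
  ctr <- colMeans(X)
  if (scale) {
    s <- sqrt(pmax(colSums(X * X) - n * ctr^2, 0) / (n - 1))
    s[s < 1e-12 | is.na(s)] <- 1
  } else s <- rep(1, ncol(X))
  list(X = sweep(sweep(X, 2, ctr), 2, s, "/"), center = ctr, scale = s)
}

applyStandardize <- function(X, std) {
  sweep(sweep(X, 2, std$center), 2, std$scale, "/")
}
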