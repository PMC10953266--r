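# Small shared helpers: deterministic seed derivation, z-scoring, Pearson
# over matrix rows, RNG-scope isolation.

#' Derive a reproducible child seed from a parent seed and context tags
#'
#' Mixes the parent seed with integer or character tags (character tags are
#' folded through their UTF-8 code points) into a 31-bit integer, so every
#' stochastic sub-task (subject, stage, restart, repeat) gets an
#' independent, reproducible stream.
#'
#' @param seed parent integer seed.
#' @param ... integer or character context tags.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (tag in tags) {
    ints <- if (is.character(tag)) utf8ToInt(paste(tag, collapse = "|"))
            else as.numeric(tag)
    for (v in ints) h <- (h * 31 + (v %% 2147483647) + 7) %% 2147483647
  }
  as.integer(max(1, h))
}

# Evaluate `expr` with its own RNG stream without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Population z-score (divide by sqrt(mean squared deviation), not n-1).
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("cannot z-score a constant vector")
  (x - m) / s
}

# Pearson r of each row of `a` against the matching row of `b`.
row_pearson <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  if (any(den == 0)) stop("zero-variance spectrum in Pearson correlation")
  rowSums(ac * bc) / den
}

# Row-normalize a non-negative matrix so each row sums to 1.
row_normalize <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)[1]
    nm <- if (!is.null(rownames(m))) rownames(m)[bad] else as.character(bad)
    stop("zero row sum (isolated region): ", nm)
  }
  m / rs
}
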