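#' @keywords internal
"_PACKAGE"

#' @importFrom stats dgeom dnbinom dpois pnbinom optim rgeom rpois
#'   runif rlnorm rmultinom setNames lm coef shapiro.test wilcox.test
#' @importFrom utils write.table read.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Run code under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards. All seeded operations in the package go
## through this so that library calls elsewhere never perturb reproducibility.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic 31-bit seed derived from a base seed and arbitrary string
## labels; keeps per-job seeds independent without a hashing dependency.
derive_seed <- function(base_seed, ...) {
  labs <- paste(c(as.character(base_seed), as.character(unlist(list(...)))),
                collapse = "\r")
  h <- 0
  for (v in utf8ToInt(labs)) h <- (h * 31 + v) %% 2147483629
  as.integer(h %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stopf("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Substitute single characters at 0-based positions of a string.
subst_chars <- function(s, pos0, chars) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  v[pos0 + 1L] <- chars
  paste(v, collapse = "")
}

chars_at <- function(s, pos0) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(v[pos0 + 1L], collapse = "")
}
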