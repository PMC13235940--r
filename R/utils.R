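# Internal numerical helpers shared across modules.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax with max-subtraction; equals the mathematical softmax.
row_softmax <- function(logits) {
  if (any(!is.finite(logits))) {
    abort("Non-finite pooling logits.", class = "scprogram_nonfinite")
  }
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Derive k reproducible substream seeds (< 2^31) from one master seed.
substream_seeds <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "scprogram_argument")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "scprogram_argument")
  }
  invisible(as.integer(x))
}
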