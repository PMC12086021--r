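#' @importFrom stats median optim p.adjust rnbinom rnorm rpois runif sd var
#'   wilcox.test cor.test aggregate quantile
#' @importFrom methods new validObject is slot
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics hist
#' @importFrom grDevices png dev.off
NULL

PERIODS <- c("pre", "saline", "doi")
ROLES   <- c("standard", "oddball", "tuning")

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded helpers do not disturb an enclosing simulation stream. With
#' `seed = NULL` the expression simply uses the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-unit substream seed from a master seed; kept below 2^31 so the
# result is a valid R integer.
substreamSeed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483629)
}

#' Paired Wilcoxon signed-rank p-value with degenerate-case handling
#'
#' Wraps [stats::wilcox.test()] (paired, two-sided) with the conventions used
#' throughout the pipeline: pairs with missing values are dropped; fewer than
#' `minPairs` complete pairs gives `NA` (test not reported); all-zero
#' differences give p = 1 (no evidence of a shift).
#'
#' @param x,y Paired numeric vectors.
#' @param minPairs Minimum number of complete pairs for a defined p-value.
#' @return A single p-value, possibly `NA`.
#' @export
wilcoxSignedRank <- function(x, y, minPairs = 6L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < minPairs) return(NA_real_)
  if (all(x == y)) return(1)
  suppressWarnings(wilcox.test(x, y, paired = TRUE)$p.value)
}

# Unpaired two-sided Mann-Whitney U p-value with the same minimum-n guard.
mannWhitneyU <- function(x, y, minN = 6L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < minN || length(y) < minN) return(NA_real_)
  suppressWarnings(wilcox.test(x, y)$p.value)
}

# FNV-1a 32-bit hash of a character scalar; used to stamp outputs with a
# configuration fingerprint.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Count spikes in half-open windows [start, end); spikes must be sorted.
countInWindows <- function(spikes, starts, ends) {
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

# stats::aggregate wrapper returning a plain data.frame with given value name.
aggMean <- function(df, value, by, name = value) {
  out <- aggregate(df[[value]], df[by], mean)
  names(out)[ncol(out)] <- name
  out
}
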