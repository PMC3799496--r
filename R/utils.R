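# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage random seed from a global seed
#'
#' Fans one global seed out into independent per-stage seeds keyed by the
#' stage name, so toggling one stochastic stage does not reshuffle another's
#' randomness. Result is a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 65521
  as.integer((abs(as.numeric(seed)) * 48271 + h * 10007) %% 2147483587)
}

#' Beta-binomial random draws
#'
#' Draws counts with intra-class correlation `rho`; `rho = 0` reduces to the
#' binomial. Degenerate probabilities 0 and 1 are handled exactly. Used by the
#' synthetic-data generator to give junction counts the depth-dependent
#' overdispersion that the local-SD noise model is designed to absorb.
#'
#' @param n number of draws.
#' @param size vector of totals (recycled).
#' @param prob vector of success probabilities (recycled).
#' @param rho overdispersion in [0, 1).
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  size <- rep_len(as.integer(size), n)
  prob <- rep_len(prob, n)
  stopifnot(all(prob >= 0 & prob <= 1))
  if (rho == 0) return(stats::rbinom(n, size, prob))
  p <- prob
  mid <- prob > 0 & prob < 1
  if (any(mid)) {
    a <- prob[mid] * (1 - rho) / rho
    b <- (1 - prob[mid]) * (1 - rho) / rho
    p[mid] <- stats::rbeta(sum(mid), a, b)
  }
  stats::rbinom(n, size, p)
}

# Sliding-window standard deviation over a vector already in window order.
# Constant window size w; windows are shifted inward (not shrunk) at the edges.
running_sd <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 2L, n >= w)
  h <- w %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, lo + w - 1L)
  lo <- pmax(1L, hi - w + 1L)
  x <- x - mean(x)  # centring avoids catastrophic cancellation in cumsums
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  s <- cs[hi + 1L] - cs[lo]
  s2 <- cs2[hi + 1L] - cs2[lo]
  m <- hi - lo + 1L
  sqrt(pmax(0, (s2 - s * s / m) / (m - 1)))
}

# 0-based half-open interval -> GRanges (1-based closed), vectorised.
as_granges0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand
  )
}

# Point positions (0-based) -> width-1 GRanges.
points_granges0 <- function(chrom, pos, strand = "*") {
  as_granges0(chrom, pos, pos + 1L, strand)
}
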