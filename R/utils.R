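# Internal helpers shared across modules.

# Deterministic per-record substream seed. The multiplier is coprime with
# 2^31 - 1 so distinct records under the same (seed, salt) never collide;
# record draws are therefore unaffected by cohort-size changes.
.substream_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) %% 2147483647) * 69069 +
    as.double(index) * 104729 + as.double(salt) * 7919
  as.integer(s %% 2147483647)
}

# Evaluate `code` without disturbing the caller's RNG state.
.with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Weighted quantiles
#'
#' Type-1 (inverse weighted ECDF) quantiles: the smallest observed value
#' whose cumulative weight share reaches `probs`.
#'
#' @param x numeric vector.
#' @param w positive weights, recycled to `length(x)`.
#' @param probs probabilities in \[0, 1\].
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  stopifnot(length(x) > 0, all(probs >= 0 & probs <= 1))
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(w, length(x))
  if (any(w < 0) || all(w == 0)) stop("weights must be non-negative, not all zero")
  ord <- order(x)
  xo <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(xo[1L])
    xo[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

.check_prob_weights <- function(pred, outcome, weights) {
  n <- length(pred)
  if (length(outcome) != n) stop("pred and outcome must have equal length")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match pred in length")
  if (any(!is.finite(pred)) || any(pred < 0) || any(pred > 1)) {
    stop("predicted risks must be finite and in [0, 1]")
  }
  if (any(weights <= 0)) stop("weights must be strictly positive")
  list(pred = pred, y = as.numeric(outcome), w = as.numeric(weights))
}
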