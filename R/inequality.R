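#' Validate a weighted sample of access times
#'
#' @param x nonnegative values (travel times in minutes, or distances)
#' @param w nonnegative weights (population counts); default all 1
#' @return list with sorted `x`, `w` and `n_effective = sum(w)`
#' @keywords internal
check_weighted_sample <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  if (length(x) == 0L) stop("empty sample", call. = FALSE)
  if (length(w) != length(x)) stop("x and w lengths differ", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0)) stop("values must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0", call. = FALSE)
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (sum(w) <= 0) stop("total weight must be > 0", call. = FALSE)
  o <- order(x)
  list(x = x[o], w = w[o], n_effective = sum(w))
}

#' Relative mean difference D of a weighted sample
#'
#' The mean absolute pairwise difference of the sample divided by its mean:
#' \deqn{D = \frac{\sum_i \sum_j w_i w_j |x_i - x_j| / (\sum_k w_k)^2}{\bar x},}
#' with the population-weighted mean \eqn{\bar x = \sum w_i x_i / \sum w_i}.
#' D is dimensionless, scale invariant, lies in `[0, 2)` and equals twice
#' the Gini coefficient. Weights are population counts, so a block-level
#' computation with integer weights equals the per-person computation on
#' the exploded sample.
#'
#' Computed by the sorted O(n log n) prefix-sum identity, which agrees with
#' the O(n^2) double sum to floating-point accuracy.
#'
#' @param x nonnegative values; @param w nonnegative weights (default 1)
#' @return D, a single number in `[0, 2)`
#' @examples
#' relative_mean_difference(c(1, 3))          # 0.5
#' relative_mean_difference(c(0, 0, 0, 4))    # 1.5
#' relative_mean_difference(c(5, 5, 5))       # 0
#' @export
relative_mean_difference <- function(x, w = NULL) {
  s <- check_weighted_sample(x, w)
  W <- s$n_effective
  xbar <- sum(s$w * s$x) / W
  if (xbar <= 0)
    stop("weighted mean is zero (all access times zero); D is undefined",
         call. = FALSE)
  n <- length(s$x)
  if (n == 1L) return(0)
  P <- cumsum(s$w)            # cumulative weight
  S <- cumsum(s$w * s$x)      # cumulative weighted value
  # sum over ordered pairs i > j of w_i w_j (x_i - x_j), doubled for |.|
  md <- 2 * sum(s$w[-1] * (s$x[-1] * P[-n] - S[-n])) / W^2
  md / xbar
}

#' Weighted Gini coefficient
#'
#' Computed independently of [relative_mean_difference()] through the
#' Lorenz-curve trapezoid formula
#' \eqn{G = 1 - \sum_i p_i (L_i + L_{i-1})} on the ascending-sorted sample,
#' where \eqn{p_i} are weight shares and \eqn{L_i} cumulative value shares.
#' For any weighted sample `gini(x, w) == relative_mean_difference(x, w)/2`
#' up to floating point.
#'
#' @inheritParams relative_mean_difference
#' @return G in `[0, 1)`
#' @examples
#' gini(c(1, 3))  # 0.25
#' @export
gini <- function(x, w = NULL) {
  s <- check_weighted_sample(x, w)
  tot <- sum(s$w * s$x)
  if (tot <= 0)
    stop("weighted mean is zero (all access times zero); Gini is undefined",
         call. = FALSE)
  p <- s$w / s$n_effective
  L <- cumsum(s$w * s$x) / tot
  1 - sum(p * (L + c(0, L[-length(L)])))
}

#' Alternative inequality measures
#'
#' Robin Hood (Hoover) index, Theil's T entropy measure, and the Atkinson
#' index, in their standard population-weighted forms. Any of them can stand
#' in for D in the standardized ratio, and they are highly rank-correlated
#' with D on typical access-time distributions; D remains the default.
#'
#' Theil uses the `0 log 0 = 0` convention. Atkinson with `epsilon >= 1`
#' returns 1 when any value is 0 (the equally-distributed equivalent
#' collapses to zero).
#'
#' @inheritParams relative_mean_difference
#' @param which subset of `c("robin_hood", "theil", "atkinson")`
#' @param epsilon Atkinson inequality-aversion parameter, > 0 (default 0.5)
#' @return named numeric vector of the requested measures
#' @examples
#' alt_measures(c(1, 3))   # robin_hood 0.25, theil, atkinson
#' @export
alt_measures <- function(x, w = NULL,
                         which = c("robin_hood", "theil", "atkinson"),
                         epsilon = 0.5) {
  which <- match.arg(which, several.ok = TRUE)
  s <- check_weighted_sample(x, w)
  mu <- sum(s$w * s$x) / s$n_effective
  if (mu <= 0) stop("weighted mean is zero; measures undefined", call. = FALSE)
  out <- numeric(0)
  p <- s$w / s$n_effective
  if ("robin_hood" %in% which) {
    # max vertical gap between the equality line and the Lorenz curve;
    # the max over sample vertices is exact for the discrete distribution
    F_ <- cumsum(p)
    L <- cumsum(s$w * s$x) / sum(s$w * s$x)
    out <- c(out, robin_hood = max(c(0, F_ - L)))
  }
  if ("theil" %in% which) {
    r <- s$x / mu
    term <- ifelse(r > 0, r * log(r), 0)
    out <- c(out, theil = sum(p * term))
  }
  if ("atkinson" %in% which) {
    if (!is.finite(epsilon) || epsilon <= 0)
      stop("atkinson epsilon must be > 0", call. = FALSE)
    if (abs(epsilon - 1) < 1e-12) {
      ede <- if (any(s$x == 0)) 0 else exp(sum(p * log(s$x)))
    } else if (epsilon > 1 && any(s$x == 0)) {
      ede <- 0
    } else {
      ede <- sum(p * s$x^(1 - epsilon))^(1 / (1 - epsilon))
    }
    out <- c(out, atkinson = 1 - ede / mu)
  }
  out[which]
}
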