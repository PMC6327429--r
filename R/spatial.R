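#' Inverse-distance spatial weights between block centroids
#'
#' Builds the n x n weight matrix \eqn{w_{ij} = 1/d_{ij}} from Euclidean
#' distances between planar block centroids, with zero diagonal and optional
#' row standardisation (each row divided by its sum, so rows with any
#' neighbour sum to 1). Coordinates are assumed planar — at town scale the
#' curvature of the earth is irrelevant.
#'
#' @param geometry tibble with columns `block_id`, `x`, `y` (at least 3
#'   rows; ids unique; no two blocks at the same point).
#' @param row_standardize divide each row by its sum (the default for
#'   Moran's I).
#' @return object of class `spatial_weights`: list with `unit_ids`,
#'   `matrix`, `row_standardized`.
#' @export
inverse_distance_weights <- function(geometry, row_standardize = TRUE) {
  stopifnot(nrow(geometry) >= 3)
  if (anyDuplicated(geometry$block_id)) stop("duplicate block ids")
  d <- as.matrix(dist(cbind(geometry$x, geometry$y)))
  zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop("duplicate coordinates for blocks '",
         geometry$block_id[zero[1, 1]], "' and '",
         geometry$block_id[zero[1, 2]], "' (infinite weight)")
  }
  w <- 1 / d
  diag(w) <- 0
  dimnames(w) <- NULL
  if (row_standardize) {
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  structure(list(unit_ids = as.character(geometry$block_id),
                 matrix = w, row_standardized = row_standardize),
            class = "spatial_weights")
}

#' Moran's I test of spatial autocorrelation
#'
#' Global Moran's I for block-level values (e.g. haplotype frequencies)
#' under an inverse-distance weighting scheme:
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with centred values \eqn{z_i} and \eqn{S_0 = \sum_{ij} w_{ij}}. The
#' expectation under no autocorrelation is \eqn{-1/(n-1)}; the p-value uses
#' the closed-form variance under the chosen null (normal values, or random
#' permutation of the observed values, which adds a kurtosis term) and a
#' two-sided normal approximation. A distribution-free permutation test
#' (random relabelling of values over locations) is available via `nperm`.
#' Units with missing values are dropped, together with their weight
#' rows/columns, before anything is computed.
#'
#' @param values numeric vector aligned with `weights$unit_ids`; `NA`s are
#'   dropped pairwise.
#' @param weights a [inverse_distance_weights()] object.
#' @param variance closed form for the null variance: `"normality"`
#'   (default) or `"randomization"`.
#' @param nperm if > 0, also compute a permutation p-value with this many
#'   random relabellings.
#' @return object of class `moran_result`: `observed_I`, `expected_I`
#'   (= -1/(n-1)), `variance`, `z`, `p_value` (normal approximation),
#'   `p_permutation` (or `NA`), `n`.
#' @export
morans_i <- function(values, weights,
                     variance = c("normality", "randomization"),
                     nperm = 0L) {
  variance <- match.arg(variance)
  stopifnot(inherits(weights, "spatial_weights"),
            length(values) == length(weights$unit_ids))
  keep <- !is.na(values)
  x <- values[keep]
  w <- weights$matrix[keep, keep, drop = FALSE]
  if (weights$row_standardized && any(!keep)) {
    # keep the row-standardisation property on the retained units
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 units with non-missing values")
  if (max(x) == min(x)) stop("zero variance: values are constant")

  I_obs <- moran_statistic(x, w)
  EI <- -1 / (n - 1)

  # Closed-form null variance from the S1, S2 spatial moments.
  S0 <- sum(w)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  if (variance == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  } else {
    zc <- x - mean(x)
    k <- (sum(zc^4) / n) / (sum(zc^2) / n)^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             k * (n * (n - 1) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - 1 / (n - 1)^2
  }
  z <- (I_obs - EI) / sqrt(VI)
  p <- 2 * pnorm(-abs(z))

  p_perm <- NA_real_
  if (nperm > 0) {
    I_perm <- vapply(seq_len(nperm),
                     function(i) moran_statistic(sample(x), w), numeric(1))
    p_perm <- (1 + sum(abs(I_perm - EI) >= abs(I_obs - EI))) / (nperm + 1)
  }

  structure(list(observed_I = I_obs, expected_I = EI, variance = VI,
                 z = z, p_value = p, p_permutation = p_perm, n = n),
            class = "moran_result")
}

moran_statistic <- function(x, w) {
  zc <- x - mean(x)
  (length(x) / sum(w)) * as.numeric(zc %*% w %*% zc) / sum(zc^2)
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f), n = %d, P = %.4g\n",
              x$observed_I, x$expected_I, sqrt(x$variance), x$n, x$p_value))
  if (!is.na(x$p_permutation)) {
    cat(sprintf("  permutation P = %.4g\n", x$p_permutation))
  }
  invisible(x)
}
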