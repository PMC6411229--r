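# Co-phosphorylation: correlation between phosphorylation profiles, and the
# complete weighted network it induces over measured phosphosites.
#
# The primary estimator is the biweight midcorrelation, a robust analogue of
# Pearson correlation that replaces means by medians and downweights
# observations far from the median with Tukey biweights:
#
#   u_i   = (x_i - med(x)) / (9 * mad(x))          mad unscaled (no 1.4826)
#   w_i   = (1 - u_i^2)^2 * I(|u_i| < 1)
#   x'_i  = (x_i - med(x)) w_i / sqrt(sum_j [(x_j - med(x)) w_j]^2)
#   c_xy  = sum_i x'_i y'_i
#
# Observations with |u| >= 1 get weight exactly 0 but still appear (with
# zero contribution) in the normalisation sum, so c_xx = 1 and |c_xy| <= 1.

# Median-centred, biweighted, norm-1 version of a profile; NULL when the
# profile is degenerate (mad = 0 or all weighted deviations zero).
.bicor_transform <- function(x) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx == 0) return(NULL)
  u <- (x - med) / (9 * madx)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  num <- (x - med) * w
  denom <- sqrt(sum(num^2))
  if (denom == 0) return(NULL)
  num / denom
}

.pearson_transform <- function(x) {
  cx <- x - mean(x)
  denom <- sqrt(sum(cx^2))
  if (denom == 0) return(NULL)
  cx / denom
}

#' Biweight midcorrelation of two phosphorylation profiles
#'
#' Robust correlation in `[-1, 1]` using medians, unscaled median absolute
#' deviations, and Tukey biweights with the conventional `9 * mad` scale.
#' Observations more than nine MADs from the median receive zero weight,
#' which makes the estimator far less sensitive to single outliers than
#' Pearson correlation.
#'
#' @param x,y numeric vectors of equal length `m >= 3`.
#' @return A single correlation value, clamped to `[-1, 1]` against
#'   floating-point overshoot.
#' @examples
#' biweight_midcorrelation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
#' @export
biweight_midcorrelation <- function(x, y) {
  .check_profile_pair(x, y)
  xt <- .bicor_transform(x)
  if (is.null(xt)) stop("degenerate profile (mad = 0): first argument")
  yt <- .bicor_transform(y)
  if (is.null(yt)) stop("degenerate profile (mad = 0): second argument")
  min(1, max(-1, sum(xt * yt)))
}

#' Pearson correlation of two phosphorylation profiles
#'
#' The standard product-moment correlation, provided as the non-robust
#' alternative to [biweight_midcorrelation()].
#'
#' @inheritParams biweight_midcorrelation
#' @return A single correlation value in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  .check_profile_pair(x, y)
  if (stats::sd(x) == 0) stop("degenerate profile (zero variance): first argument")
  if (stats::sd(y) == 0) stop("degenerate profile (zero variance): second argument")
  min(1, max(-1, stats::cor(x, y)))
}

.check_profile_pair <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("profiles must have at least 3 states")
  if (anyNA(x) || anyNA(y)) stop("profiles must not contain missing values")
  invisible(NULL)
}

#' Build the co-phosphorylation network
#'
#' Computes the complete weighted undirected graph over all measured
#' phosphosites: nodes are sites, and the weight of edge (p, q) is the
#' co-phosphorylation `c_pq` of their profiles. Degenerate profiles (median
#' absolute deviation zero under `bicor`, zero variance under `pearson`)
#' cannot be correlated and are excluded from the network; their identifiers
#' are reported in a warning and kept in the `dropped_sites` field.
#'
#' Each profile is transformed once (centred, weighted, normalised to unit
#' Euclidean norm) and all pairwise weights are obtained as inner products
#' of transformed rows, computed in row blocks of `block_size` sites to
#' bound memory; results are independent of the block size.
#'
#' @param matrix a [phospho_matrix()].
#' @param method `"bicor"` (default) or `"pearson"`.
#' @param block_size rows per block in the pairwise product.
#' @return Object of class `cophos_network`: a list with `sites` (character),
#'   `weights` (symmetric matrix, unit diagonal, entries in `[-1, 1]`),
#'   `method`, and `dropped_sites`.
#' @export
build_cophos_network <- function(matrix, method = c("bicor", "pearson"),
                                 block_size = 2048L) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "phospho_matrix"))
  f <- if (method == "bicor") .bicor_transform else .pearson_transform
  rows <- lapply(seq_len(nrow(matrix)), function(i) f(matrix[i, ]))
  degenerate <- vapply(rows, is.null, logical(1L))
  dropped <- rownames(matrix)[degenerate]
  if (length(dropped) > 0L) {
    warning("excluded ", length(dropped), " degenerate profile(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- which(!degenerate)
  if (length(keep) < 2L) stop("fewer than 2 non-degenerate profiles")
  P <- do.call(rbind, rows[keep])
  n <- nrow(P)
  W <- base::matrix(0, n, n)
  for (start in seq(1L, n, by = block_size)) {
    idx <- start:min(start + block_size - 1L, n)
    W[idx, ] <- tcrossprod(P[idx, , drop = FALSE], P)
  }
  W[W > 1] <- 1
  W[W < -1] <- -1
  W <- (W + t(W)) / 2  # enforce exact symmetry
  diag(W) <- 1
  sites <- rownames(matrix)[keep]
  dimnames(W) <- list(sites, sites)
  structure(list(sites = sites, weights = W, method = method,
                 dropped_sites = dropped),
            class = "cophos_network")
}

#' @export
print.cophos_network <- function(x, ...) {
  cat("Co-phosphorylation network: ", length(x$sites), " sites (",
      x$method, "), ", length(x$dropped_sites),
      " degenerate site(s) excluded\n", sep = "")
  invisible(x)
}

#' All pairwise co-phosphorylation values of a network
#'
#' @param network a `cophos_network`.
#' @return Numeric vector of the `n(n-1)/2` upper-triangle edge weights.
#' @export
network_values <- function(network) {
  stopifnot(inherits(network, "cophos_network"))
  network$weights[upper.tri(network$weights)]
}

#' Moment summary of a co-phosphorylation distribution
#'
#' Reports the sample mean, standard deviation (denominator `n - 1`),
#' skewness (standardised third central moment) and kurtosis (standardised
#' fourth central moment, non-excess: a normal distribution gives 3), the
#' summaries conventionally quoted for co-phosphorylation histograms.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return One-row data.frame with columns `mean`, `sd`, `skewness`,
#'   `kurtosis`, `n_pairs`.
#' @export
summarize_distribution <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("constant values: skewness/kurtosis undefined")
  data.frame(mean = mean(values),
             sd = s,
             skewness = e1071::skewness(values, type = 1),
             kurtosis = e1071::kurtosis(values, type = 1) + 3,
             n_pairs = length(values))
}
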