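# Naive Bayes kinase-substrate scoring.
#
# Two empirical co-phosphorylation distributions drive the score: the
# background distribution A over all measured site pairs, and the
# shared-kinase distribution S over pairs of sites annotated to a common
# kinase. Because shared-kinase pairs are right-shifted relative to
# background, the tail-probability ratio
#
#   Pr(C > c | S) / Pr(C > c | A)
#
# exceeds 1 for strongly co-phosphorylated pairs. The score of kinase k for
# site p sums the log2 of this ratio over the edges from p to k's annotated
# substrates measured in the data:
#
#   h(k, p) = sum over q in (P intersect T_k), q != p,
#             of log2( S_surv(c_pq) / A_surv(c_pq) )
#
# Kinases are ranked per site by decreasing h; larger h means k is more
# likely to phosphorylate p.

# Index the measured substrates of every kinase: list kinase -> integer
# indices into network$sites. Kinases with no measured substrate map to
# integer(0).
.kinase_site_index <- function(network, ksa) {
  idx <- match(ksa$site_id, network$sites)
  keep <- !is.na(idx)
  split(idx[keep], ksa$kinase[keep])
}

# Unordered shared-kinase pairs among measured sites: data.frame with the
# pair indices (i < j), the edge weight, and the number of distinct kinases
# sharing the pair.
.shared_pairs <- function(network, ksa) {
  ksi <- .kinase_site_index(network, ksa)
  pieces <- lapply(ksi, function(idx) {
    if (length(idx) < 2L) return(NULL)
    idx <- sort(idx)
    cmb <- utils::combn(idx, 2L)
    data.frame(i = cmb[1L, ], j = cmb[2L, ])
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || nrow(df) == 0L) {
    stop("no shared-kinase pair is measured: cannot fit the tail model")
  }
  key <- df$i * (length(network$sites) + 1) + df$j
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  k <- as.numeric(agg$key)
  i <- k %/% (length(network$sites) + 1)
  j <- k %% (length(network$sites) + 1)
  data.frame(i = i, j = j,
             value = network$weights[cbind(i, j)],
             n_kinases = agg$Freq)
}

#' Co-phosphorylation values of shared-kinase pairs
#'
#' Two measured phosphosites form a *shared-kinase pair* when they are
#' annotated as substrates of at least one common kinase. Each unordered
#' pair contributes exactly one value, no matter how many kinases it shares.
#' These values form the distribution S of the tail model.
#'
#' @param network a `cophos_network`.
#' @param ksa a [ksa_annotation()] with at least one kinase having two or
#'   more measured substrates.
#' @return Numeric vector of edge weights.
#' @export
collect_shared_kinase_values <- function(network, ksa) {
  .shared_pairs(network, ksa)$value
}

#' Fit empirical tail models for the background and shared-kinase
#' distributions
#'
#' Each distribution is represented by its empirical survival function with
#' an add-one continuity correction:
#' `survival(c) = (#\{v > c\} + 1) / (n + 1)`, clamped below by `epsilon`
#' (default `1/(n + 1)` per distribution). The correction keeps survival
#' probabilities strictly positive above the sample support, so the
#' log-ratio score is always finite.
#'
#' @param all_values background co-phosphorylation values (distribution A,
#'   all measured pairs).
#' @param shared_values shared-kinase pair values (distribution S).
#' @param epsilon probability floor; `NULL` (default) uses `1/(n + 1)` of
#'   each distribution.
#' @return Object of class `tail_model`.
#' @export
fit_tail_model <- function(all_values, shared_values, epsilon = NULL) {
  if (length(all_values) == 0L || length(shared_values) == 0L) {
    stop("both value sets must be non-empty")
  }
  structure(list(
    background = sort(all_values),
    shared = sort(shared_values),
    eps_background = if (is.null(epsilon)) 1 / (length(all_values) + 1)
                     else epsilon,
    eps_shared = if (is.null(epsilon)) 1 / (length(shared_values) + 1)
                 else epsilon
  ), class = "tail_model")
}

#' @export
print.tail_model <- function(x, ...) {
  cat("Tail model: |A| = ", length(x$background),
      ", |S| = ", length(x$shared), "\n", sep = "")
  invisible(x)
}

.tail_survival <- function(sorted, q, eps) {
  n <- length(sorted)
  s <- (n - findInterval(q, sorted) + 1) / (n + 1)
  pmin(1, pmax(eps, s))
}

#' Survival probability under a fitted tail model
#'
#' @param model a [fit_tail_model()] result.
#' @param c numeric vector of co-phosphorylation values to query.
#' @param which `"shared"` for `Pr(C > c | S)` or `"background"` for
#'   `Pr(C > c | A)`.
#' @return Numeric vector of survival probabilities in `(0, 1]`.
#' @export
survival_prob <- function(model, c, which = c("shared", "background")) {
  which <- match.arg(which)
  stopifnot(inherits(model, "tail_model"))
  if (which == "shared") .tail_survival(model$shared, c, model$eps_shared)
  else .tail_survival(model$background, c, model$eps_background)
}

# log2 likelihood ratio of one edge weight (vectorised).
.llr <- function(model, c) {
  log2(survival_prob(model, c, "shared") /
         survival_prob(model, c, "background"))
}

#' Score one kinase for one phosphosite
#'
#' Computes `h(k, p)`, the log-likelihood of association between kinase `k`
#' and site `p`, from the co-phosphorylation of `p` with `k`'s annotated
#' substrates measured in the network (excluding `p` itself). When `k` has
#' no measured substrate other than `p` there is no evidence either way and
#' the score is `NA` ("unscorable") — deliberately not 0, which is a
#' meaningful likelihood value.
#'
#' @param kinase kinase name.
#' @param site canonical site identifier, present in the network.
#' @param network a `cophos_network`.
#' @param ksa a [ksa_annotation()].
#' @param tails a [fit_tail_model()] result.
#' @return `h(k, p)` as a single number, or `NA_real_` if unscorable.
#' @export
score_kinase_site <- function(kinase, site, network, ksa, tails) {
  p <- match(site, network$sites)
  if (is.na(p)) stop("site ", site, " is not in the network")
  subs <- match(ksa_sites(ksa, kinase), network$sites)
  subs <- setdiff(subs[!is.na(subs)], p)
  if (length(subs) == 0L) return(NA_real_)
  sum(.llr(tails, network$weights[p, subs]))
}

#' Rank all kinases for every site in the network
#'
#' Computes `h(k, p)` for every (kinase, site) combination and ranks, per
#' site, all scorable kinases by decreasing score; ties are broken by
#' ascending kinase name so that output is deterministic. Unscorable
#' kinases (no measured substrate other than the site itself) are omitted
#' from a site's ranking. The fraction of network sites that receive at
#' least one prediction is attached as attribute `coverage`.
#'
#' @inheritParams score_kinase_site
#' @return Object of class `prediction_table`: data.frame with columns
#'   `site_id`, `rank`, `kinase`, `score`, sorted by (site, rank).
#' @export
rank_all <- function(network, ksa, tails) {
  n <- length(network$sites)
  kinases <- sort(ksa_kinases(ksa))
  ksi <- .kinase_site_index(network, ksa)
  # L[p, q] = log2 likelihood ratio of edge (p, q); h(k, p) = sum of L over
  # k's measured substrates q != p.
  L <- matrix(.llr(tails, network$weights), n, n)
  M <- matrix(0, n, length(kinases), dimnames = list(NULL, kinases))
  for (k in kinases) M[ksi[[k]], k] <- 1
  H <- L %*% M
  self <- diag(L)  # contribution of q = p, to subtract where p is in T_k
  H <- H - self * M
  n_neighbours <- matrix(colSums(M), n, length(kinases), byrow = TRUE) - M
  H[n_neighbours == 0] <- NA_real_
  scorable <- !is.na(H)
  if (!any(scorable)) stop("no scorable (kinase, site) pair")
  rows <- which(scorable, arr.ind = TRUE)
  df <- data.frame(site_id = network$sites[rows[, 1L]],
                   kinase = kinases[rows[, 2L]],
                   score = H[scorable], stringsAsFactors = FALSE)
  df <- df[order(df$site_id, -df$score, df$kinase), , drop = FALSE]
  df$rank <- stats::ave(df$score, df$site_id,
                        FUN = function(s) seq_along(s))
  df <- df[, c("site_id", "rank", "kinase", "score")]
  df$rank <- as.integer(df$rank)
  rownames(df) <- NULL
  class(df) <- c("prediction_table", "data.frame")
  attr(df, "coverage") <- length(unique(df$site_id)) / n
  df
}

#' @export
print.prediction_table <- function(x, ...) {
  cat("Prediction table: ", length(unique(x$site_id)), " sites, ",
      length(unique(x$kinase)), " kinases",
      if (!is.null(attr(x, "coverage")))
        sprintf(", coverage %.1f%%", 100 * attr(x, "coverage")),
      "\n", sep = "")
  NextMethod()
}

#' Per-site top-ranked kinase of a prediction table
#'
#' @param table a `prediction_table`.
#' @return Named character vector: names are site identifiers, values the
#'   rank-1 kinase of each site.
#' @export
top_prediction <- function(table) {
  t1 <- table[table$rank == 1L, , drop = FALSE]
  stats::setNames(t1$kinase, t1$site_id)
}
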