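# Benchmarking protocols: leave-one-out cross-validation with top-k
# metrics, cross-dataset reproducibility of top-ranked predictions, and
# multi-dataset consensus with the three-category precision.

#' Leave-one-out cross-validation of kinase ranking
#'
#' For each annotated association (k, p) with `p` measured in the matrix,
#' the single association is hidden (all of `p`'s other annotations and all
#' of `k`'s other substrates remain), the shared-kinase tail model is refit
#' without the pairs that existed only because of that association, the
#' kinases are re-ranked for `p`, and the rank of the hidden *target
#' kinase* `k` is recorded. Associations whose removal leaves `k` with no
#' other measured substrate cannot be evaluated and are counted in the
#' `n_unevaluable` attribute (for `cophosk_plus`, a target kinase without a
#' static score for `p` is likewise unevaluable).
#'
#' Refitting the tail model inside every fold is what prevents the hidden
#' association from leaking into its own evaluation: the pair weights it
#' contributed to the shared distribution are removed before rescoring.
#' Only pairs shared through no other kinase drop out.
#'
#' @param matrix a [phospho_matrix()].
#' @param ksa a [ksa_annotation()] (already filtered to the minimum
#'   substrate count).
#' @param scorer `"cophosk"` (co-phosphorylation only) or `"cophosk_plus"`
#'   (integrated with static scores).
#' @param static a [static_scores()] table; required for `cophosk_plus`.
#' @param method correlation method for the network.
#' @param network optionally, a pre-built `cophos_network` for `matrix`
#'   (rebuilt when `NULL`).
#' @return Object of class `loocv_result`: data.frame with columns
#'   `site_id`, `kinase` (the target), `rank`, `n_kinases` (scorable
#'   kinases in that fold), plus attribute `n_unevaluable`.
#' @export
loocv <- function(matrix, ksa, scorer = c("cophosk", "cophosk_plus"),
                  static = NULL, method = c("bicor", "pearson"),
                  network = NULL) {
  scorer <- match.arg(scorer)
  method <- match.arg(method)
  if (scorer == "cophosk_plus" && is.null(static)) {
    stop("scorer 'cophosk_plus' requires a static score table")
  }
  if (is.null(network)) {
    network <- suppressWarnings(build_cophos_network(matrix, method = method))
  }
  n <- length(network$sites)
  kinases <- sort(ksa_kinases(ksa))
  ksi <- .kinase_site_index(network, ksa)
  shared <- .shared_pairs(network, ksa)
  all_values <- network_values(network)
  # key -> row of the shared-pair table, for O(1) per-fold lookup
  pair_key <- function(i, j) pmin(i, j) * (n + 1) + pmax(i, j)
  shared_key <- pair_key(shared$i, shared$j)
  static_lookup <- NULL
  if (scorer == "cophosk_plus") {
    static_lookup <- stats::setNames(static$score,
                                     paste(static$kinase, static$site_id,
                                           sep = "\r"))
  }
  records <- vector("list", nrow(ksa))
  n_unevaluable <- 0L
  for (a in seq_len(nrow(ksa))) {
    k <- ksa$kinase[a]
    p <- match(ksa$site_id[a], network$sites)
    if (is.na(p)) next  # site not measured: nothing to evaluate
    neigh <- setdiff(ksi[[k]], p)
    if (length(neigh) == 0L) {
      n_unevaluable <- n_unevaluable + 1L
      next
    }
    # pairs (p, q in T_k) leave S iff k was their only shared kinase
    fold_keys <- pair_key(p, neigh)
    hit <- match(fold_keys, shared_key)
    hit <- hit[!is.na(hit)]
    drop_rows <- hit[shared$n_kinases[hit] == 1L]
    s_values <- if (length(drop_rows) > 0L) shared$value[-drop_rows]
                else shared$value
    if (length(s_values) == 0L) {
      n_unevaluable <- n_unevaluable + 1L
      next
    }
    tails <- fit_tail_model(all_values, s_values)
    llr_p <- .llr(tails, network$weights[p, ])
    h <- vapply(kinases, function(kk) {
      qq <- setdiff(ksi[[kk]], p)
      if (length(qq) == 0L) return(NA_real_)
      sum(llr_p[qq])
    }, numeric(1L))
    if (scorer == "cophosk_plus") {
      x <- static_lookup[paste(kinases, network$sites[p], sep = "\r")]
      h <- h + log2(x)  # NA where either term is missing
    }
    scorable <- which(!is.na(h))
    if (!(match(k, kinases) %in% scorable)) {
      n_unevaluable <- n_unevaluable + 1L
      next
    }
    ord <- scorable[order(-h[scorable], kinases[scorable])]
    records[[a]] <- data.frame(site_id = network$sites[p], kinase = k,
                               rank = match(match(k, kinases), ord),
                               n_kinases = length(scorable),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, records)
  if (is.null(out)) {
    stop("no association could be evaluated")
  }
  rownames(out) <- NULL
  class(out) <- c("loocv_result", "data.frame")
  attr(out, "n_unevaluable") <- n_unevaluable
  out
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("LOOCV: ", nrow(x), " evaluated associations (",
      attr(x, "n_unevaluable"), " unevaluable); top-1 = ",
      sprintf("%.3f", topk_accuracy(x, 1L)), ", top-5 = ",
      sprintf("%.3f", topk_accuracy(x, 5L)), "\n", sep = "")
  invisible(x)
}

#' Top-k accuracy of a cross-validation result
#'
#' The fraction of hidden associations whose target kinase was ranked in
#' the top `k` positions.
#'
#' @param result a [loocv()] result.
#' @param k rank cutoff.
#' @return A fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(result, k) {
  if (nrow(result) == 0L) stop("empty cross-validation result")
  mean(result$rank <= k)
}

#' Cross-dataset reproducibility of top-ranked predictions
#'
#' Over the sites ranked in both prediction tables: the rate at which the
#' two top-ranked kinases are identical, and the rate at which the first
#' table's top-ranked kinase appears in the second table's top 5.
#'
#' @param pred_a,pred_b `prediction_table`s from two datasets.
#' @return List with `top1_match_rate`, `top1_in_top5_rate`, `n_common`.
#' @export
cross_dataset_reproducibility <- function(pred_a, pred_b) {
  top_a <- top_prediction(pred_a)
  top_b <- top_prediction(pred_b)
  common <- intersect(names(top_a), names(top_b))
  if (length(common) == 0L) stop("no site is ranked in both tables")
  b5 <- pred_b[pred_b$rank <= 5L, , drop = FALSE]
  in_top5 <- vapply(common, function(s) {
    top_a[[s]] %in% b5$kinase[b5$site_id == s]
  }, logical(1L))
  list(top1_match_rate = mean(top_a[common] == top_b[common]),
       top1_in_top5_rate = mean(in_top5),
       n_common = length(common))
}

#' Multi-dataset consensus of top-ranked predictions
#'
#' Collects the per-site top-ranked kinase from each prediction table and
#' stratifies sites by their cross-dataset agreement: a site's agreement
#' level `j` is the largest number of datasets whose top-ranked kinase is
#' identical (a site predicted in one dataset only has `j = 1`). Within
#' each level, sites are classified against the annotation: category 1 if
#' the consensus top-ranked kinase matches any annotated kinase of the
#' site, category 2 if the site is annotated but the prediction disagrees,
#' category 3 if the site has no annotation. Precision is
#' `cat1 / (cat1 + cat2)`.
#'
#' @param preds list of `prediction_table`s.
#' @param ksa a [ksa_annotation()].
#' @return Object of class `consensus_report`: data.frame with one row per
#'   agreement level (`n_agreeing`, `cat1`, `cat2`, `cat3`, `precision`).
#' @export
consensus <- function(preds, ksa) {
  stopifnot(length(preds) >= 1L)
  tops <- lapply(preds, top_prediction)
  sites <- unique(unlist(lapply(tops, names)))
  annotated <- split(ksa$kinase, ksa$site_id)
  levels_j <- integer(length(sites))
  cat_of <- integer(length(sites))
  for (s in seq_along(sites)) {
    site <- sites[s]
    votes <- unlist(lapply(tops, function(t) t[[site]]))
    tab <- sort(table(votes), decreasing = TRUE)
    # deterministic modal kinase: highest vote count, then name order
    winners <- names(tab)[tab == tab[1L]]
    consensus_kinase <- sort(winners)[1L]
    levels_j[s] <- tab[[1L]]
    ann <- annotated[[site]]
    cat_of[s] <- if (is.null(ann)) 3L
                 else if (consensus_kinase %in% ann) 1L else 2L
  }
  rows <- lapply(sort(unique(levels_j)), function(j) {
    sel <- levels_j == j
    c1 <- sum(cat_of[sel] == 1L)
    c2 <- sum(cat_of[sel] == 2L)
    c3 <- sum(cat_of[sel] == 3L)
    data.frame(n_agreeing = j, cat1 = c1, cat2 = c2, cat3 = c3,
               precision = if (c1 + c2 > 0L) c1 / (c1 + c2) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("consensus_report", "data.frame")
  out
}
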