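# Integrated scoring: combine the co-phosphorylation score with a static
# kinase-site score table (sequence/interaction-based likelihoods):
#
#   M(k, p) = h(k, p) + log2(x(k, p))
#
# Both terms are required, so integrated coverage is the intersection of the
# co-phosphorylation predictions with the static table. The static score is
# used raw (no rescaling before log2); users whose static tool reports on a
# different scale can pre-normalise, and per-site multiplicative rescaling
# of x leaves the ranking unchanged.

#' Combine co-phosphorylation and static kinase-site scores
#'
#' For every (kinase, site) pair scorable in both inputs, the integrated
#' score is the co-phosphorylation log-likelihood plus `log2` of the static
#' score. Pairs missing from either table are absent from the result,
#' unless `static_fallback = TRUE`, in which case pairs with a static score
#' for a site already present in `h_table` enter with the
#' co-phosphorylation term set to 0 (a static-only fallback). Sites are
#' re-ranked with the same tie-break as the base scoring (descending score,
#' then ascending kinase name).
#'
#' @param h_table a `prediction_table` from [rank_all()].
#' @param static a [static_scores()] table (all scores positive).
#' @param static_fallback substitute 0 for a missing co-phosphorylation
#'   term instead of dropping the pair.
#' @return A `prediction_table` with the integrated scores.
#' @export
combine_scores <- function(h_table, static, static_fallback = FALSE) {
  stopifnot(inherits(static, "static_scores"))
  if (nrow(h_table) == 0L || nrow(static) == 0L) {
    stop("both score tables must be non-empty")
  }
  h <- as.data.frame(h_table)[, c("site_id", "kinase", "score")]
  merged <- merge(static, h, by = c("kinase", "site_id"),
                  all.x = static_fallback,
                  suffixes = c(".static", ".h"))
  if (static_fallback) {
    # only sites with at least one co-phosphorylation prediction qualify
    merged <- merged[merged$site_id %in% h$site_id, , drop = FALSE]
    merged$score.h[is.na(merged$score.h)] <- 0
  }
  if (nrow(merged) == 0L) {
    stop("no (kinase, site) pair is scorable in both tables")
  }
  df <- data.frame(site_id = merged$site_id, kinase = merged$kinase,
                   score = merged$score.h + log2(merged$score.static),
                   stringsAsFactors = FALSE)
  df <- df[order(df$site_id, -df$score, df$kinase), , drop = FALSE]
  df$rank <- as.integer(stats::ave(df$score, df$site_id,
                                   FUN = function(s) seq_along(s)))
  df <- df[, c("site_id", "rank", "kinase", "score")]
  rownames(df) <- NULL
  class(df) <- c("prediction_table", "data.frame")
  df
}
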