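# Independent reference implementations used as oracles. These are
# deliberately written as plain scalar loops with no helpers shared with
# the package, so agreement with the package is a genuine cross-check.

# Straight-line transcription of the biweight midcorrelation definition:
# median-centred values, Tukey biweights at the 9*mad scale (mad unscaled),
# indicator weights, normalisation by the root sum of squares.
oracle_bicor <- function(x, y) {
  m <- length(x)
  med_of <- function(v) {
    s <- sort(v)
    if (length(s) %% 2 == 1) s[(length(s) + 1) / 2]
    else (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
  }
  mad_of <- function(v) med_of(abs(v - med_of(v)))
  transform <- function(v) {
    med <- med_of(v)
    madv <- mad_of(v)
    num <- numeric(m)
    for (i in seq_len(m)) {
      u <- (v[i] - med) / (9 * madv)
      w <- if (1 - abs(u) > 0) (1 - u^2)^2 else 0
      num[i] <- (v[i] - med) * w
    }
    ss <- 0
    for (i in seq_len(m)) ss <- ss + num[i]^2
    num / sqrt(ss)
  }
  xp <- transform(x)
  yp <- transform(y)
  total <- 0
  for (i in seq_len(m)) total <- total + xp[i] * yp[i]
  total
}

# Textbook product-moment correlation, scalar loops.
oracle_pearson <- function(x, y) {
  m <- length(x)
  mx <- sum(x) / m
  my <- sum(y) / m
  sxy <- sxx <- syy <- 0
  for (i in seq_len(m)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Naive add-one survival estimate: count values above the query.
oracle_survival <- function(sample, q, eps = 1 / (length(sample) + 1)) {
  cnt <- 0
  for (v in sample) if (v > q) cnt <- cnt + 1
  max(eps, min(1, (cnt + 1) / (length(sample) + 1)))
}

# Brute-force h(k, p): loop over every network site, test substrate
# membership, accumulate the log2 tail-probability ratio.
oracle_score <- function(kinase, site, network, ksa, all_values,
                         shared_values) {
  p <- which(network$sites == site)
  total <- 0
  n_neigh <- 0
  for (q in seq_along(network$sites)) {
    if (q == p) next
    is_sub <- any(ksa$kinase == kinase & ksa$site_id == network$sites[q])
    if (!is_sub) next
    c_pq <- network$weights[p, q]
    total <- total + log2(oracle_survival(shared_values, c_pq) /
                            oracle_survival(all_values, c_pq))
    n_neigh <- n_neigh + 1
  }
  if (n_neigh == 0) NA_real_ else total
}

# Exhaustive shared-kinase pair collection: double loop over site pairs.
oracle_shared_values <- function(network, ksa) {
  n <- length(network$sites)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- FALSE
      for (k in unique(ksa$kinase)) {
        subs <- ksa$site_id[ksa$kinase == k]
        if (network$sites[i] %in% subs && network$sites[j] %in% subs) {
          shared <- TRUE
          break
        }
      }
      if (shared) out <- c(out, network$weights[i, j])
    }
  }
  out
}

# Exhaustive per-site ranking from oracle scores (descending score, ties by
# kinase name).
oracle_rank_all <- function(network, ksa, all_values, shared_values) {
  kinases <- sort(unique(ksa$kinase))
  rows <- NULL
  for (site in network$sites) {
    h <- sapply(kinases, function(k) {
      oracle_score(k, site, network, ksa, all_values, shared_values)
    })
    sc <- which(!is.na(h))
    if (length(sc) == 0) next
    ord <- sc[order(-h[sc], kinases[sc])]
    rows <- rbind(rows, data.frame(site_id = site,
                                   rank = seq_along(ord),
                                   kinase = kinases[ord],
                                   score = unname(h[ord]),
                                   stringsAsFactors = FALSE))
  }
  rows[order(rows$site_id, rows$rank), ]
}

# Brute-force two-sample KS statistic: sweep the ECDF difference over the
# pooled support.
oracle_ks_D <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  best <- 0
  for (g in grid) {
    fa <- sum(a <= g) / length(a)
    fb <- sum(b <= g) / length(b)
    if (abs(fa - fb) > best) best <- abs(fa - fb)
  }
  best
}
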