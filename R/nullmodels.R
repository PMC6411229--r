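# Permutation null models for co-phosphorylation distributions.
#
# Three schemes destroy the profile structure at different granularities
# while conserving the corresponding value multisets:
#   within_state : permute values across sites separately inside each state
#                  column (each state keeps its marginal distribution)
#   within_site  : permute each site's profile across states (each site
#                  keeps its marginal distribution)
#   global       : permute all entries of the matrix jointly
#
# All randomness is keyed off a single integer seed; replicate r of a
# permutation ensemble uses seed + r - 1, so serial and parallel execution
# of the ensemble agree.

PERMUTATION_SCHEMES <- c("within_state", "within_site", "global")

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Permute a phosphorylation profile matrix
#'
#' Produces a null-model replicate of the matrix under one of the three
#' permutation schemes. The shape, site names and state labels are
#' preserved, as is the value multiset at the scheme's granularity
#' (per state column, per site row, or globally). Deterministic for a
#' fixed seed.
#'
#' @param matrix a [phospho_matrix()].
#' @param scheme one of `"within_state"`, `"within_site"`, `"global"`.
#' @param seed integer seed.
#' @return A [phospho_matrix()] of the same shape.
#' @export
permute_matrix <- function(matrix, scheme = PERMUTATION_SCHEMES, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(matrix, "phospho_matrix"))
  vals <- unclass(matrix)
  out <- .with_seed(seed, function() {
    switch(scheme,
      within_state = apply(vals, 2L, sample),
      within_site  = t(apply(vals, 1L, sample)),
      global = {
        v <- vals
        v[] <- sample(as.vector(vals))
        v
      })
  })
  dimnames(out) <- dimnames(vals)
  suppressWarnings(phospho_matrix(out))
}

#' Null distribution of co-phosphorylation under permutation
#'
#' Pools the co-phosphorylation values of `n_perm` independently permuted
#' replicates of the matrix into one null sample. Replicate `r` is permuted
#' with seed `seed + r - 1`.
#'
#' @inheritParams permute_matrix
#' @param method correlation method, `"bicor"` or `"pearson"`.
#' @param n_perm number of permutation replicates (>= 1).
#' @return Numeric vector of pooled edge weights, of length
#'   `n_perm * n(n-1)/2` minus any degeneracy exclusions.
#' @export
null_cophos_distribution <- function(matrix, scheme = PERMUTATION_SCHEMES,
                                     method = c("bicor", "pearson"),
                                     n_perm = 100L, seed = 1L) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  stopifnot(n_perm >= 1L)
  pooled <- vector("list", n_perm)
  for (r in seq_len(n_perm)) {
    pm <- permute_matrix(matrix, scheme, seed = seed + r - 1L)
    net <- suppressWarnings(build_cophos_network(pm, method = method))
    pooled[[r]] <- network_values(net)
  }
  unlist(pooled, use.names = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Compares two empirical co-phosphorylation distributions: `D` is the
#' supremum distance between their empirical CDFs, `p` the two-sided
#' Kolmogorov-Smirnov p-value. The exact null distribution is used when
#' either sample has fewer than 50 values, the asymptotic formula otherwise.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return List with elements `D` and `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty")
  }
  exact <- min(length(sample_a), length(sample_b)) < 50L
  kt <- suppressWarnings(
    stats::ks.test(sample_a, sample_b, exact = exact)
  )
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Sample-dimension adequacy analysis
#'
#' Assesses how many biological states are needed for the co-phosphorylation
#' signal to stand out from noise. For each dimension `d`, states are
#' subsampled `n_rep` times; each replicate records the standard deviation
#' of the subsampled co-phosphorylation distribution, the standard deviation
#' of its global-permutation null, and the KS statistic between the two.
#' Replicate averages are returned. As `d` grows, the null sd shrinks
#' (approximately `1/sqrt(d - 1)` for Pearson on independent profiles) and
#' real signal becomes more easily distinguishable from random.
#'
#' @param matrix a [phospho_matrix()] with `m` states.
#' @param dims integer vector of state counts to test, each in `[3, m]`.
#' @param n_rep subsampling replicates per dimension.
#' @param n_perm permutations per null distribution.
#' @param method correlation method.
#' @param seed integer seed.
#' @return data.frame with columns `d`, `sd_original`, `sd_null`, `ks_D`.
#' @export
dimension_adequacy <- function(matrix, dims, n_rep = 100L, n_perm = 10L,
                               method = c("bicor", "pearson"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(matrix, "phospho_matrix"))
  m <- ncol(matrix)
  if (any(dims < 3L | dims > m)) {
    stop("every dimension must be between 3 and ", m)
  }
  rows <- lapply(seq_along(dims), function(di) {
    d <- dims[di]
    sd_o <- sd_n <- ksd <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      rep_seed <- seed + (di - 1L) * n_rep + r - 1L
      cols <- if (d == m) seq_len(m) else
        .with_seed(rep_seed, function() sort(sample.int(m, d)))
      sub <- suppressWarnings(
        phospho_matrix(unclass(matrix)[, cols, drop = FALSE])
      )
      net <- suppressWarnings(build_cophos_network(sub, method = method))
      vals <- network_values(net)
      nulls <- null_cophos_distribution(sub, "global", method = method,
                                        n_perm = n_perm,
                                        seed = rep_seed + 999983L)
      sd_o[r] <- stats::sd(vals)
      sd_n[r] <- stats::sd(nulls)
      ksd[r] <- ks_compare(vals, nulls)$D
    }
    data.frame(d = d, sd_original = mean(sd_o), sd_null = mean(sd_n),
               ks_D = mean(ksd))
  })
  do.call(rbind, rows)
}
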