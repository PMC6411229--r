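# Latent-factor synthetic data generator.
#
# Each kinase is given a latent activity vector over the biological states
# (i.i.d. standard normal). A substrate of kinase k mixes that activity
# with site-specific noise:
#
#   profile = sqrt(rho) * (+/- activity_k) + sqrt(1 - rho) * noise
#
# so two substrates of the same kinase have expected correlation rho while
# background sites (pure noise) are uncorrelated. This reproduces the key
# empirical structure the scoring relies on — a shared-kinase pair
# distribution right-shifted relative to background — with a closed-form
# expected shift, which makes the generator usable as an oracle. Negative
# regulators (sign-flipped loadings) emulate inhibitory phosphorylation or
# phosphatase control: their pairs with ordinary substrates are
# anti-correlated. Multi-kinase sites load on two activity vectors at
# equal weight. The generator does not model mass-spec artefacts
# (missingness, ratio compression); inputs are post-quantification by
# assumption.

#' Configuration of the synthetic phosphoproteomics generator
#'
#' Defaults describe a mid-sized study: 20 biological states, 10 kinases
#' with 20 substrates each, 200 unannotated background sites and a
#' within-kinase correlation of 0.7 — enough signal for the shared-kinase
#' pair distribution to separate clearly from background.
#'
#' @param n_states number of biological states (columns), `>= 3`.
#' @param n_kinases number of kinases.
#' @param substrates_per_kinase substrates generated per kinase.
#' @param n_background unannotated pure-noise sites.
#' @param rho within-kinase correlation in `[0, 1]`.
#' @param multi_kinase_fraction fraction of substrate sites that load on a
#'   second, randomly chosen kinase.
#' @param negative_regulator_fraction fraction of substrate sites with a
#'   sign-flipped loading.
#' @param static_informativeness in `[0, 1]`: 0 makes static scores pure
#'   noise, 1 makes them driven by the true association.
#' @param seed integer seed; every draw of [generate_synthetic()] is a
#'   deterministic function of it.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_states = 20L, n_kinases = 10L,
                             substrates_per_kinase = 20L,
                             n_background = 200L, rho = 0.7,
                             multi_kinase_fraction = 0,
                             negative_regulator_fraction = 0,
                             static_informativeness = 0.5,
                             seed = 1L) {
  cfg <- list(n_states = as.integer(n_states),
              n_kinases = as.integer(n_kinases),
              substrates_per_kinase = as.integer(substrates_per_kinase),
              n_background = as.integer(n_background),
              rho = rho,
              multi_kinase_fraction = multi_kinase_fraction,
              negative_regulator_fraction = negative_regulator_fraction,
              static_informativeness = static_informativeness,
              seed = as.integer(seed))
  if (cfg$n_states < 3L) stop("n_states must be >= 3")
  if (cfg$n_kinases < 0L || cfg$substrates_per_kinase < 0L ||
      cfg$n_background < 0L) stop("counts must be >= 0")
  for (f in c("rho", "multi_kinase_fraction",
              "negative_regulator_fraction", "static_informativeness")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic phosphoproteomics dataset
#'
#' Draws a fold-change profile matrix, the true kinase-substrate
#' annotation, a static kinase-site score table over every (kinase, site)
#' combination, and the ground truth, all reproducible from the seed in
#' the configuration. Static scores are
#' `x(k, p) = exp(a * z_true + (1 - a) * z_noise)` with
#' `a = static_informativeness`, where `z_true` is a unit-variance normal
#' shifted by +2 for true associations and `z_noise` is independent noise;
#' scores are therefore always positive.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `matrix` ([phospho_matrix()]), `ksa`
#'   ([ksa_annotation()]), `static` ([static_scores()]), and `truth`
#'   (data.frame `site_id`, `kinase`, one row per true association,
#'   including second kinases of multi-kinase sites).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  c_ <- config
  .with_seed(c_$seed, function() {
    m <- c_$n_states
    K <- c_$n_kinases
    n_sub <- K * c_$substrates_per_kinase
    n <- n_sub + c_$n_background
    kin_names <- sprintf("KIN%02d", seq_len(max(K, 1L))[seq_len(K)])
    activity <- matrix(stats::rnorm(K * m), K, m,
                       dimnames = list(kin_names, NULL))
    residues <- sample(c("S", "T", "Y"), n, replace = TRUE,
                       prob = c(0.8, 0.15, 0.05))
    positions <- sample.int(999L, n, replace = TRUE)
    site_ids <- format_site_id(sprintf("PROT%04d", seq_len(n)),
                               residues, positions)
    primary <- rep(kin_names, each = c_$substrates_per_kinase)
    secondary <- rep(NA_character_, n_sub)
    n_multi <- floor(c_$multi_kinase_fraction * n_sub)
    if (n_multi > 0L && K >= 2L) {
      multi_idx <- sample.int(n_sub, n_multi)
      secondary[multi_idx] <- vapply(primary[multi_idx], function(k) {
        sample(setdiff(kin_names, k), 1L)
      }, character(1L))
    }
    sign <- rep(1, n_sub)
    n_neg <- floor(c_$negative_regulator_fraction * n_sub)
    if (n_neg > 0L) sign[sample.int(n_sub, n_neg)] <- -1
    vals <- matrix(stats::rnorm(n * m), n, m)  # site-specific noise
    if (n_sub > 0L) {
      factor_part <- activity[primary, , drop = FALSE]
      is_multi <- !is.na(secondary)
      if (any(is_multi)) {
        factor_part[is_multi, ] <-
          (factor_part[is_multi, , drop = FALSE] +
             activity[secondary[is_multi], , drop = FALSE]) / sqrt(2)
      }
      vals[seq_len(n_sub), ] <- sqrt(c_$rho) * sign * factor_part +
        sqrt(1 - c_$rho) * vals[seq_len(n_sub), , drop = FALSE]
    }
    dimnames(vals) <- list(site_ids,
                           sprintf("state%02d", seq_len(m)))
    truth <- data.frame(
      site_id = c(site_ids[seq_len(n_sub)],
                  site_ids[which(!is.na(secondary))]),
      kinase = c(primary, secondary[!is.na(secondary)]),
      stringsAsFactors = FALSE)
    truth <- truth[order(truth$site_id, truth$kinase), , drop = FALSE]
    rownames(truth) <- NULL
    a <- c_$static_informativeness
    is_true <- matrix(0, n, K, dimnames = list(site_ids, kin_names))
    is_true[cbind(match(truth$site_id, site_ids),
                  match(truth$kinase, kin_names))] <- 1
    z_true <- 2 * is_true + matrix(stats::rnorm(n * K), n, K)
    z_noise <- matrix(stats::rnorm(n * K), n, K)
    x <- exp(a * z_true + (1 - a) * z_noise)
    static <- suppressWarnings(static_scores(
      kinase = rep(kin_names, each = n),
      site_id = rep(site_ids, times = K),
      score = as.vector(x)))
    list(matrix = suppressWarnings(phospho_matrix(vals)),
         ksa = ksa_annotation(truth$kinase, truth$site_id),
         static = static,
         truth = truth)
  })
}

#' Subsample a kinase-substrate annotation
#'
#' Emulates an incomplete annotation database by keeping each association
#' independently with probability `keep_fraction`, then re-applying the
#' minimum-substrate filter.
#'
#' @param ksa a [ksa_annotation()].
#' @param keep_fraction retention probability in `(0, 1]`.
#' @param seed integer seed.
#' @param min_substrates minimum substrate count re-applied after
#'   subsampling.
#' @return A [ksa_annotation()].
#' @export
annotation_subsample <- function(ksa, keep_fraction, seed = 1L,
                                 min_substrates = 2L) {
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be in (0, 1]")
  }
  keep <- .with_seed(seed, function() {
    stats::runif(nrow(ksa)) <= keep_fraction
  })
  suppressMessages(
    ksa_annotation(ksa$kinase[keep], ksa$site_id[keep],
                   min_substrates = min_substrates)
  )
}
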