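test_that("LOOCV recovers a constructed target kinase and records ranks", {
  # p's only strong correlates are K1's other substrates
  set.seed(91)
  m <- 12
  z <- rnorm(m)
  vals <- rbind(p0 = z + rnorm(m, sd = 0.1),
                a1 = z + rnorm(m, sd = 0.1),
                a2 = z + rnorm(m, sd = 0.1),
                b1 = rnorm(m), b2 = rnorm(m), b3 = rnorm(m))
  rownames(vals) <- paste0("P", 1:6, "_S", 1:6)
  colnames(vals) <- paste0("s", 1:m)
  mat <- phospho_matrix(vals)
  ksa <- suppressMessages(ksa_annotation(
    kinase = c("K1", "K1", "K1", "K2", "K2", "K2"),
    site_id = rownames(vals)[1:6]))
  res <- loocv(mat, ksa)
  rec <- res[res$site_id == "P1_S1", ]
  expect_identical(rec$kinase, "K1")
  expect_equal(rec$rank, 1L)
  expect_true(all(res$rank >= 1 & res$rank <= res$n_kinases))

  # one record per annotated association that is evaluable
  expect_equal(nrow(res) + attr(res, "n_unevaluable"), nrow(ksa))
})

test_that("LOOCV refuses leakage: an association is unevaluable when the
           kinase has no other measured substrate", {
  mat <- make_matrix(n = 5, m = 8, seed = 92)
  net <- build_cophos_network(mat)
  # K2 has one measured substrate and one unmeasured: hiding the measured
  # association leaves no evidence for K2
  ksa <- suppressMessages(ksa_annotation(
    kinase = c("K1", "K1", "K1", "K2", "K2"),
    site_id = c(net$sites[1:4], "UNMEASURED_S1")))
  res <- loocv(mat, ksa, network = net)
  expect_false("K2" %in% res$kinase)
  expect_equal(attr(res, "n_unevaluable"), 1L)
  expect_equal(nrow(res), 3L)
})

test_that("hiding an association removes exactly its private shared pairs", {
  # recomputation check: scores in a fold equal a from-scratch scoring with
  # the association's private pairs removed from the shared distribution
  inst <- make_instance(n_sites = 8, m = 10, n_kinases = 2,
                        subs_per_kinase = 4, seed = 93)
  net <- inst$network
  ksa <- inst$ksa
  res <- loocv(inst$matrix, ksa, network = net)
  k <- ksa$kinase[1]; p_site <- ksa$site_id[1]
  # manual fold: drop pairs (p, q in T_k) shared through k only
  av <- network_values(net)
  manual_shared <- oracle_shared_values(
    net, suppressMessages(ksa_annotation(
      ksa$kinase[-1], ksa$site_id[-1], min_substrates = 1)))
  tails <- fit_tail_model(av, manual_shared)
  kin <- sort(ksa_kinases(ksa))
  h <- sapply(kin, function(kk) {
    subs <- setdiff(ksa_sites(ksa, kk), p_site)
    subs <- subs[subs %in% net$sites]
    if (length(subs) == 0) return(NA_real_)
    sum(sapply(subs, function(q) {
      c_pq <- net$weights[p_site, q]
      log2(oracle_survival(manual_shared, c_pq) /
             oracle_survival(av, c_pq))
    }))
  })
  sc <- which(!is.na(h))
  ord <- sc[order(-h[sc], kin[sc])]
  expect_equal(res$rank[res$site_id == p_site & res$kinase == k][1],
               match(match(k, kin), ord))
})

test_that("top-k accuracy counts ranks at or below the cutoff", {
  r <- structure(data.frame(site_id = letters[1:4], kinase = "K",
                            rank = c(1L, 3L, 6L, 2L),
                            n_kinases = rep(6L, 4)),
                 class = c("loocv_result", "data.frame"))
  expect_equal(topk_accuracy(r, 5), 0.75)
  expect_equal(topk_accuracy(r, 1), 0.25)
  expect_equal(topk_accuracy(r, 6), 1)       # saturation at k >= max total
  ks <- 1:6
  expect_true(all(diff(sapply(ks, topk_accuracy, result = r)) >= 0))
  expect_error(topk_accuracy(r[0, ], 1), "empty")
})

test_that("LOOCV on pure-noise profiles matches the random baseline", {
  # i.i.d. noise: the hidden edge must not leak into its own evaluation
  accs <- sapply(1:3, function(s) {
    d <- generate_synthetic(synthetic_config(
      n_states = 10, n_kinases = 5, substrates_per_kinase = 8,
      n_background = 10, rho = 0, seed = 100 + s))
    res <- loocv(d$matrix, d$ksa)
    c(acc = topk_accuracy(res, 1), n = nrow(res))
  })
  pooled_acc <- sum(accs["acc", ] * accs["n", ]) / sum(accs["n", ])
  p0 <- 1 / 5
  se <- sqrt(p0 * (1 - p0) / sum(accs["n", ]))
  expect_lt(abs(pooled_acc - p0), 3 * se)
})

test_that("reproducibility rates compare top-ranked kinases across datasets", {
  inst <- make_instance(n_sites = 8, m = 10, n_kinases = 3,
                        subs_per_kinase = 3, seed = 94)
  tails <- fit_tail_model(network_values(inst$network),
                          collect_shared_kinase_values(inst$network,
                                                       inst$ksa))
  pred <- rank_all(inst$network, inst$ksa, tails)
  r <- cross_dataset_reproducibility(pred, pred)
  expect_equal(r$top1_match_rate, 1)
  expect_equal(r$top1_in_top5_rate, 1)
  expect_equal(r$n_common, length(unique(pred$site_id)))

  # disjoint site sets: error
  pred_b <- pred
  pred_b$site_id <- paste0("X", pred_b$site_id)
  expect_error(cross_dataset_reproducibility(pred, pred_b), "no site")

  # permuted kinase labels: top-1 agreement near the 1/|kinases| baseline
  set.seed(95)
  kin <- unique(pred$kinase)
  rates <- replicate(60, {
    relab <- setNames(sample(kin), kin)
    pb <- pred
    pb$kinase <- unname(relab[pb$kinase])
    cross_dataset_reproducibility(pred, pb)$top1_match_rate
  })
  expect_equal(mean(rates), 1 / length(kin), tolerance = 0.15)
})

test_that("consensus categories follow the any-match rule", {
  pred1 <- structure(data.frame(
    site_id = c("A_S1", "B_S2", "C_S3"), rank = 1L,
    kinase = c("K1", "K2", "K3"), score = 1),
    class = c("prediction_table", "data.frame"))
  ksa <- suppressMessages(ksa_annotation(
    kinase = c("K1", "K1", "K2", "K2"),
    site_id = c("A_S1", "X_S9", "B_S2", "Y_S8"), min_substrates = 1))

  # one dataset: predicted kinase annotated -> cat1; C_S3 unannotated -> cat3
  rep1 <- consensus(list(pred1), ksa)
  expect_equal(rep1$cat1, 2L)
  expect_equal(rep1$cat3, 1L)
  expect_equal(rep1$precision, 1)

  # any-match: site annotated {K1, K2}, predicted K2 -> still cat1
  ksa2 <- suppressMessages(ksa_annotation(
    kinase = c("K1", "K2", "K1", "K2"),
    site_id = c("B_S2", "B_S2", "Z_S1", "W_S2"), min_substrates = 1))
  pred2 <- pred1[pred1$site_id == "B_S2", ]
  rep2 <- consensus(list(pred2), ksa2)
  expect_equal(rep2$cat1, 1L)

  # two agreeing datasets stratify at level 2; disagreement stays at 1
  predX <- pred1
  predX$kinase <- c("K1", "K9", "K3")
  rep3 <- consensus(list(pred1, predX), ksa)
  lev2 <- rep3[rep3$n_agreeing == 2, ]
  expect_equal(lev2$cat1, 1L)   # A_S1 agreed and annotated-correct
  expect_equal(lev2$cat3, 1L)   # C_S3 agreed, unannotated
  lev1 <- rep3[rep3$n_agreeing == 1, ]
  expect_equal(lev1$cat1 + lev1$cat2, 1L)  # B_S2 disagreed
})

test_that("consensus precision grows with supporting datasets on synthetic data", {
  # three replicate "datasets": disjoint 10-state windows of one generated
  # study, sharing sites and truth but with independent noise realisations
  d <- generate_synthetic(synthetic_config(
    n_states = 30, n_kinases = 5, substrates_per_kinase = 8,
    n_background = 30, rho = 0.5, seed = 201))
  preds <- lapply(1:3, function(s) {
    cols <- ((s - 1) * 10 + 1):(s * 10)
    sub <- suppressWarnings(
      phospho_matrix(unclass(d$matrix)[, cols, drop = FALSE]))
    net <- build_cophos_network(sub)
    tails <- fit_tail_model(network_values(net),
                            collect_shared_kinase_values(net, d$ksa))
    rank_all(net, d$ksa, tails)
  })
  rep <- consensus(preds, d$ksa)
  expect_s3_class(rep, "consensus_report")
  ann <- rep[!is.na(rep$precision), ]
  if (nrow(ann) >= 2) {
    expect_gte(ann$precision[nrow(ann)], ann$precision[1])
  }
})
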