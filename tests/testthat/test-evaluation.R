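perturbed_copy <- function(fps, sd = 0.2, seed = 1) {
  set.seed(seed)
  vals <- as.matrix(fps[fp_cols()])
  vals <- pmin(pmax(vals + rnorm(length(vals), 0, sd), -1), 1)
  out <- fps
  out[fp_cols()] <- tibble::as_tibble(vals)
  out
}

test_that("all metrics return their analytic values on identity fixtures", {
  fps <- random_fps(12, seed = 101)
  expect_equal(rsm_r2(fps, fps), 1.0)
  rd <- rd_r2(fps, fps)
  expect_equal(rd$per_attribute$r2, rep(1, 16))
  expect_equal(rd$mean, 1.0)
  expect_equal(mae(fps, fps), 0)
  expect_equal(topk_overlap(fps, fps, k = 5)$overlap, rep(5L, 16))
  expect_equal(rank_rci(fps, fps, top_n = 10)$rci, rep(1, 16))
})

test_that("reversal fixtures give the opposite extremes", {
  fps <- random_fps(12, seed = 102)
  neg <- fps
  neg[fp_cols()] <- tibble::as_tibble(-as.matrix(fps[fp_cols()]))
  expect_equal(topk_overlap(neg, fps, k = 5)$overlap, rep(0L, 16))
  expect_equal(rank_rci(neg, fps, top_n = 12)$rci, rep(-1, 16))
})

test_that("rating-level variance explained is correlation-based", {
  fps <- random_fps(15, seed = 103)
  # affine transforms leave the per-attribute r2 at 1
  aff <- fps
  aff$scale <- "zscore"
  aff[fp_cols()] <- tibble::as_tibble(2 * as.matrix(fps[fp_cols()]) + 3)
  rd <- rd_r2(aff, fps)
  expect_equal(rd$per_attribute$r2, rep(1, 16))

  # noisy predictions match an independent correlation oracle
  noisy <- perturbed_copy(fps, seed = 104)
  rd2 <- rd_r2(noisy, fps)
  P <- as.matrix(noisy[fp_cols()])
  H <- as.matrix(fps[fp_cols()])
  for (a in 1:16) {
    expect_equal(rd2$per_attribute$r2[a], oracle_pearson(P[, a], H[, a])^2)
  }

  # constant attribute: r2 0 with warning
  flat <- fps
  flat$attr03 <- 0.5
  expect_warning(rdf <- rd_r2(flat, fps), "constant")
  expect_equal(rdf$per_attribute$r2[3], 0)
})

test_that("similarity-matrix variance explained matches triangle oracles", {
  fps <- random_fps(8, seed = 105)
  # a fixed attribute permutation applied to every fingerprint
  set.seed(106)
  perm <- sample(16)
  permuted <- fps
  permuted[fp_cols()] <- fps[fp_cols()[perm]]
  got <- rsm_r2(permuted, fps)
  # oracle: recompute both triangles with the formula oracle
  vp <- as.matrix(permuted[fp_cols()])
  vh <- as.matrix(fps[fp_cols()])
  tp <- c(); th <- c()
  for (i in 1:7) for (j in (i + 1):8) {
    tp <- c(tp, oracle_similarity(vp[i, ], vp[j, ], 0.5))
    th <- c(th, oracle_similarity(vh[i, ], vh[j, ], 0.5))
  }
  expect_equal(got, oracle_pearson(tp, th)^2)

  # 3-material toy, hand-computable triangle of 3 pairs
  toy_h <- fingerprint_set(c("a", "b", "c"),
                           rbind(seq(-1, 1, length.out = 16),
                                 seq(1, -1, length.out = 16),
                                 rep(c(-1, 1), 8)), scale = "unit")
  toy_p <- perturbed_copy(toy_h, sd = 0.3, seed = 107)
  tp3 <- c(oracle_similarity(unlist(toy_p[1, fp_cols()]),
                             unlist(toy_p[2, fp_cols()]), 0.5),
           oracle_similarity(unlist(toy_p[1, fp_cols()]),
                             unlist(toy_p[3, fp_cols()]), 0.5),
           oracle_similarity(unlist(toy_p[2, fp_cols()]),
                             unlist(toy_p[3, fp_cols()]), 0.5))
  th3 <- c(oracle_similarity(unlist(toy_h[1, fp_cols()]),
                             unlist(toy_h[2, fp_cols()]), 0.5),
           oracle_similarity(unlist(toy_h[1, fp_cols()]),
                             unlist(toy_h[3, fp_cols()]), 0.5),
           oracle_similarity(unlist(toy_h[2, fp_cols()]),
                             unlist(toy_h[3, fp_cols()]), 0.5))
  expect_equal(rsm_r2(toy_p, toy_h), oracle_pearson(tp3, th3)^2)
  expect_error(rsm_r2(toy_h[1:2, ], toy_h[1:2, ]), "at least 3")
})

test_that("mean absolute error matches a flat loop oracle", {
  fps <- random_fps(9, seed = 108)
  shifted <- fps
  shifted$scale <- "zscore"
  fps2 <- fps
  fps2$scale <- "zscore"
  shifted[fp_cols()] <- tibble::as_tibble(as.matrix(fps[fp_cols()]) + 0.1)
  expect_equal(mae(shifted, fps2), 0.1)

  noisy <- perturbed_copy(fps, seed = 109)
  acc <- 0
  for (i in 1:9) for (a in fp_cols()) {
    acc <- acc + abs(noisy[[a]][i] - fps[[a]][i])
  }
  expect_equal(mae(noisy, fps), acc / (9 * 16))
  bad <- fps
  bad$scale <- "zscore"
  expect_error(mae(bad, fps), "scale")
})

test_that("top-k overlap matches a set-intersection oracle and is symmetric", {
  fps <- random_fps(20, seed = 110)
  noisy <- perturbed_copy(fps, sd = 0.4, seed = 111)
  ov <- topk_overlap(noisy, fps, k = 5)
  H <- as.matrix(fps[fp_cols()])
  P <- as.matrix(noisy[fp_cols()])
  for (a in 1:16) {
    top_h <- fps$material_id[order(-H[, a], fps$material_id)][1:5]
    top_p <- noisy$material_id[order(-P[, a], noisy$material_id)][1:5]
    expect_equal(ov$overlap[a], length(intersect(top_h, top_p)))
  }
  expect_equal(topk_overlap(noisy, fps, k = 5)$overlap,
               topk_overlap(fps, noisy, k = 5)$overlap)
  expect_error(topk_overlap(fps, fps, k = 21), "exceeds")
})

test_that("the rank correlation index reranks the human top subset", {
  fps <- random_fps(30, seed = 112)
  noisy <- perturbed_copy(fps, sd = 0.3, seed = 113)
  rci <- rank_rci(noisy, fps, top_n = 10)
  H <- as.matrix(fps[fp_cols()])
  P <- as.matrix(noisy[fp_cols()])
  for (a in 1:16) {
    sel <- order(-H[, a], fps$material_id)[1:10]
    expect_equal(rci$rci[a], oracle_spearman(H[sel, a], P[sel, a]))
  }
  # all-tied predictions: 0 with warning
  flat <- fps
  flat$attr01 <- 0.2
  expect_warning(r <- rank_rci(flat, fps, top_n = 10), "tied")
  expect_equal(r$rci[1], 0)
})

test_that("AIC follows the Gaussian-likelihood formula", {
  set.seed(114)
  res <- rnorm(64)
  out <- aic_compare(list(a = list(n_params = 10, residuals = res),
                          b = list(n_params = 20, residuals = res)))
  expect_equal(out$aic[out$model == "b"] - out$aic[out$model == "a"], 20)
  # formula oracle
  expect_equal(out$aic[out$model == "a"],
               2 * 10 + 64 * log(sum(res^2) / 64))
  # scaling all residuals by c adds n * log(c^2)
  out2 <- aic_compare(list(a = list(n_params = 10, residuals = 3 * res)))
  expect_equal(out2$aic - out$aic[out$model == "a"], 64 * log(9))
  expect_error(aic_compare(list(a = list(n_params = 1, residuals = rep(0, 4)))),
               "degenerate")
})

test_that("metrics are invariant to material ordering", {
  fps <- random_fps(14, seed = 115)
  noisy <- perturbed_copy(fps, seed = 116)
  shuffled <- noisy[sample(14), ]
  expect_equal(rsm_r2(noisy, fps), rsm_r2(shuffled, fps))
  expect_equal(rd_r2(noisy, fps)$mean, rd_r2(shuffled, fps)$mean)
  expect_equal(mae(noisy, fps), mae(shuffled, fps))
  expect_equal(topk_overlap(noisy, fps)$overlap,
               topk_overlap(shuffled, fps)$overlap)
  expect_equal(rank_rci(noisy, fps, 10)$rci, rank_rci(shuffled, fps, 10)$rci)
})

test_that("the bundled evaluation report carries consistent summaries", {
  fps <- random_fps(10, seed = 117)
  noisy <- perturbed_copy(fps, seed = 118)
  rep <- evaluate_predictions(noisy, fps, top_n = 10)
  expect_s3_class(rep, "fp_eval")
  expect_equal(rep$rsm_r2, rsm_r2(noisy, fps))
  expect_equal(rep$mae, mae(noisy, fps))
  gl <- generics::glance(rep)
  expect_true(all(is.finite(unlist(gl[1:5]))))
  td <- generics::tidy(rep)
  expect_equal(nrow(td), 16 * 3)
})
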