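test_that("similarity metric matches its defining formula on seeded pairs", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(16, -1, 1)
    b <- runif(16, -1, 1)
    alpha <- runif(1)
    expect_lt(abs(fingerprint_similarity(a, b, alpha) -
                    oracle_similarity(a, b, alpha)), 1e-12)
    expect_equal(fingerprint_similarity(a, b, alpha),
                 fingerprint_similarity(b, a, alpha))
  }
})

test_that("identity and anti-correlated fixtures give analytic values", {
  v <- seq(-1, 1, length.out = 16)
  expect_equal(fingerprint_similarity(v, v, 0.5), 1.0)
  alt <- rep(c(1, -1), 8)
  expect_equal(fingerprint_similarity(alt, -alt, 0.5), -0.5)
})

test_that("alpha endpoints isolate the L1 and correlation terms", {
  set.seed(12)
  a <- runif(16, -1, 1)
  # alpha = 1: pure correlation, against a from-scratch correlation oracle
  for (i in 1:10) {
    b <- runif(16, -1, 1)
    expect_equal(fingerprint_similarity(a, b, 1), oracle_pearson(a, b))
  }
  # alpha = 0: strictly decreasing in the L1 distance
  deltas <- seq(0.05, 1, length.out = 8)
  sims <- vapply(deltas, function(d) {
    b <- pmin(pmax(a + d * rep(c(1, -1), 8), -1), 1)
    fingerprint_similarity(a, b, 0)
  }, numeric(1))
  l1 <- vapply(deltas, function(d) {
    b <- pmin(pmax(a + d * rep(c(1, -1), 8), -1), 1)
    sum(abs(a - b))
  }, numeric(1))
  expect_true(all(diff(l1) > 0))
  expect_true(all(diff(sims) < 0))
})

test_that("zero-variance fingerprints contribute no correlation, with warning", {
  flat <- rep(0.2, 16)
  v <- seq(-1, 1, length.out = 16)
  expect_warning(s <- fingerprint_similarity(flat, v, 0.5), "zero-variance")
  expect_equal(s, 0.5 * (1 - sum(abs(flat - v)) / 32))
})

test_that("similarity matrices are symmetric with unit diagonal", {
  fps <- random_fps(5, seed = 21)
  m <- similarity_matrix(fps, alpha = 0.5)
  expect_equal(dim(m), c(5, 5))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, 5))
  vals <- as.matrix(fps[fp_cols()])
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(m[i, j], oracle_similarity(vals[i, ], vals[j, ], 0.5))
  }
  # three identical members -> all entries 1
  same <- fingerprint_set(c("a", "b", "c"),
                          matrix(rep(seq(-1, 1, length.out = 16), 3),
                                 3, 16, byrow = TRUE), scale = "unit")
  expect_equal(unname(unclass(similarity_matrix(same, 0.5))),
               matrix(1, 3, 3))
  # singleton
  one <- similarity_matrix(fps[1, ], 0.5)
  expect_equal(unname(unclass(one)), matrix(1, 1, 1))
})

test_that("retrieval ranks by similarity with deterministic tie-breaks", {
  fps <- random_fps(10, seed = 31)
  q <- fps[1, ]
  hits <- retrieve_top_k(q, fps, k = 5, alpha = 0.5)
  expect_equal(nrow(hits), 5)
  # matches sorting the oracle similarity column
  qv <- unlist(q[fp_cols()])
  others <- fps[-1, ]
  sims <- vapply(seq_len(9), function(i) {
    oracle_similarity(qv, unlist(others[i, fp_cols()]), 0.5)
  }, numeric(1))
  ord <- order(-sims, others$material_id)
  expect_equal(hits$material_id, others$material_id[ord][1:5])
  expect_equal(hits$similarity, sims[ord][1:5])

  # query identical to one member ranks it first at similarity 1
  hits2 <- retrieve_top_k(unlist(fps[3, fp_cols()]), fps, k = 3)
  expect_equal(hits2$material_id[1], "m003")
  expect_equal(hits2$similarity[1], 1.0)

  # k larger than the corpus returns all candidates; k = N - 1 is a
  # permutation of the other ids
  all_hits <- retrieve_top_k(q, fps, k = 50)
  expect_equal(nrow(all_hits), 9)
  expect_setequal(all_hits$material_id, others$material_id)

  # exact ties break by ascending material id
  tied <- fingerprint_set(c("z", "a"),
                          matrix(rep(seq(-1, 1, length.out = 16), 2),
                                 2, 16, byrow = TRUE), scale = "unit")
  ht <- retrieve_top_k(seq(-1, 1, length.out = 16), tied, k = 2)
  expect_equal(ht$material_id, c("a", "z"))

  expect_error(retrieve_top_k(q, fps, k = 0), ">= 1")
})

test_that("typicality averages the top decile of neighbour similarities", {
  # identical corpus: typicality 1 everywhere
  same <- fingerprint_set(sprintf("s%d", 1:5),
                          matrix(rep(seq(-1, 1, length.out = 16), 5),
                                 5, 16, byrow = TRUE), scale = "unit")
  expect_equal(typicality("s2", same), 1.0)

  # N = 11: ceil(0.1 * 10) = 1 neighbour, i.e. the maximum similarity
  fps11 <- random_fps(11, seed = 41)
  sims <- vapply(2:11, function(i) {
    oracle_similarity(unlist(fps11[1, fp_cols()]),
                      unlist(fps11[i, fp_cols()]), 0.5)
  }, numeric(1))
  expect_equal(typicality("m001", fps11), max(sims))

  # N = 21: mean of the top 2
  fps21 <- random_fps(21, seed = 42)
  sims21 <- vapply(2:21, function(i) {
    oracle_similarity(unlist(fps21[1, fp_cols()]),
                      unlist(fps21[i, fp_cols()]), 0.5)
  }, numeric(1))
  expect_equal(typicality("m001", fps21),
               mean(sort(sims21, decreasing = TRUE)[1:2]))

  # invariant to member order
  shuf <- fps21[sample(21), ]
  expect_equal(typicality("m001", shuf), typicality("m001", fps21))

  expect_error(typicality("m001", fps21[1, ]), "at least 2")
})

test_that("category profiles are per-attribute medians with standard errors", {
  fps <- random_fps(5, seed = 51, categories = c("wood", "wood", "wood",
                                                 "wood", "wood"))
  prof <- category_profile(fps, "wood")
  vals <- as.matrix(fps[fp_cols()])
  expect_equal(prof$median, unname(apply(vals, 2, median)))
  expect_equal(prof$stderr, unname(apply(vals, 2, sd) / sqrt(5)))

  single <- category_profile(fps[1, ], fps$category[1])
  expect_equal(single$median, unname(unlist(fps[1, fp_cols()])))
  expect_equal(single$stderr, rep(0, 16))

  two <- random_fps(2, seed = 52, categories = "fabric")
  p2 <- category_profile(two, "fabric")
  v2 <- as.matrix(two[fp_cols()])
  expect_equal(p2$median, unname((v2[1, ] + v2[2, ]) / 2))

  expect_error(category_profile(fps, "no-such"), "no materials")
})

test_that("unit rescaling maps per-attribute ranges onto [-1, 1]", {
  vals <- matrix(rnorm(8 * 16), 8, 16)
  vals[, 3] <- c(-2, 0, 2, 1, -1, 0.5, -0.5, 0)
  z <- fingerprint_set(sprintf("m%d", 1:8), vals, scale = "zscore")
  u <- rescale_to_unit(z)
  expect_equal(unique(u$scale), "unit")
  um <- as.matrix(u[fp_cols()])
  expect_equal(unname(apply(um, 2, min)), rep(-1, 16))
  expect_equal(unname(apply(um, 2, max)), rep(1, 16))
  expect_equal(um[1:3, 3], c(-1, 0, 1), ignore_attr = TRUE)

  # a set already spanning [-1, 1] per attribute is unchanged
  z2 <- u
  z2$scale <- "zscore"
  u2 <- rescale_to_unit(z2)
  expect_equal(as.matrix(u2[fp_cols()]), um)

  # constant attribute errors, naming the attribute
  cvals <- vals
  cvals[, 7] <- 0.3
  zc <- fingerprint_set(sprintf("m%d", 1:8), cvals, scale = "zscore")
  expect_error(rescale_to_unit(zc), "shininess")

  # stored ranges map new fingerprints consistently
  ranges <- attr(u, "unit_ranges")
  again <- apply_unit_scale(z, ranges)
  expect_equal(as.matrix(again[fp_cols()]), um)
})
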