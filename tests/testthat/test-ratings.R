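test_that("participant z-scoring standardises each stratum", {
  t1 <- ratings_from_matrix(list(p1 = c(a = 0, b = 50, c = 100)))
  z1 <- zscore_participant(t1)
  expect_equal(sort(z1$response), c(-1, 0, 1))

  # single participant, several attributes: every stratum mean ~0, sd ~1
  set.seed(61)
  tbl <- tidyr::expand_grid(participant_id = "p1",
                            material_id = sprintf("m%d", 1:6),
                            attribute_id = 1:4)
  tbl$response <- runif(nrow(tbl), 0, 100)
  z <- zscore_participant(tbl)
  by_attr <- split(z$response, z$attribute_id)
  for (v in by_attr) {
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }

  # matches an independent two-pass mean/sd oracle on 3 participants
  set.seed(62)
  tbl3 <- tidyr::expand_grid(participant_id = c("p1", "p2", "p3"),
                             material_id = sprintf("m%d", 1:5),
                             attribute_id = 1:2)
  tbl3$response <- runif(nrow(tbl3), 0, 100)
  z3 <- zscore_participant(tbl3)
  for (p in c("p1", "p2", "p3")) for (a in 1:2) {
    raw <- tbl3$response[tbl3$participant_id == p & tbl3$attribute_id == a]
    mu <- sum(raw) / length(raw)
    sdv <- sqrt(sum((raw - mu)^2) / (length(raw) - 1))
    got <- z3$response[z3$participant_id == p & z3$attribute_id == a]
    expect_equal(got, (raw - mu) / sdv)
  }

  # constant stratum: responses 0 and flagged
  tc <- ratings_from_matrix(list(p1 = c(a = 40, b = 40, c = 40)))
  zc <- zscore_participant(tc)
  expect_equal(zc$response, c(0, 0, 0))
  flat <- attr(zc, "zero_variance_strata")
  expect_equal(nrow(flat), 1)
  expect_equal(flat$participant_id, "p1")
})

test_that("discordant raters are excluded by negative consensus correlation", {
  # one participant is the exact negation of two identical others
  base <- c(a = 20, b = 50, c = 80)
  tbl <- ratings_from_matrix(list(p1 = base, p2 = base,
                                  p3 = c(a = 80, b = 50, c = 20)))
  z <- zscore_participant(tbl)
  excl <- exclude_discordant(z)
  expect_equal(excl$participant_id, "p3")
  expect_equal(excl$reason, "negative correlation")

  # all identical: nobody excluded
  same <- ratings_from_matrix(list(p1 = base, p2 = base, p3 = base))
  expect_equal(nrow(exclude_discordant(zscore_participant(same))), 0)

  # a single participant is never excluded
  solo <- ratings_from_matrix(list(p1 = base))
  expect_equal(nrow(exclude_discordant(zscore_participant(solo))), 0)

  # 5 participants, one shuffled: exclusion set equals a brute-force
  # correlation loop over the all-participant consensus
  set.seed(63)
  truth <- runif(12, 0, 100)
  names(truth) <- sprintf("m%02d", 1:12)
  mats <- lapply(1:4, function(i) pmin(pmax(truth + rnorm(12, 0, 6), 0), 100))
  names(mats) <- sprintf("p%d", 1:4)
  mats$p5 <- sample(truth)
  tbl5 <- ratings_from_matrix(lapply(mats, function(v) {
    names(v) <- names(truth); v
  }))
  z5 <- zscore_participant(tbl5)
  excl5 <- exclude_discordant(z5)
  # brute force
  wide <- tidyr::pivot_wider(z5, names_from = "participant_id",
                             values_from = "response")
  wm <- as.matrix(wide[, sprintf("p%d", 1:5)])
  consensus <- rowMeans(wm)
  neg <- sprintf("p%d", 1:5)[vapply(1:5, function(j) {
    oracle_pearson(wm[, j], consensus) < 0
  }, logical(1))]
  expect_setequal(excl5$participant_id[excl5$reason == "negative correlation"],
                  neg)
})

test_that("aggregation averages surviving z-scores per material", {
  base <- c(a = 20, b = 50, c = 80)
  solo <- ratings_from_matrix(list(p1 = base))
  agg <- aggregate_ratings(solo)
  z <- zscore_participant(solo)
  expect_equal(agg$fingerprints$attr01,
               z$response[match(agg$fingerprints$material_id, z$material_id)])
  expect_equal(unique(agg$fingerprints$scale), "zscore")

  # two identical participants equal one
  two <- ratings_from_matrix(list(p1 = base, p2 = base))
  agg2 <- aggregate_ratings(two)
  expect_equal(agg2$fingerprints$attr01, agg$fingerprints$attr01)

  # row order and participant relabelling do not change the result
  set.seed(64)
  tbl <- tidyr::expand_grid(participant_id = c("p1", "p2", "p3"),
                            material_id = sprintf("m%d", 1:6),
                            attribute_id = 1:3)
  tbl$response <- runif(nrow(tbl), 0, 100)
  a1 <- aggregate_ratings(tbl)
  shuffled <- tbl[sample(nrow(tbl)), ]
  a2 <- aggregate_ratings(shuffled)
  expect_equal(a1$fingerprints, a2$fingerprints)
  relabelled <- tbl
  relabelled$participant_id <- c(p1 = "zz", p2 = "aa",
                                 p3 = "mm")[relabelled$participant_id]
  a3 <- aggregate_ratings(relabelled)
  expect_equal(a1$fingerprints, a3$fingerprints)

  # exclusion is idempotent on concordant data: re-running the filter on the
  # surviving table excludes nobody
  z4 <- zscore_participant(tbl)
  excl <- exclude_discordant(z4)
  kept <- dplyr::anti_join(z4, excl, by = c("participant_id", "attribute_id"))
  expect_equal(nrow(exclude_discordant(kept)), 0)
})

test_that("a cell with no surviving ratings aborts with its name", {
  # two participants who exactly negate each other on one attribute: both
  # correlate negatively with the (flat) consensus and are excluded
  tbl <- ratings_from_matrix(list(p1 = c(a = 20, b = 50, c = 80),
                                  p2 = c(a = 80, b = 50, c = 20)))
  expect_error(aggregate_ratings(tbl), "no surviving ratings")
})

test_that("attribute importance combines mention probability and mean rank", {
  naming <- tibble::tibble(
    participant_id = c("p1", "p1", "p1", "p2", "p2", "p2"),
    trial = c(1, 1, 2, 1, 1, 1),
    term = c("shiny", "rough", "shiny", "shiny", "colourful", "rough"),
    rank = c(1, 2, 1, 2, 1, 3)
  )
  clusters <- tibble::tibble(term = c("shiny", "rough", "colourful"),
                             attribute_id = c(7L, 2L, 1L))
  imp <- attribute_importance(naming, clusters)
  # hand enumeration: responses = distinct (participant, trial) pairs = 3
  # shiny: mentioned in all 3 -> ap = 1, ranks 1,1,2 -> ao = 4/3
  # rough: mentioned in 2 -> ap = 2/3, ranks 2,3 -> ao = 2.5 (max ao)
  # colourful: 1 of 3 -> ap = 1/3, rank 1 -> ao = 1
  expect_equal(imp$ap[7], 1)
  expect_equal(imp$ao[7], 4 / 3)
  expect_equal(imp$ap[2], 2 / 3)
  expect_equal(imp$ao[2], 2.5)
  expect_equal(imp$importance[7], 1 * (2.5 - 4 / 3))
  expect_equal(imp$importance[1], (1 / 3) * (2.5 - 1))
  # the attribute with the largest mean rank has importance 0
  expect_equal(imp$importance[2], 0)
  # never-mentioned attributes have ap = 0 and importance 0
  expect_equal(imp$ap[10], 0)
  expect_equal(imp$importance[10], 0)
  # unmapped terms abort
  expect_error(attribute_importance(naming, clusters[1:2, ]), "without")
})

test_that("Fleiss kappa equals 1 under perfect agreement and matches the
           published formula on toys", {
  perfect <- tidyr::expand_grid(response_id = sprintf("r%d", 1:10),
                                rater_id = sprintf("j%d", 1:6))
  perfect$attribute_id <- rep(c(1L, 5L), each = 30)
  expect_equal(fleiss_kappa(perfect), 1.0)

  # 2 responses x 2 raters, assignments {(A,A),(A,B)}: hand-computed
  toy <- tibble::tibble(
    response_id = c("r1", "r1", "r2", "r2"),
    rater_id = c("j1", "j2", "j1", "j2"),
    attribute_id = c(1L, 1L, 1L, 2L)
  )
  # P1 = 1, P2 = 0, Pbar = 1/2; p = (3/4, 1/4), Pe = 10/16 = 5/8
  # kappa = (1/2 - 5/8) / (1 - 5/8) = -1/3
  expect_equal(fleiss_kappa(toy), -1 / 3)
  expect_equal(fleiss_kappa(toy), oracle_fleiss(toy))

  # seeded random assignments match the loop oracle
  set.seed(65)
  rand <- tidyr::expand_grid(response_id = sprintf("r%02d", 1:20),
                             rater_id = sprintf("j%d", 1:4))
  rand$attribute_id <- sample(1:16, nrow(rand), replace = TRUE)
  expect_equal(fleiss_kappa(rand), oracle_fleiss(rand))

  # unequal rater counts are rejected
  uneven <- dplyr::bind_rows(toy, tibble::tibble(
    response_id = "r1", rater_id = "j3", attribute_id = 3L))
  expect_error(fleiss_kappa(uneven), "same number of raters")
})

test_that("unanimity counts tally modal agreement levels", {
  perfect <- tidyr::expand_grid(response_id = sprintf("r%d", 1:7),
                                rater_id = sprintf("j%d", 1:6))
  perfect$attribute_id <- 3L
  u <- unanimity_counts(perfect)
  expect_equal(u$unanimous, 7)
  expect_equal(u$at_least_3, 7)
  expect_equal(u$at_least_2, 7)

  # six raters, all distinct categories: modal count 1, in no bucket
  distinct6 <- tibble::tibble(response_id = "r1",
                              rater_id = sprintf("j%d", 1:6),
                              attribute_id = 1:6)
  u2 <- unanimity_counts(distinct6)
  expect_equal(c(u2$unanimous, u2$at_least_3, u2$at_least_2), c(0, 0, 0))

  # seeded assignments match a brute-force tally
  set.seed(66)
  rand <- tidyr::expand_grid(response_id = sprintf("r%02d", 1:30),
                             rater_id = sprintf("j%d", 1:6))
  rand$attribute_id <- sample(1:4, nrow(rand), replace = TRUE)
  u3 <- unanimity_counts(rand)
  modal <- vapply(split(rand$attribute_id, rand$response_id),
                  function(a) max(table(a)), numeric(1))
  expect_equal(u3$unanimous, sum(modal == 6))
  expect_equal(u3$at_least_3, sum(modal >= 3))
  expect_equal(u3$at_least_2, sum(modal >= 2))
})

test_that("aggregation reports tidy and glance summaries", {
  set.seed(67)
  tbl <- tidyr::expand_grid(participant_id = c("p1", "p2"),
                            material_id = sprintf("m%d", 1:4),
                            attribute_id = 1:2)
  tbl$response <- runif(nrow(tbl), 0, 100)
  agg <- aggregate_ratings(tbl)
  td <- generics::tidy(agg)
  expect_equal(nrow(td), 4 * 16)
  gl <- generics::glance(agg)
  expect_equal(gl$n_materials, 4)
  expect_equal(gl$n_ratings_used, agg$n_ratings_used)
})
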