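# Mutual information, F statistic, redundancy, the five mRMR criteria and
# the frequency consensus.

test_that("mutual information matches closed forms", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), log(2),
               tolerance = 1e-12)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0,
               tolerance = 1e-12)
  expect_equal(mutual_information(rep(1, 10), rep(0:1, 5)), 0)
  expect_error(mutual_information(1:3, 1:3), "at least 4")
})

test_that("F statistic matches hand ANOVA and guards degeneracy", {
  expect_equal(f_statistic(c(1, 2, 3, 4, 5, 6), rep(0:1, each = 3)), 13.5,
               tolerance = 1e-12)
  expect_equal(f_statistic(c(1, 2, 1, 2), c(0, 0, 1, 1)), 0)
  expect_warning(fcap <- f_statistic(c(0, 0, 1, 1), c(0, 0, 1, 1)), "capped")
  expect_true(is.finite(fcap) && fcap > 1e6)
  expect_error(f_statistic(1:3, c(0, 0, 1)), "2 members")
})

test_that("pearson redundancy is absolute and guards constants", {
  expect_equal(pearson_redundancy(1:3, c(2, 4, 6)), 1)
  expect_equal(pearson_redundancy(1:3, c(6, 4, 2)), 1)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  expect_lt(pearson_redundancy(x, y), 1e-12)
  expect_warning(r0 <- pearson_redundancy(rep(1, 4), 1:4), "constant")
  expect_equal(r0, 0)
})

test_that("mRMR difference and quotient forms follow the printed arithmetic", {
  # relevance 0.5, redundancies {0.2, 0.2}
  expect_equal(0.5 - mean(c(0.2, 0.2)), 0.3)
  expect_equal(0.5 / mean(c(0.2, 0.2)), 2.5)

  # wiring check on real data: the step-2 score equals the formula computed
  # from the package's own relevance/redundancy primitives
  d <- planted_mrmr_design(5, n = 200)
  r <- mrmr_rank(d$X, d$y, "MID", depth = 2)
  rel <- vapply(d$X, mutual_information, 0, y = d$y)
  first <- names(which.max(rel))
  expect_identical(r$features[1], first)
  expect_equal(r$scores[1], unname(rel[first]), tolerance = 1e-9)
  penal <- vapply(setdiff(names(d$X), first), function(f)
    rel[f] - mutual_information(d$X[[f]],
                                cut(d$X[[first]],
                                    unique(quantile(d$X[[first]],
                                                    seq(0, 1, length.out = 9))),
                                    include.lowest = TRUE)), 0)
  expect_equal(r$scores[2], max(penal), tolerance = 1e-9)
  expect_identical(r$features[2], names(which.max(penal)))
})

test_that("greedy ranking is deterministic and order-invariant", {
  d <- planted_mrmr_design(9, n = 200)
  r1 <- mrmr_rank(d$X, d$y, "FCQ", depth = 6)
  r2 <- mrmr_rank(d$X[, rev(names(d$X))], d$y, "FCQ", depth = 6)
  expect_identical(r1$features, r2$features)
  expect_error(mrmr_rank(d$X, d$y, "MID", depth = 0), "depth")
})

test_that("paired criteria agree on the first selected feature", {
  d <- planted_mrmr_design(3, n = 300)
  expect_identical(mrmr_rank(d$X, d$y, "MID", depth = 1)$features,
                   mrmr_rank(d$X, d$y, "MIQ", depth = 1)$features)
  expect_identical(mrmr_rank(d$X, d$y, "FCD", depth = 1)$features,
                   mrmr_rank(d$X, d$y, "FCQ", depth = 1)$features)
})

test_that("greedy MID triples score near the exhaustive optimum", {
  # set-level MID objective: total relevance minus mean pairwise redundancy
  set_score <- function(X, y, trip) {
    rel <- sum(vapply(trip, function(f) mutual_information(X[[f]], y), 0))
    prs <- utils::combn(trip, 2)
    red <- mean(vapply(seq_len(ncol(prs)), function(i)
      mutual_information(X[[prs[1, i]]],
                         cut(X[[prs[2, i]]],
                             unique(quantile(X[[prs[2, i]]],
                                             seq(0, 1, length.out = 9))),
                             include.lowest = TRUE)), 0))
    rel - red
  }
  for (seed in c(2, 4)) {
    d <- planted_mrmr_design(seed, n = 300)
    X <- d$X[, c("inf1", "inf2", "inf3", "red1",
                 sprintf("noise%02d", 1:8))]
    greedy <- mrmr_rank(X, d$y, "MID", depth = 3)$features
    all_trips <- utils::combn(names(X), 3)
    scores <- vapply(seq_len(ncol(all_trips)), function(i)
      set_score(X, d$y, all_trips[, i]), 0)
    g_score <- set_score(X, d$y, greedy)
    expect_gte(g_score, unname(quantile(scores, 0.9)))
  }
})

test_that("rf relevance finds the informative feature deterministically", {
  hits <- 0
  for (seed in 1:25) {
    sim <- withr::with_seed(seed, {
      n <- 500
      y <- rep(0:1, each = n / 2)
      X <- matrix(rnorm(n * 11), n, 11,
                  dimnames = list(NULL, c("inf", paste0("n", 1:10))))
      X[, "inf"] <- X[, "inf"] + 1.2 * y
      list(X = X, y = y)
    })
    imp <- rf_relevance(sim$X, sim$y, n_trees = 200, seed = seed)
    if (names(which.max(imp)) == "inf") hits <- hits + 1
    expect_gte(min(imp), 0)
    expect_lte(sum(imp), 1 + 1e-9)
  }
  expect_gte(hits, 24)
  # determinism
  sim <- planted_mrmr_design(1, n = 100)
  i1 <- rf_relevance(sim$X, sim$y, n_trees = 100, seed = 3)
  i2 <- rf_relevance(sim$X, sim$y, n_trees = 100, seed = 3)
  expect_identical(i1, i2)
})

test_that("consensus counting and ordering follow the 15-list rule", {
  feats <- sprintf("f%02d", 1:20)
  same <- lapply(1:5, function(i)
    structure(list(criterion = "MID", features = feats,
                   scores = seq(20, 1)), class = "ranking_result"))
  d <- planted_mrmr_design(1, n = 100)
  X <- setNames(d$X[, 1:20], feats)
  cs <- consensus_select(same, X, d$y, m_range = 5:8)
  expect_identical(cs$candidates[1:8], feats[1:8])
  # a feature in every top-5 list is counted 15 times
  expect_equal(unname(cs$frequency["f01"]), 15)
  expect_equal(unname(cs$frequency["f07"]), 10) # top-10 and top-15 lists
  expect_equal(unname(cs$frequency["f12"]), 5)  # top-15 lists only
  expect_equal(unname(cs$frequency["f16"]), 0)  # below every cutoff
  expect_identical(cs$chosen_set, cs$candidates[seq_len(cs$chosen_m)])

  expect_warning(
    consensus_select(lapply(same, function(r) {
      r$features <- r$features[1:10]; r$scores <- r$scores[1:10]; r
    }), X[, 1:10], d$y, m_range = 5:15),
    "truncated")
})

test_that("consensus heads the ordering with the planted informative set", {
  sim <- withr::with_seed(77, {
    n <- 240
    y <- rep(0:1, each = n / 2)
    X <- data.frame(matrix(rnorm(n * 11), n, 11))
    names(X) <- sprintf("noise%02d", 1:11)
    for (j in 1:9) X[[paste0("inf", j)]] <- rnorm(n) + 0.9 * y
    list(X = X, y = y)
  })
  sel <- select_features(sim$X, sim$y, seed = 4)
  expect_true(all(grepl("^inf", sel$consensus$candidates[1:9])))
  expect_true(sel$consensus$chosen_m %in% 5:15)
  expect_equal(length(sel$consensus$chosen_set), sel$consensus$chosen_m)
  expect_named(sel$rankings, c("MID", "MIQ", "FCD", "FCQ", "RFCQ"))
})
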