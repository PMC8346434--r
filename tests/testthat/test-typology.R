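test_that("curve features match closed forms on linear and step curves", {
  t <- seq(0, 2490, 10)
  lin <- consumption_curve(t, 1 - t / 2500)
  f <- extract_features(lin)
  expect_equal(f$t20, 500, tolerance = 1e-9)
  expect_equal(f$t50, 1250, tolerance = 1e-9)
  expect_equal(f$t80, 2000, tolerance = 1e-9)
  expect_equal(f$total_consumed, 2490 / 2500)

  flat <- consumption_curve(t, rep(1, length(t)))
  ff <- extract_features(flat)
  expect_equal(c(ff$t20, ff$t50, ff$t80), c(2500, 2500, 2500))
  expect_equal(ff$total_consumed, 0)

  # instantaneous drop to zero at t = 100 (1-minute sampling)
  ts <- 0:300
  step <- consumption_curve(ts, ifelse(ts < 100, 1, 0))
  fs <- extract_features(step)
  expect_equal(fs$t20, 100, tolerance = 1)
  expect_equal(fs$t50, 100, tolerance = 1)
  expect_equal(fs$t80, 100, tolerance = 1)
  expect_equal(fs$total_consumed, 1)

  expect_error(extract_features(consumption_curve(numeric(0), numeric(0))),
               "empty")
})

test_that("feature ordering t20 <= t50 <= t80 holds under noise and capping", {
  set.seed(31)
  for (i in 1:50) {
    cv <- simulate_curve(sample(LETTERS[1:6], 1), sigma = 0.05, seed = i)
    f <- extract_features(cv)
    expect_lte(f$t20, f$t50)
    expect_lte(f$t50, f$t80)
    expect_lte(f$t80, 2500)
  }
})

test_that("SOTA grows exactly the requested number of leaves", {
  set.seed(6)
  x <- matrix(rnorm(40 * 20), 40)
  tr <- sota_cluster(x, n_clusters = 7, seed = 2)
  expect_equal(tr$n_clusters, 7)
  expect_equal(nrow(tr$centroids), 7)
  expect_length(tr$assignment, 40)
  expect_true(all(tr$assignment %in% 1:7))
  expect_error(sota_cluster(x, 1), "at least 2")
  expect_error(sota_cluster(x, 41), "exceed")
})

test_that("SOTA resource is non-increasing across growth cycles", {
  set.seed(12)
  x <- rbind(matrix(rnorm(30 * 15, 0), 30), matrix(rnorm(30 * 15, 4), 30),
             matrix(rnorm(30 * 15, -3), 30))
  tr <- sota_cluster(x, n_clusters = 8, seed = 3)
  expect_true(all(diff(tr$cycle_resource) <= 1e-8))
})

test_that("SOTA with 2 clusters matches exhaustive 2-means on separated bundles", {
  set.seed(8)
  b1 <- matrix(rnorm(8 * 12, 0, 0.1), 8)
  b2 <- matrix(rnorm(8 * 12, 10, 0.1), 8)
  x <- rbind(b1, b2)[sample(16), ]
  truth <- as.integer(rowMeans(x) > 5)
  tr <- sota_cluster(x, 2, seed = 4)
  # the two-leaf partition must coincide with the obvious optimal 2-split
  expect_equal(length(unique(tr$assignment[truth == 0])), 1)
  expect_equal(length(unique(tr$assignment[truth == 1])), 1)
  expect_false(tr$assignment[truth == 0][1] == tr$assignment[truth == 1][1])
  # exhaustive check: no 2-partition has lower within-cluster SS
  best <- brute_kmeans(x, 2)
  expect_equal(unname(table(tr$assignment)), unname(table(best$assign)))
})

test_that("a single repeated curve yields identical centroids and zero resource", {
  x <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 6)
  tr <- sota_cluster(x, 2, seed = 1)
  expect_equal(tr$centroids[1, ], tr$centroids[2, ], tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(sum(tr$resource), 0, tolerance = 1e-6)
})

test_that("cluster medians equal the sort-and-pick oracle", {
  set.seed(14)
  x <- matrix(rnorm(12 * 5), 12)
  tr <- sota_cluster(x, 3, seed = 9)
  feats <- data.frame(t20 = runif(12, 0, 2500), t50 = runif(12, 0, 2500),
                      t80 = runif(12, 0, 2500), total_consumed = runif(12))
  med <- summarize_clusters(tr, feats)
  for (k in seq_len(3)) {
    m <- tr$assignment == k
    for (col in names(feats)) {
      sorted <- sort(feats[[col]][m])
      n <- length(sorted)
      manual <- if (n %% 2 == 1) sorted[(n + 1) / 2]
                else (sorted[n / 2] + sorted[n / 2 + 1]) / 2
      expect_equal(med[[col]][k], manual)
    }
  }
  # single-member cluster returns that member's features
  feats1 <- feats[1, , drop = FALSE]
  tr1 <- list(assignment = 1L, n_clusters = 1L)
  class(tr1) <- "sota_tree"
  expect_equal(summarize_clusters(tr1, feats1)$t20, feats1$t20)
})

test_that("K-means grouping finds planted structure and the global optimum", {
  set.seed(18)
  centers <- data.frame(t20 = c(100, 900, 100, 900, 1500, 2500),
                        t50 = c(200, 1000, 400, 1600, 2500, 2500),
                        t80 = c(400, 1200, 1700, 2500, 2500, 2500),
                        total_consumed = c(1, 1, 0.9, 0.7, 0.5, 0.03))
  idx <- rep(1:6, length.out = 14)
  feats <- centers[idx, ] + matrix(rnorm(14 * 4, 0, 1e-3), 14)
  km <- kmeans_group(feats, k = 6, seed = 3)
  expect_equal(length(unique(paste(km$group, idx))), 6)   # groups == planted

  # global optimum vs exhaustive partition search at small size
  z <- scale(as.matrix(feats[1:9, ]))
  z[is.nan(z)] <- 0
  km9 <- kmeans_group(feats[1:9, ], k = 3, seed = 3)
  best <- brute_kmeans(z, 3)
  # compare attained WSS on the z-scored scale
  wss <- sum(vapply(1:3, function(g) {
    m <- z[km9$group == g, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }, numeric(1)))
  expect_equal(wss, best$wss, tolerance = 1e-8)

  # k equal to the number of points: singleton groups, zero WSS
  kmn <- kmeans_group(feats[1:6, ], k = 6, seed = 1)
  expect_equal(sort(kmn$group), 1:6)
  expect_equal(kmn$tot_withinss, 0, tolerance = 1e-12)

  # duplicated rows land in the same group
  dup <- centers[c(1, 1, 2, 2, 3, 3, 4, 5), ]
  kmd <- kmeans_group(dup, k = 4, seed = 2)
  expect_equal(unname(kmd$group[1]), unname(kmd$group[2]))
  expect_equal(unname(kmd$group[3]), unname(kmd$group[4]))
  expect_error(kmeans_group(centers, k = 7), "exceed")
})

test_that("letter assignment recovers the archetype identities", {
  feats <- do.call(rbind, lapply(archetype_params(), function(p)
    as.data.frame(archetype_features(p))))
  # shuffle rows; assign_labels must put the right letter on each
  set.seed(3)
  ord <- sample(6)
  lab <- assign_labels(feats[ord, ])
  expect_equal(lab, rownames(feats)[ord])

  # direct description checks: F barely consumes; A is the fastest feeder
  expect_equal(lab[which(feats$total_consumed[ord] < 0.1)], "F")
  expect_equal(lab[which.min(feats$t50[ord])], "A", ignore_attr = TRUE)

  expect_error(assign_labels(feats[c(1, 1, 2, 3, 4, 5), ]), "degenerate")
  expect_error(assign_labels(feats[1:5, ]), "6 groups")
})

test_that("full typology recovers generating archetypes at low noise", {
  set.seed(42)
  letts <- sample(rep(LETTERS[1:6], each = 50))
  cvl <- simulate_curve_set(letts, seed = 99, sigma = 0.02)
  cm <- t(vapply(cvl, function(cv) cv$fraction_intact, numeric(250)))
  fx <- features_table(cvl)
  ty <- build_typology(cm, fx, n_clusters = 14, n_groups = 6, seed = 5)
  expect_equal(ty$tree$n_clusters, 14)
  expect_gte(mean(ty$curve_letters == letts), 0.95)
  # letters partition the curves
  expect_length(ty$curve_letters, 300)
  expect_true(all(ty$curve_letters %in% LETTERS[1:6]))
})

test_that("typology is reproducible under a fixed seed", {
  set.seed(1)
  cvl <- simulate_curve_set(rep(LETTERS[1:6], each = 5), seed = 3, sigma = 0.02)
  cm <- t(vapply(cvl, function(cv) cv$fraction_intact, numeric(250)))
  fx <- features_table(cvl)
  t1 <- build_typology(cm, fx, n_clusters = 8, n_groups = 6, seed = 11)
  t2 <- build_typology(cm, fx, n_clusters = 8, n_groups = 6, seed = 11)
  expect_identical(t1$curve_letters, t2$curve_letters)
  expect_identical(t1$tree$centroids, t2$tree$centroids)
})
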