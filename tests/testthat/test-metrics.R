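test_that("ARI hits its analytic anchor points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c("a", "a", "b", "b", "c")),
               1.0)
  # relabeling does not matter
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(9, 9, 4, 4)), 1.0)
  # all-same vs all-distinct: chance-corrected to 0
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0.0)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI agrees exactly with pair counting over all small partitions", {
  parts <- all_partitions(6, 3)
  expect_gt(length(parts), 100)
  set.seed(2)
  idx <- cbind(sample(length(parts), 120, TRUE),
               sample(length(parts), 120, TRUE))
  for (r in seq_len(nrow(idx))) {
    a <- parts[[idx[r, 1]]]
    b <- parts[[idx[r, 2]]]
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                 tolerance = 1e-14)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  }
})

test_that("purity evaluates the majority-class formula", {
  expect_equal(purity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(purity(c("A", "A", "B", "B"), c("x", "y", "x", "y")), 0.5)
  # one cluster holding everything over k balanced classes -> 1/k
  expect_equal(purity(rep(1, 12), rep(1:4, each = 3)), 1 / 4)
  expect_error(purity(1:3, 1:2), "length")
})

test_that("purity matches direct contingency evaluation on random tables", {
  set.seed(14)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    cl <- sample(1:4, n, TRUE)
    cs <- sample(letters[1:5], n, TRUE)
    direct <- sum(vapply(unique(cl), function(k) {
      max(table(cs[cl == k]))
    }, numeric(1))) / n
    expect_equal(purity(cl, cs), direct)
    # purity 1 iff clusters are class-pure
    expect_equal(purity(cl, cl) == 1, TRUE)
    expect_lt(purity(cl, cs), 1 + 1e-15)
  }
})

test_that("intra_type_distance averages all within-type pairs", {
  coords <- rbind(c(-1, 0), c(1, 0), c(0.5, 0.5), c(0.5, 0.5))
  res <- intra_type_distance(coords, c("a", "a", "b", "b"))
  expect_equal(res$per_type$mean_distance, c(2, 0))
  expect_equal(res$overall, 1)

  set.seed(44)
  xy <- matrix(runif(100, -1, 1), 50, 2)
  res2 <- intra_type_distance(xy, rep("t", 50))
  brute <- mean(as.matrix(dist(xy))[upper.tri(diag(50))])
  expect_equal(res2$per_type$mean_distance, brute, tolerance = 1e-12)
  # singleton types are reported missing
  res3 <- intra_type_distance(xy, c("solo", rep("t", 49)))
  expect_true(is.na(res3$per_type$mean_distance[1]))
  expect_false(is.na(res3$overall))
})

test_that("intra_type_distance shrinks when within-type spread shrinks", {
  centers <- rbind(c(0, 0), c(0.5, 0.5))
  wide <- make_blobs(40, centers, sd = 0.2, seed = 3)
  tight <- make_blobs(40, centers, sd = 0.02, seed = 3)
  d_wide <- intra_type_distance(wide$coords, wide$labels)$overall
  d_tight <- intra_type_distance(tight$coords, tight$labels)$overall
  expect_lt(d_tight, d_wide)
})

test_that("subsampled pair enumeration approximates the exact average", {
  set.seed(91)
  xy <- matrix(rnorm(2 * 2000), ncol = 2)
  lab <- rep("t", 2000)
  exact <- intra_type_distance(xy, lab)$overall
  sub <- intra_type_distance(xy, lab, max_pairs = 5e4, seed = 1)$overall
  expect_equal(sub, exact, tolerance = 0.02)
})

test_that("annotation_accuracy counts per-cell agreement with grouping", {
  expect_equal(annotation_accuracy(c("a", "a", "b"), c("a", "a", "b"))$accuracy_pct,
               100)
  # one of two equal-size types mis-annotated -> 50%
  res <- annotation_accuracy(c("a", "a", "x", "x"), c("a", "a", "b", "b"))
  expect_equal(res$accuracy_pct, 50)
  expect_equal(res$per_type$recall[res$per_type$cell_type == "b"], 0)
  # grouping map collapses subtypes before comparison
  gm <- c(t_naive = "T", t_mem = "T", b = "B", x = "X", a = "A")
  expect_equal(annotation_accuracy(c("t_naive", "b"), c("t_mem", "b"),
                                   group_map = gm)$accuracy_pct, 100)
  expect_error(annotation_accuracy(c("zz", "b"), c("t_mem", "b"),
                                   group_map = gm), "zz")
})

test_that("evaluate_clustering bundles metrics and serializes to JSON", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(40, 0)), sd = 0.5, seed = 10)
  g <- knn_graph(blobs$coords, k = 25)
  cl <- louvain_cluster(g, seed = 0)
  truth <- tibble::tibble(cell_id = rownames(blobs$coords),
                          cell_type = paste0("t", blobs$labels))
  e <- rescale_coords(structure(list(coords = blobs$coords, method = "tsne",
                                     seed = 0, perplexity = 30,
                                     rescaled = FALSE), class = "embedding"))
  rep <- evaluate_clustering(cl, truth, e = e)
  expect_equal(rep$ari, 1)
  expect_equal(rep$purity, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$ari, 1)
  expect_equal(parsed$n_clusters, 2)
})
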