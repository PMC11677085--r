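test_that("shannon index matches direct evaluation and its entropy bound", {
  expect_equal(shannon_index(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(10), 0)
  expect_equal(shannon_index(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), "zero total")

  set.seed(7)
  for (i in 1:20) {
    x <- rpois(12, 4)
    if (sum(x) == 0) next
    h <- shannon_index(x)
    expect_lte(h, log(sum(x > 0)) + 1e-12)
  }
})

test_that("faith PD equals brute-force subtree sums and is monotone", {
  tr <- read_tree(textConnection <- local({
    f <- tempfile(); writeLines("((A:1,B:1):0.5,C:1.5);", f); f
  }))
  expect_equal(unname(faith_pd(c("A", "B"), tr)), 2.0)
  expect_equal(unname(faith_pd(c("A", "B", "C"), tr)), 4.0)
  expect_equal(unname(faith_pd("A", tr)), 0)
  expect_error(faith_pd(c("A", "Z"), tr), "Z")

  set.seed(11)
  for (i in 1:20) {
    tree <- simulate_tree(sample(6:15, 1))
    k <- sample(2:length(tree$tip.label), 1)
    tips <- sample(tree$tip.label, k)
    expect_equal(unname(faith_pd(tips, tree)), brute_pd(tips, tree),
                 tolerance = 1e-10)
    if (k < length(tree$tip.label)) {
      extra <- sample(setdiff(tree$tip.label, tips), 1)
      expect_gte(faith_pd(c(tips, extra), tree) + 1e-12, faith_pd(tips, tree))
    }
  }
})

test_that("bray-curtis matches its definition and bounds", {
  m <- matrix(c(1, 1, 1, 1, 2, 0, 0, 2, 1, 3), 5, 2, byrow = TRUE)
  t <- tiny_table(m)
  d <- bray_curtis(t)
  expect_equal(d[1, 2], 0)            # identical rows
  expect_equal(d[3, 4], 1)            # disjoint supports
  expect_equal(d[1, 5], 2 / 6)        # hand evaluation
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_error(bray_curtis(matrix(0, 2, 2)), "zero total")
})

test_that("NMDS recovers embeddable configurations and stress is rigid-motion invariant", {
  set.seed(3)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  ord <- suppressWarnings(nmds_ordination(d, k = 2, seed = 1))
  expect_lt(ord$stress, 1e-4)
  expect_equal(colMeans(ord$points), c(0, 0), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## rotating the input coordinates leaves the (distance-based) stress alone
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  d2 <- as.matrix(dist(pts %*% R)); dimnames(d2) <- dimnames(d)
  ord2 <- suppressWarnings(nmds_ordination(d2, k = 2, seed = 1))
  expect_equal(ord$stress, ord2$stress, tolerance = 1e-6)
  expect_error(nmds_ordination(d, k = 6), "smaller")
})

test_that("ANOSIM separates groups, respects the permutation p bound and is centered under the null", {
  set.seed(5)
  within <- matrix(abs(rnorm(36, 0.1, 0.02)), 6, 6)
  d <- (within + t(within)) / 2
  d[1:3, 4:6] <- d[1:3, 4:6] + 5     # all between > all within
  d[4:6, 1:3] <- t(d[1:3, 4:6])
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  g <- rep(c("A", "B"), each = 3)
  res <- anosim_test(d, g, n_perm = 199, seed = 1)
  expect_equal(res$value, 1)
  expect_gte(res$p_value, 1 / 200)

  ## null calibration: random distances, many seeds
  rs <- replicate(60, {
    x <- matrix(rnorm(18), 6, 3)
    dn <- as.matrix(dist(x)); dimnames(dn) <- dimnames(d)
    anosim_test(dn, sample(g), n_perm = 49, seed = NULL)$value
  })
  expect_lt(abs(mean(rs)), 0.12)
  expect_error(anosim_test(d, c("A", "B", "C", "D", "E", "F")), "at least 2")
})

test_that("mantel and partial mantel behave as correlations of distance structure", {
  set.seed(9)
  x <- matrix(rnorm(24), 8, 3)
  d1 <- as.matrix(dist(x))
  ids <- paste0("s", 1:8); dimnames(d1) <- list(ids, ids)
  r <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r$value, 1, tolerance = 1e-12)
  ## affine transform, pearson: still r = 1
  d2 <- 3 * d1 + 0.5; diag(d2) <- 0
  expect_equal(mantel_test(d1, d2, n_perm = 99, seed = 1)$value, 1,
               tolerance = 1e-12)

  ## independent matrices: mean r near 0 over seeds
  rs <- replicate(60, {
    a <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
    b <- as.matrix(dist(matrix(rnorm(24), 8, 3)))
    dimnames(a) <- dimnames(b) <- list(ids, ids)
    mantel_test(a, b, n_perm = 23)$value
  })
  expect_lt(abs(mean(rs)), 0.1)

  ## controlling for the second matrix itself wipes out the correlation
  d3 <- as.matrix(dist(matrix(rnorm(24), 8, 3))); dimnames(d3) <- list(ids, ids)
  pr <- partial_mantel_test(d1, d3, d3, n_perm = 99, seed = 1)
  expect_lt(abs(pr$value), 1e-8)
  ## d1 = d2 with an unrelated control stays near 1
  pr2 <- partial_mantel_test(d1, d1, d3, n_perm = 99, seed = 1)
  expect_gt(pr2$value, 0.95)
})

test_that("correlation screen reports per-layer correlations and flags constants", {
  set.seed(2)
  ids <- paste0("s", 1:12)
  resp <- data.frame(div = rnorm(12), row.names = ids)
  pred <- data.frame(same = resp$div, anti = -resp$div, const = rep(1, 12),
                     row.names = ids)
  out <- correlation_screen(resp, pred, method = "spearman")
  expect_equal(out$r[out$predictor == "same"], 1)
  expect_equal(out$r[out$predictor == "anti"], -1)
  expect_true(is.na(out$r[out$predictor == "const"]))
  expect_identical(out$flag[out$predictor == "const"], "constant")

  layers <- setNames(rep(c("W", "S1"), each = 6), ids)
  out2 <- correlation_screen(resp, pred["same"], layers = layers)
  expect_setequal(out2$layer, c("W", "S1"))
  expect_equal(out2$n, c(6, 6))
})

test_that("forward selection finds planted predictors and can stay empty", {
  set.seed(4)
  n <- 60
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  y <- 3 * X$x1
  fit <- suppressWarnings(forward_select_regression(y, X))  # perfect fit
  expect_identical(fit$selected[1], "x1")
  expect_gt(fit$adj_r_squared, 0.999)

  ## pure noise: the empty model is admissible (selection may stop at 0)
  y0 <- rnorm(n)
  fit0 <- forward_select_regression(y0, X)
  expect_lte(length(fit0$selected), 2)

  ## planted two-signal recovery across seeds
  hits <- 0
  for (s in 1:30) {
    set.seed(100 + s)
    X2 <- as.data.frame(matrix(rnorm(100 * 7), 100, 7))
    names(X2) <- c("a", "b", paste0("n", 1:5))
    y2 <- X2$a + X2$b + rnorm(100, 0, 0.3)
    f2 <- forward_select_regression(y2, X2)
    hits <- hits + (all(c("a", "b") %in% f2$selected[1:2]))
  }
  expect_gte(hits, 27)
})
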