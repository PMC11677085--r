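make_tree <- function() {
  f <- tempfile(); writeLines("((A:1,B:1):0.5,C:1.5);", f)
  read_tree(f)
}

test_that("betaMNTD matches the double-loop oracle and scales with branch lengths", {
  tr <- make_tree()
  D <- ape::cophenetic.phylo(tr)

  t1 <- otu_table(matrix(c(1, 2, 3, 1, 2, 3), 2, 3, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
                  "bacteria", c(s1 = "W", s2 = "W"))
  expect_equal(unname(beta_mntd(t1, tr)[1, 2]), 0)   # shared taxa: nearest is itself

  t2 <- otu_table(matrix(c(4, 0, 0, 0, 9, 0), 2, 3, byrow = TRUE,
                         dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
                  "bacteria", c(s1 = "W", s2 = "W"))
  expect_equal(unname(beta_mntd(t2, tr)[1, 2]), D["A", "B"])

  w <- matrix(c(0.5, 0.5, 0, 0, 0.2, 0.8), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  t3 <- otu_table(w, "bacteria", c(s1 = "W", s2 = "W"))
  expect_equal(unname(beta_mntd(t3, tr)[1, 2]),
               unname(brute_bmntd(w[1, ], w[2, ], D)), tolerance = 1e-12)
  expect_equal(unname(beta_mntd(t3, tr, abundance_weighted = FALSE)[1, 2]),
               unname(brute_bmntd(w[1, ], w[2, ], D, weighted = FALSE)),
               tolerance = 1e-12)

  ## global branch-length multiplier scales betaMNTD linearly
  tr5 <- tr; tr5$edge.length <- tr$edge.length * 5
  expect_equal(beta_mntd(t3, tr5), 5 * beta_mntd(t3, tr), tolerance = 1e-12)

  ## random fixtures against the oracle
  set.seed(8)
  for (i in 1:10) {
    tree <- simulate_tree(7)
    Dr <- ape::cophenetic.phylo(tree)
    m <- matrix(rpois(21, 2), 3, 7,
                dimnames = list(paste0("s", 1:3), tree$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    tt <- tiny_table(m)
    b <- beta_mntd(tt, tree)
    for (k in 1:2) for (l in (k + 1):3)
      expect_equal(unname(b[k, l]), unname(brute_bmntd(m[k, ], m[l, ], Dr)),
                   tolerance = 1e-12)
  }
})

test_that("betaNTI masks degenerate nulls and centres exchangeable cases", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  t <- otu_table(matrix(c(3, 1, 0, 0, 0, 0, 2, 5), 2, 4, byrow = TRUE,
                        dimnames = list(c("s1", "s2"), LETTERS[1:4])),
                 "bacteria", c(s1 = "W", s2 = "W"))
  expect_warning(b <- bnti(t, star, null_config(n_null = 49, seed = 1)),
                 "degenerate")
  expect_true(is.na(b$values[1, 2]))
})

test_that("Monte-Carlo betaNTI null matches exhaustive tip permutation on a small tree", {
  set.seed(21)
  tree <- simulate_tree(5)
  D <- ape::cophenetic.phylo(tree)
  m <- matrix(c(5, 3, 0, 0, 0,
                0, 0, 4, 2, 1), 2, 5, byrow = TRUE,
              dimnames = list(c("s1", "s2"), tree$tip.label))
  t <- tiny_table(m)

  perms <- perms_of(5)
  null_vals <- apply(perms, 1, function(p) {
    Dp <- D[p, p]
    dimnames(Dp) <- dimnames(D)
    brute_bmntd(m[1, ], m[2, ], Dp)
  })
  mu_ex <- mean(null_vals)
  ## exhaustive sd over the uniform permutation distribution (population sd)
  sd_ex <- sqrt(mean((null_vals - mu_ex)^2))

  b <- bnti(t, tree, null_config(n_null = 999, seed = 5))
  expect_lt(abs(b$null_mean[1, 2] - mu_ex), 3 * sd_ex / sqrt(999))
  expect_lt(abs(b$null_sd[1, 2] - sd_ex), 3 * sd_ex / sqrt(2 * 998))
  expect_equal(unname(b$observed[1, 2]), unname(brute_bmntd(m[1, ], m[2, ], D)),
               tolerance = 1e-12)
})

test_that("RC-bray hits its definition bounds and matches exhaustive enumeration", {
  ## identical samples in a diverse pool: more similar than almost any null
  m <- matrix(c(5, 5, 5, 5, 0, 0,
                5, 5, 5, 5, 0, 0,
                1, 0, 9, 2, 4, 4,
                0, 7, 1, 1, 6, 1), 4, 6, byrow = TRUE)
  t <- tiny_table(m)
  rc <- raup_crick_bray(t, null_config(n_null = 499, seed = 2))
  expect_lt(rc$values[1, 2], -0.9)
  expect_true(all(abs(rc$values[upper.tri(rc$values)]) <= 1))

  expect_error(raup_crick_bray(tiny_table(matrix(c(2, 3), 2, 1))),
               "single-taxon")

  ## enumeration oracle on a tiny metacommunity
  m2 <- matrix(c(3, 2, 0, 0,
                 0, 0, 3, 1), 2, 4, byrow = TRUE)
  t2 <- tiny_table(m2)
  ex <- rc_exact(m2)
  mc <- raup_crick_bray(t2, null_config(n_null = 999, seed = 31))
  p_hat <- (ex$rc + 1) / 2
  se <- 2 * sqrt(max(p_hat * (1 - p_hat), 1e-6) / 999)
  expect_lt(abs(mc$values[1, 2] - ex$rc), 3 * se + 1 / 999)
})

test_that("the five-way classifier applies the rule table exactly", {
  ids <- c("x", "y")
  mk <- function(v) {
    m <- matrix(c(0, v, v, 0), 2, 2, dimnames = list(ids, ids))
    pairwise_statistic(m, "s")
  }
  cases <- list(
    list(b = -3,   r = 0.99,  lab = "homogeneous selection"),
    list(b = 3,    r = -0.99, lab = "heterogeneous selection"),
    list(b = 0,    r = 0.97,  lab = "dispersal limitation"),
    list(b = 0,    r = -0.97, lab = "homogenizing dispersal"),
    list(b = 1.9,  r = 0.5,   lab = "undominated"),
    list(b = -2.0, r = 0.99,  lab = "dispersal limitation"),  # boundary: |b| <= T
    list(b = 2.1,  r = 0.99,  lab = "heterogeneous selection"))
  for (cs in cases) {
    res <- classify_assembly(mk(cs$b), mk(cs$r))
    expect_identical(unname(res$process[1, 2]), cs$lab)
    expect_equal(sum(res$fractions), 1)
  }
})

test_that("per-group fractions are computed over within-group pairs only", {
  ids <- paste0("s", 1:12)
  g <- setNames(rep(c("W", "S1"), each = 6), ids)
  b <- matrix(-3, 12, 12, dimnames = list(ids, ids)); diag(b) <- 0
  r <- matrix(0, 12, 12, dimnames = list(ids, ids))
  res <- classify_assembly(pairwise_statistic(b, "bNTI"),
                           pairwise_statistic(r, "RCbray"))
  fr <- assembly_by_group(res, g)
  expect_equal(unique(fr$n_pairs), choose(6, 2))   # 15 within-layer pairs
  hs <- fr[fr$process == "homogeneous selection", ]
  expect_equal(hs$fraction, c(1, 1))
  expect_warning(assembly_by_group(res, setNames(c("A", rep("B", 11)), ids)),
                 "omitted")
})

test_that("null-model stages are bitwise reproducible under a fixed seed", {
  set.seed(99)
  tree <- simulate_tree(12)
  m <- matrix(rpois(48, 3) + 1, 4, 12,
              dimnames = list(paste0("s", 1:4), tree$tip.label))
  t <- tiny_table(m)
  cfg <- null_config(n_null = 99, seed = 123)
  expect_identical(suppressWarnings(bnti(t, tree, cfg)$values),
                   suppressWarnings(bnti(t, tree, cfg)$values))
  expect_identical(raup_crick_bray(t, cfg)$values,
                   raup_crick_bray(t, cfg)$values)
})
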