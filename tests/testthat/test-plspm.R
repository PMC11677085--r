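test_that("path model specs validate block membership and acyclicity", {
  expect_error(plspm_spec(list(A = "x", B = "x"), list(B = "A")),
               "more than one block")
  expect_error(plspm_spec(list(A = "x", B = "y"), list(B = "A", A = "B")),
               "cycle")
  sp <- plspm_spec(list(A = "x", B = "y"), list(B = "A"))
  expect_s3_class(sp, "plspm_spec")
})

test_that("single-indicator blocks reproduce ordinary correlation/path analysis", {
  set.seed(6)
  n <- 80
  x <- rnorm(n); y <- 0.6 * x + rnorm(n, 0, 0.7)
  dat <- data.frame(x = x, y = y)
  m <- fit_plspm(dat, plspm_spec(list(X = "x", Y = "y"), list(Y = "X")))
  expect_equal(m$paths$coefficient, cor(x, y), tolerance = 1e-10)
  expect_equal(unname(m$r_squared["Y"]), cor(x, y)^2, tolerance = 1e-10)
  ## latent scores have unit variance
  expect_equal(unname(apply(m$scores, 2, sd)), c(1, 1), tolerance = 1e-10)

  ## three single-indicator blocks = OLS path analysis on standardized data
  z <- 0.5 * x - 0.4 * y + rnorm(n, 0, 0.5)
  dat3 <- data.frame(x = x, y = y, z = z)
  m3 <- fit_plspm(dat3, plspm_spec(list(X = "x", Y = "y", Z = "z"),
                                   list(Z = c("X", "Y"))))
  ols <- coef(lm(scale(z) ~ scale(x) + scale(y)))[-1]
  expect_equal(m3$paths$coefficient, unname(ols), tolerance = 1e-8)
})

test_that("duplicated manifests load equally and noiseless structures reach GoF 1", {
  set.seed(13)
  lv <- rnorm(60)
  dat <- data.frame(a = lv, b = lv, c = 2 * lv, d = -3 * lv)
  sp <- plspm_spec(list(L1 = c("a", "b"), L2 = c("c", "d")), list(L2 = "L1"))
  m <- fit_plspm(dat, sp)
  expect_equal(m$loadings[["a"]], m$loadings[["b"]], tolerance = 1e-9)
  expect_equal(m$gof, 1, tolerance = 1e-6)
  expect_true(all(abs(m$loadings) <= 1 + 1e-9))

  ## observation order invariance
  perm <- sample(60)
  m2 <- fit_plspm(dat[perm, ], sp)
  expect_equal(m2$paths$coefficient, m$paths$coefficient, tolerance = 1e-8)

  expect_error(fit_plspm(data.frame(a = rep(1, 60), b = lv),
                         plspm_spec(list(L1 = "a", L2 = "b"), list(L2 = "L1"))),
               "constant")
})

test_that("low-loading manifests are pruned and refit, strong specs are fixpoints", {
  set.seed(14)
  n <- 100
  lv1 <- rnorm(n); lv2 <- 0.8 * lv1 + rnorm(n, 0, 0.6)
  dat <- data.frame(a = lv1 + rnorm(n, 0, 0.2), b = lv1 + rnorm(n, 0, 0.2),
                    junk = rnorm(n),
                    c = lv2 + rnorm(n, 0, 0.2), d = lv2 + rnorm(n, 0, 0.2))
  sp <- plspm_spec(list(L1 = c("a", "b", "junk"), L2 = c("c", "d")),
                   list(L2 = "L1"))
  m <- fit_plspm(dat, sp)
  pruned <- prune_low_loadings(m)
  expect_false("junk" %in% unlist(pruned$spec$blocks))
  expect_setequal(pruned$spec$blocks$L1, c("a", "b"))
  ## a spec whose loadings all clear the threshold is left unchanged
  again <- prune_low_loadings(pruned)
  expect_identical(again$spec$blocks, pruned$spec$blocks)

  ## planted noise manifest removed across seeds
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    lv <- rnorm(60)
    d2 <- data.frame(a = lv + rnorm(60, 0, 0.3), b = lv + rnorm(60, 0, 0.3),
                     nz = rnorm(60), y = 0.7 * lv + rnorm(60, 0, 0.5))
    mm <- fit_plspm(d2, plspm_spec(list(L = c("a", "b", "nz"), Y = "y"),
                                   list(Y = "L")))
    hits <- hits + !("nz" %in% unlist(prune_low_loadings(mm)$spec$blocks))
  }
  expect_gte(hits, 18)
})

test_that("bootstrap paths are seeded, detect strong paths and keep null paths insignificant", {
  set.seed(15)
  n <- 100
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.6)
  dat <- data.frame(x = x, y = y)
  sp <- plspm_spec(list(X = "x", Y = "y"), list(Y = "X"))
  m <- fit_plspm(dat, sp)
  b1 <- bootstrap_paths(m, B = 200, seed = 9)
  b2 <- bootstrap_paths(m, B = 200, seed = 9)
  expect_identical(b1$boot, b2$boot)
  expect_lt(b1$boot$p_value, 0.05)
  expect_gt(b1$boot$ci_lower, 0)

  ## null path: moderate rejection behaviour (single-run smoke check)
  y0 <- rnorm(n)
  m0 <- fit_plspm(data.frame(x = x, y = y0), sp)
  b0 <- bootstrap_paths(m0, B = 200, seed = 10)
  expect_true(b0$boot$ci_lower < 0 && b0$boot$ci_upper > 0)
})

test_that("the pairwise observation table broadcasts layer covariates correctly", {
  ids <- paste0(rep(c("W", "S1"), each = 4), "_", 1:4)
  layers <- setNames(rep(c("W", "S1"), each = 4), ids)
  env <- data.frame(pH = c(7, 7, 7, 7, 8, 8, 8, 8),
                    NH4 = c(1, 2, 1, 2, 3, 4, 3, 4), row.names = ids)
  b <- matrix(rnorm(64), 8, 8, dimnames = list(ids, ids))
  b <- (b + t(b)) / 2
  bn <- pairwise_statistic(b, "bNTI")
  pn <- data.frame(PN_F = c(2.2, 1.5), PN_P = c(2.5, 1.1),
                   row.names = c("W", "S1"))
  obs <- build_observation_table(env, pn, bn, layers)
  expect_equal(nrow(obs), 2 * choose(4, 2))     # within-layer pairs only
  expect_true(all(obs$PN_F[obs$layer == "W"] == 2.2))
  expect_true(all(obs$PN_P[obs$layer == "S1"] == 1.1))
  ## identical standardized env vectors give distance 0
  same <- obs[obs$id1 == "W_1" & obs$id2 == "W_3", ]
  expect_equal(same$Env, 0, tolerance = 1e-12)
  expect_equal(obs$bNTI, b[cbind(obs$id1, obs$id2)])
})
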