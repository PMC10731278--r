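test_that("membership normalizes the published index columns correctly", {
  fx <- load_fixture("table2_seedling_eval")
  u <- membership_values(fx$F)
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(unname(round(u, 3)), unname(fx$U), tolerance = 0.002)
  # each column attains both endpoints
  expect_equal(unname(apply(u, 2, min)), rep(0, 3))
  expect_equal(unname(apply(u, 2, max)), rep(1, 3))
})

test_that("membership handles two-point and degenerate columns", {
  expect_equal(unname(membership_values(cbind(c(1, 3)))[, 1]), c(0, 1))
  flat <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(membership_values(flat), "constant column.*b")
  expect_warning(u <- membership_values(flat, degenerate = "drop"),
                 "dropping")
  expect_equal(colnames(u), "a")
})

test_that("membership is invariant under positive affine transforms", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(24), 6, 4)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(membership_values(a * x + b), membership_values(x),
                 tolerance = 1e-12)
  }
})

test_that("comprehensive indices recover planted variance structure", {
  # two orthonormal mean-zero factors with planted variance ratio 3:1;
  # columns are unit-sd by construction, eigenvalues known exactly
  u1 <- c(1, -1, 0, 0, 0) / sqrt(2)
  u2 <- c(1, 1, -2, 0, 0) / sqrt(6)
  X <- cbind(sqrt(3) * u1 + u2, sqrt(3) * u1 - u2,
             sqrt(3) * u1 + u2, sqrt(3) * u1 - u2)
  colnames(X) <- paste0("i", 1:4)
  ci <- comprehensive_indices(X)
  expect_equal(ci$contribution[1:2], c(75, 25), tolerance = 1e-9)
  # independent oracle: eigen-decomposition of the sample covariance
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ci$eigenvalues[1:2], ev[1:2], tolerance = 1e-9)
})

test_that("rank-1 input yields a single 100% component", {
  z <- standardize_columns(cbind(c(1, 2, 4, 8)))
  X <- cbind(a = drop(z), b = drop(z), c = drop(z))
  ci <- comprehensive_indices(X)
  expect_equal(length(ci$contribution), 1)
  expect_equal(ci$contribution, 100, tolerance = 1e-9)
})

test_that("with g genotypes at most g-1 components carry variance", {
  set.seed(5)
  for (i in 1:10) {
    X <- standardize_columns(matrix(rnorm(4 * 6), 4, 6))
    ci <- comprehensive_indices(X, retain = "all")
    expect_equal(sum(ci$contribution), 100, tolerance = 1e-6)
    expect_equal(sum(ci$contribution[1:3]), 100, tolerance = 1e-6)
    # reconstruction from all components reproduces the input
    expect_equal(ci$scores %*% t(ci$loadings), unclass(X),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # default retention caps at genotypes - 1
    expect_lte(ncol(comprehensive_indices(X)$scores), 3)
  }
})

test_that("indices agree with prcomp up to orientation", {
  set.seed(9)
  X <- standardize_columns(matrix(rnorm(30), 6, 5))
  ci <- comprehensive_indices(X)
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  m <- ncol(ci$scores)
  expect_equal(abs(unname(ci$scores)), abs(unname(pc$x[, 1:m])),
               tolerance = 1e-8)
  expect_equal(ci$eigenvalues, unname(pc$sdev[1:m]^2), tolerance = 1e-8)
  # orientation rule: loading sums positive (or tie broken by largest)
  for (j in seq_len(m)) expect_gte(sum(ci$loadings[, j]), -1e-12)
})

test_that("non-standardized input to comprehensive_indices is refused", {
  expect_error(comprehensive_indices(matrix(1:12, 4, 3)), "standardized")
  expect_error(comprehensive_indices(matrix(rnorm(3), 1, 3)), "at least 2")
})

test_that("contribution weights normalize to one", {
  expect_equal(contribution_weights(c(45.5, 31.7, 22.8)),
               c(0.455, 0.317, 0.228))
  expect_equal(contribution_weights(rep(25, 4)), rep(0.25, 4))
  expect_equal(contribution_weights(100), 1)
  expect_error(contribution_weights(c(50, 0)), "positive")
  set.seed(2)
  for (i in 1:10) {
    w <- contribution_weights(runif(sample(2:6, 1), 0.1, 60))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
  }
})

test_that("weighted D reproduces the published seedling scores", {
  fx <- load_fixture("table2_seedling_eval")
  sc <- d_score_weighted(membership_values(fx$F), fx$weights)
  expect_equal(sc$d, unname(fx$D), tolerance = 0.002)
  expect_equal(sc$rank, unname(fx$rank))
  expect_equal(sc$genotype[order(sc$rank)],
               c("JaCg144", "JaCg151", "JaCg32", "JaCg205"))
})

test_that("D scores respect bounds and simple identities", {
  u <- rbind(a = c(0, 0, 0), b = c(1, 1, 1), c = c(0.2, 0.4, 0.6))
  d <- d_score_unweighted(u)
  expect_equal(d$d, c(0, 1, 0.4))
  expect_equal(d$rank, c(3, 1, 2))
  # uniform weights reduce the weighted score to the unweighted one
  expect_equal(d_score_weighted(u, rep(1 / 3, 3))$d, d$d)
  # single column with weight 1 is the identity
  expect_equal(d_score_weighted(u[, 1, drop = FALSE], 1)$d, u[, 1],
               ignore_attr = TRUE)
  expect_error(d_score_weighted(u, c(0.5, 0.5)), "weights")
})

test_that("membership, weights and D match the brute-force oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(2:5, 1); p <- sample(2:5, 1)
    x <- matrix(rnorm(n * p), n, p)
    u <- membership_values(x)
    expect_equal(unname(u), oracle_membership(x), tolerance = 1e-12)
    expect_equal(d_score_unweighted(u)$d, oracle_d_unweighted(u),
                 tolerance = 1e-12)
    pr <- runif(p, 1, 50)
    w <- contribution_weights(pr)
    expect_equal(w, oracle_weights(pr), tolerance = 1e-12)
    expect_equal(d_score_weighted(u, w)$d, oracle_d_weighted(u, w),
                 tolerance = 1e-12)
  }
})

test_that("full evaluation recovers planted structure end to end", {
  # zero-noise generator: unweighted D order equals the latent order
  cfg <- generator_config(n_genotypes = 10, noise_cv = 0, seed = 19)
  tab <- generate_trait_table(cfg)
  tol <- attr(tab, "latent_tolerance")
  ev <- evaluate(tab, mode = "unweighted")
  expect_equal(order(-ev$scores$d),
               order(-tol[ev$scores$genotype]))
  expect_true(all(ev$scores$d >= 0 & ev$scores$d <= 1))

  # weighted mode runs the full PCA chain and stays in bounds
  cfg2 <- generator_config(
    n_genotypes = 6, noise_cv = 0.05, seed = 23,
    traits = data.frame(label = c("area", "biomass"),
                        control_mean = c(4, 2), control_cv = 0.2,
                        sensitivity = c(0.5, 0.3), direction = "higher"))
  ev2 <- evaluate(generate_trait_table(cfg2), mode = "weighted")
  expect_true(all(ev2$scores$d >= 0 & ev2$scores$d <= 1))
  expect_equal(sum(ev2$weights), 1, tolerance = 1e-9)
  expect_equal(ncol(ev2$crc), 8)

  # a single genotype cannot be evaluated
  one <- trait_table(data.frame(genotype = "A", trait = "t",
                                treatment = c(0, 2), replicate = 1L,
                                value = c(4, 2)))
  expect_error(evaluate(one), "at least 2")
})

test_that("inverse-PCA construction reproduces the printed evaluation", {
  # Build a 4-genotype x 4-indicator standardized matrix whose principal
  # component scores are (a positive multiple of) the published index
  # matrix: X = cF V' with V = three orthonormal Hadamard columns, whose
  # equal-magnitude rows make every indicator variance exactly 1 when
  # c^2 = 12 / sum(F^2). Column-wise membership is invariant to the
  # common positive factor c, so running the weighted chain on X must
  # return the published weights, memberships and D scores (up to the
  # 3-decimal rounding of the printed F, and up to component sign,
  # which the printed table does not constrain).
  fx <- load_fixture("table2_seedling_eval")
  Fm <- fx$F
  H <- matrix(c(1, 1, 1, 1,  1, -1, 1, -1,  1, 1, -1, -1), 4, 3) / 2
  cc <- sqrt(12 / sum(Fm^2))
  X <- (cc * Fm) %*% t(H)
  colnames(X) <- paste0("i", 1:4)

  z <- standardize_columns(X)   # sds are 1 up to printed rounding
  ci <- comprehensive_indices(z)
  expect_equal(length(ci$contribution), 3)
  expect_equal(ci$cumulative[3], 100, tolerance = 1e-6)

  w <- contribution_weights(ci$contribution)
  expect_equal(w, unname(fx$weights), tolerance = 0.002)

  # align component signs with the printed convention before membership
  flip <- sign(diag(cor(ci$scores, Fm)))
  scores <- sweep(ci$scores, 2, flip, "*")
  expect_equal(unname(scores), unname(cc * Fm), tolerance = 0.01)
  sc <- d_score_weighted(membership_values(scores), w)
  expect_equal(sc$d, unname(fx$D), tolerance = 0.005)
  expect_equal(sc$rank, unname(fx$rank))
})
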