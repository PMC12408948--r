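test_that("population tips: duplicates become near-zero cherries", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pops <- data.frame(species = c("A", "A", "B", "C"),
                     pop = c("A|0.6", "A|0.9", "B|0.9", "C|0.9"))
  pt <- attach_population_tips(tree, pops)
  expect_equal(ape::Ntip(pt), 4)
  expect_setequal(pt$tip.label, pops$pop)
  C <- phylo_covariance(pt)
  # duplicated populations share essentially their full path length
  expect_equal(C["A|0.6", "A|0.9"], C["A|0.6", "A|0.6"], tolerance = 1e-4)
  # single-record species keep their original depth
  expect_equal(unname(C["C|0.9", "C|0.9"]), 2, tolerance = 1e-9)
  expect_error(attach_population_tips(tree,
                                      data.frame(species = "Z", pop = "Z|1")),
               "not in tree")
})

test_that("phylogenetic covariance is the shared-path matrix and PSD", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unname(phylo_covariance(star)), diag(3))
  sisters <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  C <- phylo_covariance(sisters)
  expect_equal(unname(C["A", "B"]), 0.5)
  for (seed in 1:20) {
    tr <- simulate_yule_tree(10, seed = seed)
    C <- phylo_covariance(tr)
    expect_equal(C, t(C))
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("lambda transform endpoints", {
  tr <- simulate_yule_tree(8, seed = 5)
  C <- phylo_covariance(tr)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
})

test_that("Pagel's lambda ML separates star-tree from Brownian data", {
  tr <- simulate_yule_tree(150, seed = 11)
  C <- phylo_covariance(tr)
  # independent data: no signal
  set.seed(12)
  X0 <- matrix(rnorm(150 * 4), 150, 4, dimnames = list(rownames(C), NULL))
  expect_lt(pagel_lambda_ml(X0, C)$lambda, 0.1)
  # pure Brownian data: full signal
  X1 <- simulate_bm_traits(tr, 1, diag(4), seed = 13)
  expect_gt(pagel_lambda_ml(X1, C)$lambda, 0.9)
})

test_that("lambda ML tracks the phytools estimator on simulated data", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(60, seed = 3)
  Sig <- diag(4); Sig[1, 2] <- Sig[2, 1] <- 0.6
  X <- simulate_bm_traits(tr, 0.7, Sig, seed = 4)
  mine <- pagel_lambda_ml(X, phylo_covariance(tr))$lambda
  oracle <- phytools::phyl.pca(tr, X, method = "lambda", mode = "cov")$lambda
  expect_equal(mine, oracle, tolerance = 0.05)
})

test_that("star-tree pPCA reproduces ordinary PCA up to sign", {
  set.seed(21)
  X <- matrix(rnorm(40 * 5), 40, 5)
  X <- scale(X %*% matrix(runif(25, -1, 1), 5, 5))
  fit <- ppca(X)                               # C = I
  ref <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(fit$eigenvalues, unname(ref$sdev^2), tolerance = 1e-8)
  expect_equal(abs(unname(fit$scores)), abs(unname(ref$x)), tolerance = 1e-8)
  expect_equal(sum(fit$eigenvalues),
               sum(diag(stats::cov(X))), tolerance = 1e-10)
})

test_that("pPCA matches the phytools reference implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(50, seed = 31)
  X <- simulate_bm_traits(tr, 1, diag(5), seed = 32)
  fit <- ppca(X, phylo_covariance(tr))
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(fit$eigenvalues, unname(diag(ref$Eval)), tolerance = 1e-8)
  expect_equal(abs(unname(fit$scores)), abs(unclass(unname(ref$S))),
               tolerance = 1e-8)
})

test_that("collinear traits collapse onto one axis", {
  set.seed(41)
  x <- rnorm(30)
  X <- cbind(x, 2 * x)
  fit <- ppca(scale(X))
  expect_equal(fit$var_prop[1], 1, tolerance = 1e-10)
})

test_that("varimax rotation is orthogonal and preserves communalities", {
  set.seed(51)
  X <- scale(matrix(rnorm(60 * 6), 60, 6) %*% matrix(runif(36, -1, 1), 6, 6))
  fit <- ppca(X)
  retained <- rep(c(TRUE, FALSE), c(3, 3))
  rot <- varimax_rotate(fit$loadings, fit$scores, retained)
  R <- rot$rotmat
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  h_before <- rowSums(fit$loadings[, retained]^2)
  h_after <- rowSums(rot$loadings^2)
  expect_equal(h_before, h_after, tolerance = 1e-8)
  # already-simple structure stays put (up to sign/permutation)
  Lsimple <- diag(c(2, 1.5))
  rs <- varimax_rotate(Lsimple, matrix(0, 1, 2))
  expect_equal(abs(unclass(rs$loadings)), Lsimple, tolerance = 1e-6,
               ignore_attr = TRUE)
  # single retained axis: identity rotation
  r1 <- varimax_rotate(fit$loadings, fit$scores, c(TRUE, rep(FALSE, 5)))
  expect_equal(r1$rotmat, diag(1))
})

test_that("Kaiser rule keeps axes with eigenvalue above one", {
  expect_equal(kaiser_retain(c(2.1, 1.3, 0.4)), c(TRUE, TRUE, FALSE))
  expect_warning(flags <- kaiser_retain(c(0.9, 0.5)), "no axis")
  expect_false(any(flags))
})

test_that("mass correction residualizes and is idempotent", {
  set.seed(61)
  mass <- 10^runif(50, 1, 6)
  X <- scale(cbind(3 * log10(mass) + rnorm(50, 0, 0.2), rnorm(50)))
  Xc <- mass_correct(X, mass)
  expect_equal(unname(apply(Xc, 2, mean)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(Xc, 2, sd)), c(1, 1), tolerance = 1e-10)
  # residuals orthogonal to the predictor
  expect_lt(max(abs(cor(Xc, log10(mass)))), 1e-10)
  # idempotence
  expect_equal(mass_correct(Xc, mass), Xc, tolerance = 1e-8)
  # an exactly linear trait is annihilated (degenerate scale -> NaN guard)
  Xlin <- cbind(2 * log10(mass), rnorm(50))
  res <- apply(Xlin, 2, function(x) residuals(lm(x ~ log10(mass))))
  expect_lt(max(abs(res[, 1])), 1e-10)
  expect_error(mass_correct(X, rep(2, 50)), "constant mass")
})

test_that("feeding-level correlation matches the textbook formula", {
  f <- c(0.6, 0.6, 0.9)
  s <- c(1, 2, 0)
  out <- feeding_correlation(s, f)
  r_hand <- sum((f - mean(f)) * (s - mean(s))) /
    sqrt(sum((f - mean(f))^2) * sum((s - mean(s))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$df, 1)
  # exact linear relation with negative slope
  f2 <- c(0.6, 0.7, 0.8, 0.9)
  out2 <- feeding_correlation(-2 * f2, f2)
  expect_equal(out2$r, -1, tolerance = 1e-12)
  expect_error(feeding_correlation(rep(1, 4), f2), "zero variance")
})

test_that("trait matrix preparation standardizes and handles zeros", {
  tt <- trait_table(sample_deb_params(12, seed = 71), feeding_levels = 0.9,
                    n_bins = 80)
  prep <- prepare_trait_matrix(tt[tt$persistent, ])
  expect_equal(unname(colMeans(prep$X)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(apply(prep$X, 2, sd)), rep(1, 8), tolerance = 1e-9)
  expect_false(any(is.na(prep$X)))
})
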