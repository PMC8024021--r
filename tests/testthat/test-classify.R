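two_clouds <- function(n_per = 10, p = 8, delta = 10, seed = 31) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p), n_per, p),
             matrix(rnorm(n_per * p, delta), n_per, p))
  colnames(x) <- paste0("g", seq_len(p))
  list(x = x, y = factor(rep(c("w", "e"), each = n_per)))
}

test_that("plsda_separation separates well-split clouds and not null data", {
  cl <- two_clouds()
  fit <- plsda_separation(cl$x, cl$y)
  expect_true(fit$perfectly_separated)
  expect_equal(dim(fit$scores), c(20, 2))
  expect_length(fit$explained_variance, 2)
  # duplicated features: identical latent directions up to sign
  dup <- cbind(cl$x, cl$x)
  colnames(dup) <- c(colnames(cl$x), paste0(colnames(cl$x), ".copy"))
  fit2 <- plsda_separation(dup, cl$y)
  expect_equal(abs(cor(fit$scores[, 1], fit2$scores[, 1])), 1,
               tolerance = 1e-6)
  # label permutation destroys separability in nearly all draws (at a
  # sane sample-to-feature ratio; PLS-DA is known to overfit when the
  # feature count approaches the sample count)
  set.seed(32)
  noise <- matrix(rnorm(24 * 8), 24, 8,
                  dimnames = list(NULL, paste0("g", 1:8)))
  sep <- vapply(1:20, function(i)
    plsda_separation(noise, sample(rep(c("a", "b"), 12)))$perfectly_separated,
    logical(1))
  expect_lt(mean(sep), 0.25)
  expect_error(plsda_separation(cl$x, rep("e", 20)), "two classes")
})

test_that("the convex-hull separability test is exact in easy cases", {
  A <- cbind(c(0, 1, 0), c(0, 0, 1))
  B <- A + 5
  expect_true(hypernet:::linearly_separable(A, B))
  expect_false(hypernet:::linearly_separable(A, A + 0.1))
  # collinear degenerate hulls
  expect_true(hypernet:::linearly_separable(cbind(0:1, 0:1),
                                            cbind(3:4, 3:4)))
  expect_false(hypernet:::linearly_separable(cbind(c(0, 2), c(0, 2)),
                                             cbind(c(1, 3), c(1, 3))))
  # 1D intervals
  expect_true(hypernet:::linearly_separable(cbind(1:3), cbind(5:6)))
  expect_false(hypernet:::linearly_separable(cbind(1:3), cbind(2:5)))
})

test_that("rf_oob_auc is perfect on a label-identical feature and null on noise", {
  set.seed(33)
  y <- factor(rep(c("w", "e"), each = 12))
  x <- cbind(lab = as.numeric(y), matrix(rnorm(24 * 5), 24, 5))
  colnames(x) <- c("lab", paste0("n", 1:5))
  rep1 <- rf_oob_auc(x, y, n_trees = 300, seed = 1)
  expect_equal(rep1$oob_auc, 1.0)
  expect_equal(rep1$oob_error_rate, 0)
  # deterministic under a fixed seed
  rep2 <- rf_oob_auc(x, y, n_trees = 300, seed = 1)
  expect_identical(rep1$oob_auc, rep2$oob_auc)
  expect_identical(rep1$votes, rep2$votes)
  # permuting samples together with labels changes nothing
  perm <- sample(24)
  rep3 <- rf_oob_auc(x[perm, ], y[perm], n_trees = 300, seed = 1)
  expect_equal(rep3$oob_auc, rep1$oob_auc)
  # pure-noise AUC hovers around 0.5
  aucs <- vapply(1:10, function(s) {
    set.seed(40 + s)
    xn <- matrix(rnorm(40 * 10), 40, 10)
    rf_oob_auc(xn, factor(rep(c("w", "e"), 20)), n_trees = 300,
               seed = s)$oob_auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the rank AUC equals an independent ROC integration", {
  skip_if_not_installed("pROC")
  set.seed(34)
  scores <- rnorm(30)
  pos <- rep(c(TRUE, FALSE), 15)
  got <- hypernet:::auc_from_scores(scores, pos)
  want <- as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("shadow_select confirms a perfect predictor and rejects noise", {
  set.seed(35)
  y <- factor(rep(c("w", "e"), each = 10))
  x <- cbind(sig = as.numeric(y) + rnorm(20, sd = 0.05),
             matrix(rnorm(20 * 15), 20, 15))
  colnames(x) <- c("sig", paste0("noise", 1:15))
  sel <- shadow_select(x, y, n_iterations = 25, n_trees = 150, seed = 2)
  expect_equal(unname(as.character(sel$status["sig"])), "confirmed")
  expect_gte(mean(sel$status[-1] == "rejected"), 0.8)
  expect_true("sig" %in% sel$selected)
  expect_equal(dim(sel$importance_history), c(25, 16))
})

test_that("direction_consistent filters by shared fold-change sign", {
  dA <- data.frame(feature_id = c("pb_g1", "pb_g2", "pb_g3"),
                   log2fc = c(1, 1, -2), q = c(0.01, 0.2, 0.01),
                   direction = c(1, 1, -1))
  dB <- data.frame(feature_id = c("ad_g1", "ad_g2", "ad_g3"),
                   log2fc = c(0.2, -1, -0.5), q = c(0.04, 0.7, 0.3),
                   direction = c(1, -1, -1))
  expect_equal(direction_consistent(dA, dB, c("pb_g1", "pb_g2", "pb_g3")),
               c("pb_g1", "pb_g3"))
  expect_equal(direction_consistent(dA, dB, "pb_g1",
                                    require_significant = TRUE), "pb_g1")
  expect_equal(direction_consistent(dA, dB, "pb_g3",
                                    require_significant = TRUE),
               character(0))
  expect_error(direction_consistent(dA, dB, "pb_g9"), "pb_g9")
  # brute-force oracle on random signs
  set.seed(36)
  n <- 40
  dA2 <- data.frame(feature_id = paste0("x_", 1:n),
                    log2fc = rnorm(n), q = runif(n))
  dA2$direction <- sign(dA2$log2fc)
  dB2 <- data.frame(feature_id = paste0("y_", 1:n),
                    log2fc = rnorm(n), q = runif(n))
  dB2$direction <- sign(dB2$log2fc)
  got <- direction_consistent(dA2, dB2, dA2$feature_id)
  want <- dA2$feature_id[dA2$direction == dB2$direction]
  expect_equal(got, want)
})

test_that("external_validate reports coverage and discriminates", {
  cl <- two_clouds(n_per = 12, p = 10, delta = 6, seed = 37)
  rep1 <- external_validate(paste0("g", 1:10), cl$x, cl$y, n_trees = 300,
                            seed = 3)
  expect_gte(rep1$oob_auc, 0.95)
  expect_equal(rep1$coverage, 1)
  # partial coverage above the floor is allowed and reported
  rep2 <- external_validate(c(paste0("g", 1:6), "absent1", "absent2"),
                            cl$x, cl$y, n_trees = 300, seed = 3)
  expect_equal(rep2$coverage, 0.75)
  expect_error(external_validate(c(paste0("g", 1:2), paste0("zz", 1:8)),
                                 cl$x, cl$y), "50%")
  expect_error(external_validate("zz", cl$x, cl$y), "no gene-set")
  # a noise gene set stays near chance
  set.seed(38)
  xn <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("g", 1:8)))
  repn <- external_validate(paste0("g", 1:8), xn,
                            factor(rep(c("w", "e"), 20)), n_trees = 500,
                            seed = 4)
  expect_lt(abs(repn$oob_auc - 0.5), 0.25)
})
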