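named_mat <- function(m, n, prefix = c("a", "b"), data = NULL) {
  v <- if (is.null(data)) matrix(rnorm(m * n), m, n) else data
  dimnames(v) <- list(paste0(prefix[1], seq_len(m)),
                      paste0("s", seq_len(n)))
  v
}

test_that("correlation_matrix matches the closed-form covariance formula", {
  set.seed(11)
  a <- named_mat(20, 9, "a")
  b <- named_mat(50, 9, "b")
  R <- correlation_matrix(a, b)
  # element-wise oracle: cov(x, y) / (sd(x) sd(y))
  for (idx in list(c(1, 1), c(7, 23), c(20, 50))) {
    x <- a[idx[1], ]; y <- b[idx[2], ]
    expect_equal(R$r[idx[1], idx[2]],
                 sum((x - mean(x)) * (y - mean(y))) / 8 / (sd(x) * sd(y)),
                 tolerance = 1e-12)
  }
  expect_equal(R$r_mean, mean(R$r))
  # self-correlation 1, negation -1
  Rs <- correlation_matrix(a[1:2, ], rbind(a[1:2, ], -a[1, , drop = FALSE]))
  expect_equal(unname(diag(Rs$r[, 1:2])), c(1, 1))
  expect_equal(unname(Rs$r[1, 3]), -1)
  # zero-variance vectors are flagged and set to r = 0
  a0 <- a; a0[3, ] <- 5
  expect_warning(R0 <- correlation_matrix(a0, b), "zero-variance")
  expect_equal(unname(R0$r[3, ]), rep(0, 50))
  expect_error(correlation_matrix(a[, 1:2], b[, 1:2]), "at least 3")
})

test_that("dichotomize applies the standardized-deviation rule", {
  set.seed(12)
  R <- correlation_matrix(named_mat(15, 8, "a"), named_mat(40, 8, "b"))
  M <- dichotomize(R, 1.5)
  expect_equal(M$M, (abs(R$r - mean(R$r)) >= 1.5 * sd(R$r)) * 1L)
  # z = (-2, 0, +2) at k = 1.5 -> (1, 0, 1) is forced by the rule
  z <- R$r_mean + c(-2, 0, 2) * R$r_sd
  Rz <- R; Rz$r[1, 1:3] <- z
  expect_equal(unname(dichotomize(Rz, 1.5)$M[1, 1:3]), c(1L, 0L, 1L))
  # raising k never turns a 0 into a 1
  for (k in c(0.5, 1, 2, 2.5)) {
    M2 <- dichotomize(R, k)$M
    if (k > 1.5) expect_true(all(M2 <= M$M)) else expect_true(all(M2 >= M$M))
  }
  Rflat <- R; Rflat$r[] <- 0.2; Rflat$r_sd <- 0
  expect_error(dichotomize(Rflat, 1.5), "degenerate")
})

test_that("adjacency equals brute-force shared-column counting", {
  M <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  colnames(M) <- paste0("c", 1:3)
  H <- adjacency(M)
  expect_equal(H$sM["a", "b"], 1L)
  I5 <- diag(5); dimnames(I5) <- list(letters[1:5], letters[1:5])
  expect_equal(unname(adjacency(I5)$sM), unname(diag(5L)))
  set.seed(13)
  for (i in 1:20) {
    m <- sample(3:15, 1); n <- sample(5:25, 1)
    Mi <- matrix(rbinom(m * n, 1, runif(1, 0.2, 0.7)), m, n,
                 dimnames = list(paste0("r", 1:m), paste0("c", 1:n)))
    H <- adjacency(Mi)
    expect_identical(H$sM, adjacency_brute(Mi))
    # structural invariants: symmetry, degree diagonal, pairwise bound
    expect_identical(H$sM, t(H$sM))
    expect_equal(unname(diag(H$sM)), unname(rowSums(Mi)))
    bound <- outer(diag(H$sM), diag(H$sM), pmin)
    expect_true(all(H$sM <= bound))
  }
})

test_that("chi2_signal matches hand arithmetic in both expectation modes", {
  s1 <- matrix(c(4L, 0L, 0L, 4L), 2, 2)
  expect_equal(chi2_signal(s1, "mean_element")$chi2, 8)   # m_e = 2
  expect_equal(chi2_signal(s1, "literal")$m_e, 4)
  s2 <- matrix(c(3L, 1L, 1L, 3L), 2, 2)
  expect_equal(chi2_signal(s2, "mean_element")$chi2, 2)   # m_e = 2
  expect_equal(chi2_signal(s2, "literal")$chi2, 5)        # m_e = 4
  expect_equal(chi2_signal(matrix(2L, 3, 3), "mean_element")$chi2, 0)
  # linear scaling: chi2(c * sM) = c * chi2(sM), both modes
  set.seed(14)
  s3 <- matrix(rpois(36, 5), 6, 6); s3 <- s3 + t(s3)
  for (mode in c("mean_element", "literal"))
    expect_equal(chi2_signal(3 * s3, mode)$chi2,
                 3 * chi2_signal(s3, mode)$chi2)
  expect_error(chi2_signal(matrix(0L, 2, 2)), "no signal")
})

test_that("threshold_sweep maximizes the chi-squared window", {
  set.seed(15)
  R <- correlation_matrix(named_mat(15, 8, "a"), named_mat(60, 8, "b"))
  one <- threshold_sweep(R, 1.5)
  expect_equal(one$best_k, 1.5)
  # ties break toward the smaller k (duplicated grid value)
  tie <- threshold_sweep(R, c(1.2, 1.2))
  expect_equal(tie$best_k, 1.2)
  # planted block structure: the window peaks at an interior grid point
  interior <- vapply(1:10, function(seed) {
    cfg <- sim_config(layer_dims = c(a = 150, b = 150),
                      n_responsive = c(a = 60, b = 60),
                      latent_members = c(a = 30, b = 30), seed = seed)
    sim <- generate_study(cfg)
    D <- lapply(sim$study, paired_difference, design = sim$design)
    dr <- paired_t_test(sim$study$a, sim$design)
    R <- correlation_matrix(D$a[dr$feature_id[dr$p < 0.05], ], D$b)
    grid <- seq(0.5, 3, by = 0.5)
    sw <- threshold_sweep(R, grid)
    sw$best_k > min(grid) && sw$best_k < max(grid)
  }, logical(1))
  expect_gte(mean(interior), 0.8)
})

test_that("central_cluster pulls out a planted dense block", {
  # block-diagonal sM: a dense block of 6 (shared edges 10) in noise-free
  # surroundings is returned exactly
  M <- matrix(0L, 12, 20, dimnames = list(paste0("n", 1:12), paste0("c", 1:20)))
  M[1:6, 1:10] <- 1L
  M[cbind(7:12, 11:16)] <- 1L
  H <- adjacency(M)
  cl <- central_cluster(H, min_size = 4)
  expect_setequal(cl$members, paste0("n", 1:6))
  expect_gte(cl$connectivity, cl$overall_connectivity)
  # permuting node order leaves the member set unchanged
  set.seed(16)
  perm <- sample(12)
  clp <- central_cluster(adjacency(M[perm, ]), min_size = 4)
  expect_setequal(clp$members, cl$members)
  expect_error(central_cluster(adjacency(M[1:3, ])), "at least 4")
})

test_that("dissimilarity robustness eliminates complement-pattern features only", {
  M <- robustness_fixture()
  H <- adjacency(M)
  cl <- central_cluster(H, min_size = 5)
  expect_true(all(paste0("planted", 1:10) %in% cl$members))
  rob <- dissimilarity_robust(M, cl, min_size = 5)
  expect_setequal(rob$eliminated, paste0("comp", 1:5))
  expect_setequal(rob$robust, paste0("planted", 1:10))
  # M all ones: complement carries nothing, no eliminations
  M1 <- matrix(1L, 8, 10, dimnames = list(paste0("n", 1:8), paste0("c", 1:10)))
  rob1 <- dissimilarity_robust(M1, paste0("n", 1:8), min_size = 4)
  expect_length(rob1$eliminated, 0)
  expect_setequal(rob1$robust, paste0("n", 1:8))
})

test_that("layer_overlap reproduces brute-force Venn counts", {
  sets <- list(x = c("a", "b", "c"), y = c("b", "c", "d"), z = c("c", "e"))
  ov <- layer_overlap(sets)
  expect_equal(unname(ov$sizes), c(3L, 3L, 2L))
  want <- c("x&y" = 2L, "x&z" = 1L, "y&z" = 1L, "x&y&z" = 1L)
  expect_equal(setNames(ov$overlaps$n, ov$overlaps$sets), want)
  ident <- layer_overlap(list(p = c("a", "b"), q = c("a", "b")))
  expect_equal(ident$overlaps$n, 2L)
  disj <- layer_overlap(list(p = "a", q = "b", r = "c"))
  expect_true(all(disj$overlaps$n == 0))
  set.seed(17)
  rnd <- lapply(1:3, function(i) sample(letters, 10))
  names(rnd) <- c("u", "v", "w")
  ov2 <- layer_overlap(rnd)
  expect_equal(ov2$overlaps$n[ov2$overlaps$sets == "u&v"],
               sum(rnd$u %in% rnd$v))
})

test_that("centrality_rank matches power iteration and handles ties", {
  # star: hub shares edges with every leaf, leaves share none
  M <- rbind(hub = rep(1L, 8),
             diag(1L, 4, 8))
  rownames(M) <- c("hub", paste0("leaf", 1:4))
  colnames(M) <- paste0("c", 1:8)
  H <- adjacency(M)
  expect_equal(centrality_rank(H)$node_id[1], "hub")
  # complete graph: all tied, ranked by node ID
  K <- matrix(1L, 5, 12, dimnames = list(paste0("n", 1:5), paste0("c", 1:12)))
  ranks <- centrality_rank(adjacency(K))
  expect_equal(ranks$node_id, paste0("n", 1:5))
  expect_equal(ranks$score, rep(1, 5))
  # random graph vs power-iteration oracle
  set.seed(18)
  Mr <- matrix(rbinom(15 * 30, 1, 0.4), 15, 30,
               dimnames = list(paste0("n", 1:15), paste0("c", 1:30)))
  Hr <- adjacency(Mr)
  got <- centrality_rank(Hr)
  want <- power_iteration_centrality(Hr$sM)
  expect_equal(got$score, unname(want[match(got$node_id, Hr$node_ids)]),
               tolerance = 1e-8)
  Z <- diag(1L, 4, 6)
  dimnames(Z) <- list(paste0("n", 1:4), paste0("c", 1:6))
  expect_error(centrality_rank(adjacency(Z)), "centrality undefined")
})

test_that("hypernetwork object prints, summarizes and exposes metadata", {
  set.seed(19)
  hn <- hypernetwork(named_mat(12, 9, "a"), named_mat(30, 9, "b"), k = 1.5)
  expect_s3_class(hn, "hypernetwork")
  expect_equal(hn$threshold_k, 1.5)
  expect_equal(hn$N, 12)
  expect_output(print(hn), "12 nodes")
  expect_output(print(summary(hn)), "Chi-squared")
})
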