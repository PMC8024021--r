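# Independent oracles and shared fixtures, deliberately brute-force.

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (R's exact convention: twice the smaller tail, capped at 1).
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  v_all <- as.vector(signs %*% r)
  v <- sum(r[d > 0])
  min(1, 2 * min(mean(v_all <= v), mean(v_all >= v)))
}

# Exact two-sided rank-sum p by enumeration of all C(n+m, n) labelings.
rank_sum_exact_p <- function(a, b) {
  pool <- c(a, b)
  r <- rank(pool)
  na <- length(a)
  combos <- utils::combn(length(pool), na)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - na * (na + 1) / 2
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(w_all <= w), mean(w_all >= w)))
}

# Shared-edge counting by explicit pairwise column intersection.
adjacency_brute <- function(M) {
  m <- nrow(M)
  out <- matrix(0L, m, m, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(m)) for (j in seq_len(m))
    out[i, j] <- sum(M[i, ] == 1 & M[j, ] == 1)
  out
}

# Power-iteration eigenvector centrality (max-normalized).
power_iteration_centrality <- function(A, iters = 2000) {
  diag(A) <- 0
  v <- rep(1, nrow(A))
  for (i in seq_len(iters)) {
    v <- A %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- abs(as.vector(v))
  v / max(v)
}

# Small-scale study dimensions used throughout the suite.
test_dims <- c(pbmc = 400, adipose = 400, mirna = 100, metabolome = 80)

# Incidence fixture for the robustness filter: a planted dense block with
# diverse zeros, complement-pattern rows (incident on the block only, so
# their zeros align), and unrelated sparse rows.
robustness_fixture <- function() {
  set.seed(99)
  n <- 60
  S <- 1:20
  A <- t(sapply(1:10, function(i) {
    r <- integer(n); r[S] <- 1L; r[sample(21:n, 20)] <- 1L; r
  }))
  C <- t(sapply(1:5, function(i) { r <- integer(n); r[S] <- 1L; r }))
  D <- t(sapply(1:5, function(i) {
    r <- integer(n); r[sample(n, 12)] <- 1L; r
  }))
  M <- rbind(A, C, D)
  rownames(M) <- c(paste0("planted", 1:10), paste0("comp", 1:5),
                   paste0("noise", 1:5))
  colnames(M) <- paste0("bg", seq_len(n))
  M
}

# Latent-member recovery of the central cluster for one simulated study:
# anchors are the raw-p DE features of the anchor layer, the background is
# every element called present, pooled over layers.
recovery_one_seed <- function(seed, dims = test_dims, latent_loading = 0.8) {
  cfg <- sim_config(layer_dims = dims, latent_loading = latent_loading,
                    seed = seed)
  sim <- generate_study(cfg)
  D <- lapply(sim$study, paired_difference, design = sim$design)
  dr <- paired_t_test(sim$study$pbmc, sim$design)
  anchor_ids <- dr$feature_id[dr$p < 0.05]
  mem <- sim$truth$factor_members[[1]]
  mem_pbmc <- mem$feature_id[mem$layer == "pbmc"]
  mem_in_anchor <- intersect(mem_pbmc, anchor_ids)
  hn <- hypernetwork(D$pbmc[anchor_ids, , drop = FALSE], do.call(rbind, D),
                     k = 1.5)
  cl <- tryCatch(central_cluster(hn), error = function(e) NULL)
  if (is.null(cl))
    return(c(sens = NA, contam = NA, excess_frac = NA))
  c(sens = length(intersect(cl$members, mem_in_anchor)) /
      length(mem_in_anchor),
    contam = length(setdiff(cl$members, mem_pbmc)) / length(cl$members),
    excess_frac = length(intersect(cl$members, mem_in_anchor)) /
      length(mem_in_anchor) - length(cl$members) / hn$N)
}
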