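ref_state <- function(M, N, seed = 7) {
  b <- build_sector_basis(M, N_sys = N)
  set.seed(seed)
  state_vector(b, rnorm(b$dim), normalize = TRUE)
}

test_that("RDM traces equal the normalization p! C(N, p)", {
  for (cfg in list(c(6L, 3L), c(6L, 4L), c(8L, 4L))) {
    psi <- ref_state(cfg[1], cfg[2])
    g1 <- compute_rdm(psi, 1L)
    g2 <- compute_rdm(psi, 2L)
    expect_equal(Re(sum(diag(g1$matrix))), cfg[2], tolerance = 1e-12)
    expect_equal(Re(sum(diag(g2$matrix))), 2 * choose(cfg[2], 2),
                 tolerance = 1e-12)
  }
})

test_that("1-RDM entries are bare expectations <a_i^+ a_k>", {
  psi <- ref_state(6L, 3L)
  g1 <- compute_rdm(psi, 1L)
  for (i in 1:6) for (k in 1:6) {
    ref <- sum(psi$amplitudes *
               as.numeric(one_body_matrix(psi$basis, i, k) %*% psi$amplitudes))
    expect_equal(Re(g1$matrix[i, k]), ref, tolerance = 1e-12)
  }
})

test_that("2-RDM entries are bare expectations <a_i^+ a_j^+ a_l a_k>", {
  psi <- ref_state(6L, 3L)
  g2 <- compute_rdm(psi, 2L)
  M <- 6L
  idx <- function(i, j) (i - 1L) * M + j
  set.seed(21)
  for (trial in 1:12) {
    v <- sample(M, 4, replace = TRUE)
    i <- v[1]; j <- v[2]; k <- v[3]; l <- v[4]
    # element [(ij),(kl)] = <a_i^+ a_j^+ a_l a_k>
    ref <- sum(psi$amplitudes *
               as.numeric(two_body_matrix(psi$basis, i, j, l, k) %*%
                          psi$amplitudes))
    expect_equal(Re(g2$matrix[idx(i, j), idx(k, l)]), ref, tolerance = 1e-12)
  }
})

test_that("contracting the 2-RDM reproduces the 1-RDM", {
  for (cfg in list(c(6L, 3L), c(6L, 4L), c(8L, 4L))) {
    psi <- ref_state(cfg[1], cfg[2])
    g1 <- compute_rdm(psi, 1L)
    g2 <- compute_rdm(psi, 2L)
    tr <- contract_2rdm(g2)
    expect_equal(as.matrix(tr$matrix), as.matrix(g1$matrix), tolerance = 1e-10)
  }
})

test_that("hs_distance_sq is the squared Frobenius distance and is symmetric", {
  psi <- ref_state(6L, 4L, seed = 1)
  phi <- ref_state(6L, 4L, seed = 2)
  a <- compute_rdm(psi, 1L); b <- compute_rdm(phi, 1L)
  d <- hs_distance_sq(a, b)
  expect_equal(d, sum(Mod(a$matrix - b$matrix)^2), tolerance = 1e-12)
  expect_equal(d, hs_distance_sq(b, a), tolerance = 1e-12)
  expect_equal(hs_distance_sq(a, a), 0)
})

test_that("RDM gradient matches finite differences of the distance", {
  psi <- ref_state(6L, 4L, seed = 5)
  target <- compute_rdm(ref_state(6L, 4L, seed = 6), 1L)
  gs <- rdm_gradient_state(psi, target)
  pool <- build_pool(psi$basis, pool_config())
  h <- 1e-6
  set.seed(8)
  for (op in pool[sample(length(pool), 6)]) {
    g_an <- 4 * sum(gs * as.numeric(op$matrix %*% psi$amplitudes))
    dp <- compute_rdm(apply_exponential(op, h, psi), target$p)
    dm <- compute_rdm(apply_exponential(op, -h, psi), target$p)
    g_fd <- (hs_distance_sq(dp, target) - hs_distance_sq(dm, target)) / (2 * h)
    expect_equal(g_an, g_fd, tolerance = 1e-6)
  }
})

test_that("RDM file round-trip is exact to write precision", {
  psi <- ref_state(6L, 3L)
  g <- compute_rdm(psi, 2L)
  f <- tempfile(fileext = ".rdm")
  write_rdm(g, f)
  back <- read_rdm(f)
  expect_equal(back$p, g$p)
  expect_equal(back$M_sys, g$M_sys)
  expect_equal(back$N, g$N)
  expect_equal(as.matrix(back$matrix), as.matrix(g$matrix), tolerance = 1e-12)
  unlink(f)
})

test_that("add_noise is deterministic per seed and scales with eps", {
  psi <- ref_state(6L, 4L)
  g <- compute_rdm(psi, 1L)
  n1 <- add_noise(g, 1e-2, seed = 42L)
  n2 <- add_noise(g, 1e-2, seed = 42L)
  n3 <- add_noise(g, 1e-2, seed = 43L)
  expect_equal(as.matrix(n1$matrix), as.matrix(n2$matrix))
  expect_false(isTRUE(all.equal(as.matrix(n1$matrix), as.matrix(n3$matrix))))
  dev <- max(abs(as.matrix(n1$matrix - g$matrix)))
  expect_lte(dev, 1e-2)
  expect_gt(dev, 1e-3)
  # eps = 0 leaves the matrix untouched
  n0 <- add_noise(g, 0, seed = 42L)
  expect_equal(as.matrix(n0$matrix), as.matrix(g$matrix))
  # global RNG state is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(add_noise(g, 1e-2, seed = 9L)); after <- rnorm(1)
  expect_equal(before, after)
})
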