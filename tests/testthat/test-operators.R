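# Oracle checks of the second-quantized operator algebra against independent
# constructions.

test_that("one_body_matrix equals t(A_i) %*% A_k built from annihilation maps", {
  b <- build_sector_basis(6L, N_sys = 3L)
  for (i in 1:6) for (k in 1:6) {
    Ai <- annihilation_map(b, i)
    Ak <- annihilation_map(b, k)
    ref <- Matrix::t(Ai) %*% Ak
    expect_equal(as.matrix(one_body_matrix(b, i, k)), as.matrix(ref),
                 tolerance = 1e-14)
  }
})

test_that("two_body_matrix matches the composed annihilation-map construction", {
  b <- build_sector_basis(6L, N_sys = 3L)
  # a_i^+ a_j^+ a_k a_l = t(A_i^{N-1}) t(A_j^{N-2}) A_k^{N-2} A_l^{N-1}
  for (trial in list(c(1L, 2L, 3L, 4L), c(2L, 5L, 1L, 6L), c(1L, 3L, 3L, 1L),
                     c(4L, 6L, 2L, 5L), c(1L, 2L, 2L, 1L))) {
    i <- trial[1]; j <- trial[2]; k <- trial[3]; l <- trial[4]
    Al <- annihilation_map(b, l); tl <- annihilation_target(b, l)
    Ak <- annihilation_map(tl, k); tk <- annihilation_target(tl, k)
    Aj <- annihilation_map(tl, j)
    Ai <- annihilation_map(b, i); ti <- annihilation_target(b, i)
    Aj2 <- annihilation_map(ti, j)
    ref <- Matrix::t(Ai) %*% Matrix::t(Aj2) %*% Ak %*% Al
    expect_equal(as.matrix(two_body_matrix(b, i, j, k, l)), as.matrix(ref),
                 tolerance = 1e-14)
  }
})

test_that("fermionic anticommutation {a_i, a_j^+} = delta_ij holds on the sector", {
  b <- build_sector_basis(4L, N_sys = 2L)
  bp <- build_sector_basis(4L, N_sys = 3L)
  for (i in 1:4) for (j in 1:4) {
    Ai <- annihilation_map(b, i)             # N -> N-1
    Aj <- annihilation_map(b, j)
    Aip <- annihilation_map(bp, i)           # N+1 -> N
    Ajp <- annihilation_map(bp, j)
    # a_j a_i^+ (through the N+1 sector) + a_i^+ a_j (through N-1)
    s <- as.matrix(Ajp %*% Matrix::t(Aip)) + as.matrix(Matrix::t(Ai) %*% Aj)
    expect_equal(s, diag(as.numeric(i == j), b$dim), tolerance = 1e-14)
  }
})

test_that("pool generators satisfy O^3 = -O and the closed-form exponential", {
  b <- build_sector_basis(6L, N_sys = 4L)
  pool <- build_pool(b, pool_config())
  set.seed(3)
  for (op in pool[sample(length(pool), 5)]) {
    O <- op$matrix
    expect_equal(as.matrix(O %*% O %*% O), as.matrix(-O), tolerance = 1e-13)
    expect_equal(as.matrix(Matrix::t(O)), as.matrix(-O), tolerance = 1e-14)
    theta <- 0.731
    a <- rnorm(b$dim); a <- a / sqrt(sum(a^2))
    ref <- as.numeric(Matrix::expm(theta * O) %*% a)
    expect_equal(exp_apply(O, theta, a), ref, tolerance = 1e-12)
    # unitarity
    expect_equal(sum(exp_apply(O, theta, a)^2), 1, tolerance = 1e-13)
  }
})

test_that("apply_exponential rejects non-finite angles", {
  b <- build_sector_basis(4L, N_sys = 2L)
  pool <- build_pool(b, pool_config())
  psi <- slater_determinant(b, c("1a", "1b"))
  expect_error(apply_exponential(pool[[1]], NaN, psi), "non-finite")
})
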