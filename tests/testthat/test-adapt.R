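# Engine-level tests: analytic gradients, convergence behavior, and a
# brute-force variational oracle on the smallest nontrivial system.

test_that("ansatz parameter gradients match finite differences", {
  b <- build_sector_basis(6L, N_sys = 4L)
  pool <- build_pool(b, pool_config())
  psi0 <- slater_determinant(b, c("1a", "1b", "2a", "2b"))
  d <- model_determinants()$sys_4e3o
  target <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0.5), 2L, 6L)
  set.seed(9)
  ops <- pool[sample(length(pool), 4)]
  ops <- c(ops, ops[2])               # repeated operator exercises the adjoint
  obj <- ensrep:::.ansatz_objective(psi0, ops, target)
  thetas <- c(0.3, -0.7, 0.25, 0.9, -0.4)
  g_an <- obj$gr(thetas)
  h <- 1e-6
  for (m in seq_along(thetas)) {
    tp <- thetas; tp[m] <- tp[m] + h
    tm <- thetas; tm[m] <- tm[m] - h
    g_fd <- (obj$fn(tp) - obj$fn(tm)) / (2 * h)
    expect_equal(g_an[m], g_fd, tolerance = 1e-6)
  }
})

test_that("a representable target from the initial state converges at iteration 0", {
  d <- model_determinants()$sys_4e3o
  target <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0), 1L, d$M_sys)
  psi0 <- initial_state("pure", d$occ1, d$M_sys)
  pool <- build_pool(psi0$basis, pool_config())
  res <- adapt_run(psi0, target, pool, adapt_settings())
  expect_equal(res$d_min, 0, tolerance = 1e-12)
  expect_equal(length(res$operators), 0L)
  expect_true(res$converged)
})

brute_force_min <- function(target, basis, n_tries = 8) {
  best <- Inf
  for (s in seq_len(n_tries)) {
    set.seed(100 + s)
    x0 <- rnorm(basis$dim)
    fn <- function(x) {
      psi <- state_vector(basis, x, normalize = TRUE)
      hs_distance_sq(compute_rdm(psi, target$p), target)
    }
    o <- stats::optim(x0, fn, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

test_that("ADAPT matches a brute-force variational oracle on (2e, 2o)", {
  # mixture of |1a 1b> and |2a 2b> in 4 spin-orbitals
  for (w in c(0.5, 0.25)) {
    for (p in 1:2) {
      spec <- two_state_mixture(c("1a", "1b"), c("2a", "2b"), w)
      target <- mixture_target(spec, p, 4L)
      psi0 <- initial_state("pure", c("1a", "1b"), 4L)
      pool <- build_pool(psi0$basis, pool_config())
      res <- adapt_run(psi0, target, pool, adapt_settings())
      oracle <- brute_force_min(target, psi0$basis)
      expect_lte(res$d_min, oracle + 1e-6)
      expect_gte(res$d_min, oracle - 1e-6)
    }
  }
})

test_that("ensemble minimum never exceeds the pure minimum", {
  d <- model_determinants()$sys_4e3o
  for (p in 1:2) {
    target <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0.5), p, d$M_sys)
    pure0 <- initial_state("pure", d$occ1, d$M_sys)
    ens0 <- initial_state("ensemble", d$occ1, d$M_sys)
    rp <- adapt_run(pure0, target, build_pool(pure0$basis, pool_config()),
                    adapt_settings())
    re <- adapt_run(ens0, target, build_pool(ens0$basis, pool_config()),
                    adapt_settings())
    expect_lte(re$d_min, rp$d_min + 1e-8)
  }
})

test_that("trace of the evolved RDM is conserved along the run", {
  d <- model_determinants()$sys_4e3o
  target <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0.5), 2L, d$M_sys)
  psi0 <- initial_state("pure", d$occ1, d$M_sys)
  res <- adapt_run(psi0, target, build_pool(psi0$basis, pool_config()),
                   adapt_settings())
  expect_equal(Re(sum(diag(res$evolved_rdm$matrix))), 2 * choose(4, 2),
               tolerance = 1e-10)
  # distances in the trace are monotone non-increasing
  expect_true(all(diff(res$trace$distance) <= 1e-12))
})

test_that("classify_rdm distinguishes pure, ensemble-only and unrepresentable", {
  d <- model_determinants()$sys_4e3o
  # w = 0.5 1-RDM mixture on (4e,3o) is pure-representable
  t_pure <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0.5), 1L, d$M_sys)
  c_pure <- classify_rdm(t_pure, d$occ1)
  expect_equal(c_pure$classification, "pure")
  # its noisy version is not representable at all
  t_bad <- add_noise(t_pure, 0.3, seed = 5L)
  c_bad <- classify_rdm(t_bad, d$occ1,
                        settings = adapt_settings(delta = 3e-5,
                                                  zero_threshold = 3e-5))
  expect_equal(c_bad$classification, "not_representable")
  expect_s3_class(c_bad$nearest_rdm, "rdm")
})
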