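test_that("two_state_mixture weights follow the admixture convention", {
  d <- model_determinants()$sys_4e3o
  s0 <- two_state_mixture(d$occ1, d$occ2, 0)
  expect_equal(vapply(s0$components, `[[`, numeric(1), "weight"), c(1, 0))
  s5 <- two_state_mixture(d$occ1, d$occ2, 0.5)
  expect_equal(vapply(s5$components, `[[`, numeric(1), "weight"), c(0.5, 0.5))
  expect_error(two_state_mixture(d$occ1, d$occ2, 1.3), "\\[0, 1\\]")
})

test_that("mixture 1-RDM target of the half mixture has the published spectrum", {
  d <- model_determinants()$sub1
  tgt <- mixture_target(two_state_mixture(d$occ1, d$occ2, 0.5), 1L, d$M_sys)
  ev <- sort(Re(eigen(as.matrix(tgt$matrix), symmetric = TRUE,
                      only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(ev, c(1, 1, 1, 0.5, 0.5, 0, 0, 0), tolerance = 1e-12)
})

test_that("mixture target is the weighted sum of determinant RDMs", {
  d <- model_determinants()$sys_4e3o
  b <- build_sector_basis(d$M_sys, N_sys = 4L)
  g1 <- compute_rdm(slater_determinant(b, d$occ1), 1L)
  g2 <- compute_rdm(slater_determinant(b, d$occ2), 1L)
  w <- 0.3
  tgt <- mixture_target(two_state_mixture(d$occ1, d$occ2, w), 1L, d$M_sys)
  expect_equal(as.matrix(tgt$matrix),
               (1 - w) * as.matrix(g1$matrix) + w * as.matrix(g2$matrix),
               tolerance = 1e-12)
})

test_that("product purification reproduces the determinant RDM on the system", {
  b <- build_sector_basis(6L, N_sys = 4L)
  phi0 <- slater_determinant(b, c("1a", "1b", "2a", "2b"))
  psi <- purify_product(phi0)
  expect_equal(state_norm2(psi), 1, tolerance = 1e-13)
  expect_equal(psi$basis$M_bath, 6L)
  expect_equal(psi$basis$N_bath, 4L)
  g_sys <- compute_rdm(phi0, 1L)
  g_ext <- compute_rdm(psi, 1L)
  expect_equal(as.matrix(g_ext$matrix)[1:6, 1:6], as.matrix(g_sys$matrix),
               tolerance = 1e-12)
})

test_that("mixture purification marginal equals the mixed 1-RDM", {
  d <- model_determinants()$sys_4e3o
  spec <- two_state_mixture(d$occ1, d$occ2, 0.5)
  psi <- purify_mixture(spec, d$M_sys)
  expect_equal(state_norm2(psi), 1, tolerance = 1e-13)
  tgt <- mixture_target(spec, 1L, d$M_sys)
  g <- compute_rdm(psi, 1L)
  expect_equal(as.matrix(g$matrix)[1:6, 1:6], as.matrix(tgt$matrix),
               tolerance = 1e-12)
})

test_that("initial_state dispatches on scenario", {
  p <- initial_state("pure", c("1a", "1b", "2a", "2b"), 6L)
  expect_equal(p$basis$M_bath, 0L)
  e <- initial_state("ensemble", c("1a", "1b", "2a", "2b"), 6L)
  expect_equal(e$basis$M_bath, 6L)
  expect_equal(e$basis$N_bath, 4L)
})
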