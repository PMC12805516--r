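test_that("coleman_check accepts valid spectra and flags violations", {
  b <- build_sector_basis(6L, N_sys = 4L)
  set.seed(13)
  psi <- state_vector(b, rnorm(b$dim), normalize = TRUE)
  g <- compute_rdm(psi, 1L)
  chk <- coleman_check(g)
  expect_true(chk$ok)
  expect_equal(chk$trace, 4, tolerance = 1e-10)
  bad <- rdm(1L, 6L, 4L, diag(c(1.2, 1, 1, 0.8, 0, 0)))
  chk2 <- coleman_check(bad)
  expect_false(chk2$ok)
  expect_true(any(grepl("exceeds 1", chk2$violations)))
})

test_that("klyachko_check evaluates a custom inequality table", {
  ineq <- data.frame(kind = c("pauli", "gpc"),
                     b = c(1, 2),
                     a1 = c(1, 1), a2 = c(0, 1), a3 = c(0, 0), a4 = c(0, 1),
                     a5 = c(0, 0), a6 = c(0, 0), a7 = c(0, 1), a8 = c(0, 0),
                     stringsAsFactors = FALSE)
  r1 <- klyachko_check(c(0.9, 0.7, 0.6, 0.4), inequalities = ineq)
  expect_equal(r1$n_total, 2L)
  expect_equal(r1$n_satisfied, 2L)        # 0.9<=1; 0.9+0.7+0.4+0<=2
  r2 <- klyachko_check(c(1, 1, 1, 1), inequalities = ineq)
  expect_equal(r2$n_satisfied, 1L)        # second inequality: 3 > 2
  expect_false(r2$ok)
})

test_that("the packaged (4,8) inequality list is well formed", {
  ineq <- load_inequalities(4L, 8L)
  expect_equal(nrow(ineq), 15L)
  expect_true(all(ineq$kind %in% c("pauli", "gpc")))
  acols <- grep("^a[0-9]+$", names(ineq))
  expect_length(acols, 8L)
  A <- as.matrix(ineq[, acols])
  expect_true(all(A == round(A)))
  # every inequality holds on a large sample of actual pure-state spectra,
  # including determinants and random superpositions
  b <- build_sector_basis(8L, N_sys = 4L)
  set.seed(31)
  for (rep in 1:25) {
    amp <- if (rep <= 5) {
      a <- numeric(b$dim); a[sample(b$dim, 1)] <- 1; a
    } else rnorm(b$dim)
    psi <- state_vector(b, amp, normalize = TRUE)
    lam <- coleman_check(compute_rdm(psi, 1L))$eigenvalues
    chk <- klyachko_check(lam)
    expect_true(chk$ok)
  }
})

test_that("audits of the four model mixture spectra match the published counts", {
  det <- model_determinants()
  cases <- list(list(d = det$sys_4e3o, w = 0,   n = 15L),
                list(d = det$sys_4e3o, w = 0.5, n = 15L),
                list(d = det$sub1,     w = 0,   n = 15L),
                list(d = det$sub1,     w = 0.5, n = 7L))
  for (cs in cases) {
    tgt <- mixture_target(two_state_mixture(cs$d$occ1, cs$d$occ2, cs$w),
                          1L, cs$d$M_sys)
    chk <- klyachko_check(tgt)
    expect_equal(chk$n_total, 15L)
    expect_equal(chk$n_satisfied, cs$n)
  }
})
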