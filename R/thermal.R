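# Canonical-ensemble (thermal) targets from molecular integrals
# -------------------------------------------------------------
# The electronic Hamiltonian in a fixed N-electron sector is built from
# spatial-orbital integrals (FCIDUMP content), fully diagonalized (the
# sectors used here are tiny), and the thermal p-RDM is the Boltzmann
# average of the eigenstate p-RDMs over ALL eigenstates of the sector --
# every spin projection included, which is why the operator pool's default
# restriction is register particle number only.

#' Second-quantized Hamiltonian on a sector basis
#'
#' `H = sum_pq h[p,q] E_pq + 1/2 sum_pqrs (pq|rs) sum_st
#'  a^+_{p s} a^+_{r t} a_{s t} a_{q s}` over the system register, with
#' spatial orbital `p` mapping to spin-orbitals `2p-1` (alpha) and `2p`
#' (beta).  The core energy is NOT added (it shifts all eigenvalues equally
#' and cancels from Boltzmann weights).
#'
#' @param basis a system-only `sector_basis` with `M_sys = 2 * nrow(h)`
#' @param h one-electron spatial integrals
#' @param eri chemist-notation `(pq|rs)` spatial integrals
#' @return sparse symmetric matrix on the sector
#' @export
build_hamiltonian <- function(basis, h, eri) {
  n <- nrow(h)
  if (basis$M_sys != 2L * n)
    stop("basis has ", basis$M_sys, " spin-orbitals; integrals imply ", 2L * n)
  if (basis$M_bath != 0L) stop("build the Hamiltonian on a system-only sector")
  so <- function(p, spin) 2L * (p - 1L) + spin  # spin 1 = alpha, 2 = beta
  H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(basis$dim, basis$dim))
  for (p in seq_len(n)) for (q in seq_len(n)) {
    if (abs(h[p, q]) < 1e-14) next
    for (s in 1:2)
      H <- H + h[p, q] * one_body_matrix(basis, so(p, s), so(q, s))
  }
  for (p in seq_len(n)) for (q in seq_len(n))
    for (r in seq_len(n)) for (s in seq_len(n)) {
      v <- eri[p, q, r, s]
      if (abs(v) < 1e-14) next
      for (s1 in 1:2) for (s2 in 1:2) {
        i <- so(p, s1); j <- so(r, s2); k <- so(s, s2); l <- so(q, s1)
        if (i == j || k == l) next
        H <- H + (v / 2) * two_body_matrix(basis, i, j, k, l)
      }
    }
  H
}

#' Full diagonalization of an N-electron sector
#'
#' @param h,eri spatial integrals as in [build_hamiltonian()]
#' @param nelec electron count
#' @return list with `basis`, `values` (ascending), `vectors` (columns are
#'   eigenstates in the occupation basis)
#' @export
diagonalize_sector <- function(h, eri, nelec) {
  basis <- build_sector_basis(2L * nrow(h), 0L, nelec, 0L)
  H <- as.matrix(build_hamiltonian(basis, h, eri))
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  list(basis = basis, values = rev(e$values),
       vectors = e$vectors[, rev(seq_len(basis$dim)), drop = FALSE])
}

#' Default thermal energy scale: the first spectral gap
#'
#' `kT = E_k - E_0` for the lowest eigenvalue `E_k` that differs from the
#' ground energy beyond degeneracy tolerance.
#'
#' @param values ascending eigenvalues
#' @param tol degeneracy tolerance
#' @return positive numeric scalar
#' @export
first_gap <- function(values, tol = 1e-10) {
  gaps <- values - values[1]
  k <- which(gaps > tol)
  if (!length(k)) stop("spectrum is fully degenerate: no gap to set kT")
  gaps[k[1]]
}

#' Canonical-ensemble p-RDM of a molecular sector
#'
#' Diagonalizes the N-electron sector and Boltzmann-averages the eigenstate
#' p-RDMs over every eigenstate (all spin projections): `w_i proportional to
#' exp(-(E_i - E_0)/kT)`.  When `kT` is omitted it defaults to the first
#' spectral gap, which keeps both the ground state and the lowest excited
#' states at comparable weight.
#'
#' @param h,eri spatial integrals, e.g. from [read_fcidump()] or
#'   [hydrogen_chain_integrals()]
#' @param nelec electron count
#' @param p RDM order (1 or 2)
#' @param kT thermal energy (Hartree); default the first spectral gap
#' @return list with `rdm` (an [rdm()]), `weights`, `energies`, `kT`,
#'   `eig` (the [diagonalize_sector()] output)
#' @export
thermal_rdm <- function(h, eri, nelec, p, kT = NULL) {
  eig <- diagonalize_sector(h, eri, nelec)
  if (is.null(kT)) kT <- first_gap(eig$values)
  if (kT <= 0) stop("kT must be positive")
  wts <- exp(-(eig$values - eig$values[1]) / kT)
  wts <- wts / sum(wts)
  acc <- NULL
  for (m in seq_along(wts)) {
    if (wts[m] < 1e-16) next
    psi <- state_vector(eig$basis, eig$vectors[, m])
    r <- compute_rdm(psi, p)
    acc <- if (is.null(acc)) wts[m] * r$matrix else acc + wts[m] * r$matrix
  }
  list(rdm = rdm(p, eig$basis$M_sys, nelec, acc), weights = wts,
       energies = eig$values, kT = kT, eig = eig)
}
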