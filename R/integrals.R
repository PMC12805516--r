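# Minimal molecular integrals for s-type Gaussian basis sets
# -----------------------------------------------------------
# Self-contained one- and two-electron integrals over contracted s-type
# Gaussians (STO-nG style), sufficient for hydrogen chains: overlap, kinetic,
# nuclear attraction and electron repulsion, with the Boys function
# F0(x) = (1/2) sqrt(pi/x) erf(sqrt(x)).  Everything is closed-form for
# l = 0, so no quantum-chemistry backend is required.

#' STO-3G hydrogen basis shell
#'
#' Exponents and contraction coefficients of the standard STO-3G 1s shell for
#' hydrogen (zeta = 1.24 scaling already folded in).
#'
#' @return list with `exponents` and `coefficients`
#' @export
sto3g_hydrogen <- function() {
  list(exponents = c(3.42525091, 0.62391373, 0.16885540),
       coefficients = c(0.15432897, 0.53532814, 0.44463454))
}

# Boys function of order zero; the x -> 0 limit is 1 - x/3 + ...
.boys0 <- function(x) {
  ifelse(x < 1e-12, 1 - x / 3,
         0.5 * sqrt(pi / pmax(x, 1e-300)) * .erf_sqrt(x))
}

.erf_sqrt <- function(x) {
  s <- sqrt(pmax(x, 0))
  2 * stats::pnorm(s * sqrt(2)) - 1
}

# normalized primitive s-Gaussian prefactor
.snorm <- function(alpha) (2 * alpha / pi)^0.75

#' Build contracted s-shell centers
#'
#' @param centers numeric matrix, one row per atom, columns x, y, z (bohr)
#' @param shell a basis shell like [sto3g_hydrogen()]
#' @return list of shells, each with `center`, `exponents`, `coefficients`
#'   (primitive normalization folded into the coefficients)
#' @export
s_basis <- function(centers, shell = sto3g_hydrogen()) {
  centers <- as.matrix(centers)
  lapply(seq_len(nrow(centers)), function(a)
    list(center = as.numeric(centers[a, ]),
         exponents = shell$exponents,
         coefficients = shell$coefficients * .snorm(shell$exponents)))
}

# primitive s-overlap and kinetic between Gaussians (alpha, A), (beta, B)
.prim_overlap <- function(alpha, beta, A, B) {
  p <- alpha + beta
  r2 <- sum((A - B)^2)
  (pi / p)^1.5 * exp(-alpha * beta / p * r2)
}

.prim_kinetic <- function(alpha, beta, A, B) {
  p <- alpha + beta
  mu <- alpha * beta / p
  r2 <- sum((A - B)^2)
  mu * (3 - 2 * mu * r2) * .prim_overlap(alpha, beta, A, B)
}

.prim_nuclear <- function(alpha, beta, A, B, C) {
  p <- alpha + beta
  r2 <- sum((A - B)^2)
  P <- (alpha * A + beta * B) / p
  -2 * pi / p * exp(-alpha * beta / p * r2) * .boys0(p * sum((P - C)^2))
}

# (ab|cd) over primitives, chemist notation
.prim_eri <- function(a, b, c, d, A, B, C, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p
  Q <- (c * C + d * D) / q
  rab2 <- sum((A - B)^2); rcd2 <- sum((C - D)^2)
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * rab2 - c * d / q * rcd2) *
    .boys0(p * q / (p + q) * sum((P - Q)^2))
}

.contract2 <- function(sh1, sh2, prim) {
  s <- 0
  for (i in seq_along(sh1$exponents)) for (j in seq_along(sh2$exponents))
    s <- s + sh1$coefficients[i] * sh2$coefficients[j] *
      prim(sh1$exponents[i], sh2$exponents[j], sh1$center, sh2$center)
  s
}

#' One- and two-electron AO integrals of an s-type basis
#'
#' @param basis list of shells from [s_basis()]
#' @param charges nuclear charges, one per atom
#' @param centers numeric matrix of nuclear positions (bohr)
#' @return list with `S` (overlap), `T` (kinetic), `V` (nuclear attraction),
#'   `eri` (4-index array, chemist `(ij|kl)`), `enuc` (nuclear repulsion)
#' @export
ao_integrals <- function(basis, charges, centers) {
  n <- length(basis)
  centers <- as.matrix(centers)
  S <- T <- V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    S[i, j] <- .contract2(basis[[i]], basis[[j]], .prim_overlap)
    T[i, j] <- .contract2(basis[[i]], basis[[j]], .prim_kinetic)
    v <- 0
    for (a in seq_len(nrow(centers))) {
      sh1 <- basis[[i]]; sh2 <- basis[[j]]
      for (p in seq_along(sh1$exponents)) for (q in seq_along(sh2$exponents))
        v <- v + charges[a] * sh1$coefficients[p] * sh2$coefficients[q] *
          .prim_nuclear(sh1$exponents[p], sh2$exponents[q],
                        sh1$center, sh2$center, as.numeric(centers[a, ]))
    }
    V[i, j] <- v
  }
  eri <- array(0, c(n, n, n, n))
  for (i in seq_len(n)) for (j in seq_len(n))
    for (k in seq_len(n)) for (l in seq_len(n)) {
      s <- 0
      b1 <- basis[[i]]; b2 <- basis[[j]]; b3 <- basis[[k]]; b4 <- basis[[l]]
      for (p in seq_along(b1$exponents)) for (q in seq_along(b2$exponents))
        for (r in seq_along(b3$exponents)) for (t in seq_along(b4$exponents))
          s <- s + b1$coefficients[p] * b2$coefficients[q] *
            b3$coefficients[r] * b4$coefficients[t] *
            .prim_eri(b1$exponents[p], b2$exponents[q],
                      b3$exponents[r], b4$exponents[t],
                      b1$center, b2$center, b3$center, b4$center)
      eri[i, j, k, l] <- s
    }
  enuc <- 0
  na <- nrow(centers)
  if (na > 1L)
    for (a in seq_len(na - 1L)) for (b in seq.int(a + 1L, na))
      enuc <- enuc + charges[a] * charges[b] /
        sqrt(sum((centers[a, ] - centers[b, ])^2))
  list(S = S, T = T, V = V, eri = eri, enuc = enuc)
}

#' Molecular-orbital integrals of a hydrogen chain
#'
#' Builds STO-3G AO integrals for `n` hydrogen atoms placed on the x axis
#' with uniform spacing, orthogonalizes into molecular orbitals and returns
#' the transformed one- and two-electron integrals.  For two atoms the
#' orbitals are the symmetry-determined gerade/ungerade combinations (equal
#' to RHF); for longer chains the core-Hamiltonian eigenbasis (symmetric
#' orthogonalization followed by diagonalizing `T + V`) is used.
#'
#' @param n_atoms number of hydrogen atoms
#' @param spacing internuclear distance in Angstrom
#' @return list with `h` (core Hamiltonian, MO basis), `eri` (chemist
#'   `(ij|kl)`, MO basis), `enuc`, `C` (AO -> MO coefficients), `S`
#' @export
hydrogen_chain_integrals <- function(n_atoms, spacing) {
  bohr <- spacing / 0.529177210903
  centers <- cbind(x = (seq_len(n_atoms) - 1) * bohr, y = 0, z = 0)
  basis <- s_basis(centers)
  ints <- ao_integrals(basis, rep(1, n_atoms), centers)
  hcore <- ints$T + ints$V
  # symmetric (Loewdin) orthogonalization, then diagonalize the core
  # Hamiltonian; orbitals ordered by core energy
  es <- eigen(ints$S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
  hx <- t(X) %*% hcore %*% X
  eh <- eigen(hx, symmetric = TRUE)
  ord <- order(eh$values)    # eigen() sorts descending; want core energy ascending
  C <- X %*% eh$vectors[, ord, drop = FALSE]
  # fix sign convention: largest-magnitude AO coefficient positive
  for (m in seq_len(ncol(C))) {
    k <- which.max(abs(C[, m]))
    if (C[k, m] < 0) C[, m] <- -C[, m]
  }
  h <- t(C) %*% hcore %*% C
  n <- n_atoms
  eri <- array(0, c(n, n, n, n))
  # two-step quarter transformations would be faster; n <= 3 here
  for (i in seq_len(n)) for (j in seq_len(n))
    for (k in seq_len(n)) for (l in seq_len(n)) {
      s <- 0
      for (p in seq_len(n)) for (q in seq_len(n))
        for (r in seq_len(n)) for (t in seq_len(n))
          s <- s + C[p, i] * C[q, j] * C[r, k] * C[t, l] * ints$eri[p, q, r, t]
      eri[i, j, k, l] <- s
    }
  list(h = h, eri = eri, enuc = ints$enuc, C = C, S = ints$S)
}
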