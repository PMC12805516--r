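# p-body reduced density matrices
# -------------------------------
# Elements are bare second-quantized expectations over SYSTEM spin-orbitals,
#   p = 1:  gamma[i, k]          = <a_i^+ a_k>
#   p = 2:  Gamma[(i,j), (k,l)]  = <a_i^+ a_j^+ a_l a_k>
# (the common quantum-chemistry element convention, positive diagonal).  The
# bath, when present, is traced out implicitly because indices never touch it.
# Traces are then p! C(N, p): N for p = 1 and N(N-1) for p = 2, the stated
# normalization.  The 2-RDM is stored over all M^2 ordered index pairs with
# pair (i, j) at row (i-1)*M + j; antisymmetry is explicit and (i,i) rows are
# identically zero.  Distances are plain squared Frobenius norms of this
# representation, which counts every physical 2-body element four times for
# both operands.

pair_rows <- function(M) {
  # representative pairs i < j, lexicographic
  p <- utils::combn(M, 2L)
  list(i = p[1, ], j = p[2, ], n = ncol(p))
}

# signed incidence M^2 x nrep: full ordered-pair matrix = S %*% rep %*% t(S)
pair_scatter <- function(M) {
  pr <- pair_rows(M)
  S <- matrix(0, M * M, pr$n)
  idx <- function(i, j) (i - 1L) * M + j
  for (a in seq_len(pr$n)) {
    S[idx(pr$i[a], pr$j[a]), a] <- 1
    S[idx(pr$j[a], pr$i[a]), a] <- -1
  }
  S
}

#' Construct a reduced-density-matrix object
#'
#' @param p body order (1 or 2)
#' @param M_sys number of system spin-orbitals
#' @param N electron count used for the normalization
#' @param matrix the matrix itself: `M_sys x M_sys` for p = 1,
#'   `M_sys^2 x M_sys^2` over ordered index pairs for p = 2
#' @return object of class `rdm`
#' @export
rdm <- function(p, M_sys, N, matrix) {
  p <- as.integer(p)
  if (!p %in% c(1L, 2L)) stop("unsupported RDM order p = ", p)
  d <- if (p == 1L) M_sys else M_sys^2
  if (!all(dim(matrix) == c(d, d)))
    stop("matrix dimension ", nrow(matrix), " does not match p = ", p,
         " with ", M_sys, " spin-orbitals (expected ", d, ")")
  structure(list(p = p, M_sys = as.integer(M_sys), N = as.integer(N),
                 matrix = matrix),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  herm <- max(abs(x$matrix - Conj(t(x$matrix))))
  cat(sprintf("<rdm> p = %d, %d system spin-orbitals, N = %d, trace %.6f, hermiticity residual %.2e\n",
              x$p, x$M_sys, x$N, Re(sum(diag(x$matrix))), herm))
  invisible(x)
}

# columns chi_k = a_k psi for system k (p = 1); cached per basis
.chi1 <- function(psi) {
  b <- psi$basis
  M <- b$M_sys
  C <- matrix(0, annihilation_target(b, 1L)$dim, M)
  for (k in seq_len(M))
    C[, k] <- as.numeric(annihilation_map(b, k) %*% psi$amplitudes)
  C
}

# columns chi_(i<j) = a_j a_i psi for system pairs (p = 2)
.chi2 <- function(psi) {
  b <- psi$basis
  pr <- pair_rows(b$M_sys)
  C <- matrix(0, pair_annihilation_target(b, pr$i[1], pr$j[1])$dim, pr$n)
  for (a in seq_len(pr$n))
    C[, a] <- as.numeric(pair_annihilation_map(b, pr$i[a], pr$j[a]) %*% psi$amplitudes)
  C
}

#' Compute the p-body reduced density matrix of a statevector
#'
#' Indices run over the system register only, so for an extended
#' (system + bath) state the bath is traced out.  The result carries the
#' normalization trace = p! C(N, p) with N the system electron count.
#'
#' @param psi a normalized `state_vector`
#' @param p 1 or 2
#' @return an [rdm()]
#' @export
compute_rdm <- function(psi, p) {
  p <- as.integer(p)
  b <- psi$basis
  if (p == 1L) {
    C <- .chi1(psi)
    g <- crossprod(C)
    return(rdm(1L, b$M_sys, b$N_sys, g))
  }
  if (p == 2L) {
    if (b$N_sys < 2L) stop("p = 2 requires at least two system electrons")
    C <- .chi2(psi)
    grep_ <- crossprod(C)
    S <- pair_scatter(b$M_sys)
    full <- S %*% grep_ %*% t(S)
    return(rdm(2L, b$M_sys, b$N_sys, full))
  }
  stop("unsupported RDM order p = ", p)
}

#' Squared Hilbert-Schmidt distance between two RDMs
#'
#' @param a,b `rdm`s of the same order and orbital count
#' @return non-negative numeric scalar, `sum(|a - b|^2)`
#' @export
hs_distance_sq <- function(a, b) {
  stopifnot(inherits(a, "rdm"), inherits(b, "rdm"))
  if (a$p != b$p || a$M_sys != b$M_sys)
    stop("RDM shape mismatch: (p = ", a$p, ", M = ", a$M_sys, ") vs (p = ",
         b$p, ", M = ", b$M_sys, ")")
  sum(Mod(a$matrix - b$matrix)^2)
}

# internal: distance, effective symmetric residual, evolved rdm
.residual <- function(evolved, target) {
  D <- sum(Mod(evolved$matrix - target$matrix)^2)
  re <- Re(target$matrix)
  delta <- Re(evolved$matrix) - (re + t(re)) / 2
  list(D = D, delta = delta, rdm = evolved)
}

#' Cost-gradient state of the squared-distance functional
#'
#' Returns `w` such that the derivative of
#' `D(theta) = || rho_p(exp(theta O) psi) - target ||^2` at `theta = 0` is
#' `4 * <w, O psi>` for any antihermitian generator `O`; `w` is the state
#' `A psi` with `A` the residual-weighted sum of p-body transition operators.
#'
#' @param psi normalized `state_vector`
#' @param target target [rdm()]
#' @return numeric vector of length `psi$basis$dim`
#' @export
rdm_gradient_state <- function(psi, target) {
  .gradient_state(psi, target, compute_rdm(psi, target$p))$w
}

# shared worker: given psi and its evolved rdm, return D and w
.gradient_state <- function(psi, target, evolved) {
  b <- psi$basis
  res <- .residual(evolved, target)
  if (target$p == 1L) {
    C <- .chi1(psi)
    Y <- C %*% res$delta                     # Y[, i] = sum_k delta[k, i] chi_k
    w <- numeric(b$dim)
    for (i in seq_len(b$M_sys))
      w <- w + as.numeric(Matrix::t(annihilation_map(b, i)) %*% Y[, i])
  } else {
    C <- .chi2(psi)
    S <- pair_scatter(b$M_sys)
    drep <- t(S) %*% res$delta %*% S         # nrep x nrep
    Y <- C %*% drep
    pr <- pair_rows(b$M_sys)
    w <- numeric(b$dim)
    for (a in seq_len(pr$n))
      w <- w + as.numeric(Matrix::t(pair_annihilation_map(b, pr$i[a], pr$j[a])) %*% Y[, a])
  }
  list(D = res$D, w = w, rdm = evolved)
}

#' Contract a 2-RDM to its 1-RDM
#'
#' `gamma[i, k] = 1/(N-1) * sum_j Gamma[(i,j), (k,j)]`, trace N.
#'
#' @param rdm2 an [rdm()] with p = 2
#' @return an [rdm()] with p = 1
#' @export
contract_2rdm <- function(rdm2) {
  stopifnot(inherits(rdm2, "rdm"), rdm2$p == 2L)
  if (rdm2$N <= 1L) stop("contraction requires N > 1")
  M <- rdm2$M_sys
  g <- matrix(0, M, M)
  idx <- function(i, j) (i - 1L) * M + j
  for (i in seq_len(M)) for (k in seq_len(M)) {
    s <- 0
    for (j in seq_len(M)) s <- s + rdm2$matrix[idx(i, j), idx(k, j)]
    g[i, k] <- Re(s) / (rdm2$N - 1L)
  }
  rdm(1L, M, rdm2$N, g)
}

#' Perturb an RDM with uniform random noise
#'
#' Adds `eps * R` with `R` sampled element-wise from the uniform distribution
#' on `[-1, 1]`.  By default `R` is used as drawn, so the perturbed target is
#' in general neither Hermitian nor antisymmetry-conforming (the distance to
#' it then contains an irreducible offset, which is the intended measure of
#' the representability violation).  Set `hermitize = TRUE` to symmetrize
#' `R <- (R + t(R))/2` and keep the target Hermitian.
#'
#' @param x an [rdm()]
#' @param eps noise strength, >= 0
#' @param seed integer seed making the draw reproducible
#' @param hermitize symmetrize the noise matrix
#' @return an [rdm()] with the perturbed matrix
#' @export
add_noise <- function(x, eps, seed, hermitize = FALSE) {
  stopifnot(inherits(x, "rdm"))
  if (eps < 0) stop("noise strength must be non-negative")
  if (eps == 0) return(x)
  d <- nrow(x$matrix)
  R <- with_seed(seed, matrix(runif(d * d, -1, 1), d, d))
  if (hermitize) R <- (R + t(R)) / 2
  rdm(x$p, x$M_sys, x$N, x$matrix + eps * R)
}

# evaluate thunk under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Write an RDM to a plain-text file
#'
#' Format: a header line `p M_sys N` followed by the matrix, one row per
#' line, whitespace-separated, full precision.
#'
#' @param x an [rdm()]
#' @param file path
#' @export
write_rdm <- function(x, file) {
  stopifnot(inherits(x, "rdm"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d", x$p, x$M_sys, x$N), con)
  m <- Re(x$matrix)
  for (r in seq_len(nrow(m)))
    writeLines(paste(formatC(m[r, ], format = "g", digits = 17), collapse = " "), con)
  invisible(file)
}

#' Read an RDM from a plain-text file written by [write_rdm()]
#'
#' @param file path
#' @return an [rdm()]
#' @export
read_rdm <- function(file) {
  lines <- readLines(file)
  hd <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hd) != 3) stop("malformed RDM header (expected: p M_sys N)")
  rows <- lapply(lines[-1][nzchar(trimws(lines[-1]))],
                 function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  m <- do.call(rbind, rows)
  rdm(hd[1], hd[2], hd[3], m)
}
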