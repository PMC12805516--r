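#' @importFrom Matrix sparseMatrix
#' @importFrom stats optim runif rnorm setNames
#' @importFrom utils head tail combn
NULL

# Canonical spin-orbital ordering
# ------------------------------
# Global indices are 1-based: system register first, then bath; within a
# register spatial orbitals ascending; within a spatial orbital alpha before
# beta.  Occupation words store spin-orbital g in bit (g - 1), so a word is an
# ordinary non-negative integer < 2^M and the basis order is simply ascending
# word value.  All fermionic phases are parities of occupied bits below a
# given position, i.e. the Jordan-Wigner sign convention for this ordering.

.popcount16 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      v <- 0:65535L
      cnt <- integer(65536L)
      for (b in 0:15) cnt <- cnt + bitwAnd(bitwShiftR(v, b), 1L)
      tab <<- cnt
    }
    tab
  }
})

#' Count set bits of occupation words
#' @param w integer vector of occupation words (< 2^30)
#' @return integer vector of bit counts
#' @keywords internal
#' Number of set bits of an occupation word
#'
#' @param w integer vector of occupation words
#' @return integer vector of electron counts
#' @export
popcount <- function(w) {
  tab <- .popcount16()
  tab[bitwAnd(w, 65535L) + 1L] + tab[bitwShiftR(w, 16L) + 1L]
}

# parity (+1/-1) of the number of occupied bits of w strictly below bit `bit`
# (bit is 0-based)
.jw_sign <- function(w, bit) {
  mask <- bitwShiftL(1L, bit) - 1L
  1L - 2L * bitwAnd(popcount(bitwAnd(w, mask)), 1L)
}

#' Describe a spin orbital by its global index
#'
#' Inverts the canonical ordering: global index -> (register, spatial, spin).
#'
#' @param g vector of 1-based global spin-orbital indices
#' @param M_sys number of system spin-orbitals
#' @return data.frame with columns `global`, `register`, `spatial`, `spin`
#' @export
spin_orbital <- function(g, M_sys) {
  g <- as.integer(g)
  stopifnot(all(g >= 1L))
  reg <- ifelse(g > M_sys, "bath", "system")
  loc <- ifelse(g > M_sys, g - M_sys, g)
  data.frame(global = g, register = reg,
             spatial = (loc + 1L) %/% 2L,
             spin = ifelse(loc %% 2L == 1L, "alpha", "beta"),
             stringsAsFactors = FALSE)
}

#' Global index of a spin orbital
#'
#' @param spatial 1-based spatial orbital index
#' @param spin "alpha" or "beta" (abbreviations "a"/"b" accepted)
#' @param register "system" or "bath"
#' @param M_sys number of system spin-orbitals (needed for bath orbitals)
#' @return 1-based global index under the canonical ordering
#' @export
so_index <- function(spatial, spin, register = "system", M_sys = NULL) {
  spin <- match.arg(substr(spin, 1, 1), c("a", "b"))
  loc <- 2L * (as.integer(spatial) - 1L) + ifelse(spin == "a", 1L, 2L)
  if (identical(register, "bath")) {
    if (is.null(M_sys)) stop("M_sys required for bath orbitals")
    loc <- loc + as.integer(M_sys)
  }
  loc
}

#' Parse determinant labels like c("1a", "1b", "2a", "2b")
#'
#' Each element is `<spatial><a|b>`; an optional leading "~" marks a bath
#' orbital (e.g. "~1a").
#'
#' @param labels character vector of spin-orbital labels
#' @param M_sys number of system spin-orbitals
#' @return integer vector of global indices
#' @export
parse_orbitals <- function(labels, M_sys = NULL) {
  if (is.numeric(labels)) return(as.integer(labels))
  vapply(labels, function(s) {
    bath <- startsWith(s, "~")
    if (bath) s <- substring(s, 2)
    m <- regmatches(s, regexec("^([0-9]+)([ab])$", s))[[1]]
    if (length(m) != 3) stop("cannot parse spin-orbital label: ", s)
    so_index(as.integer(m[2]), m[3],
             register = if (bath) "bath" else "system", M_sys = M_sys)
  }, integer(1), USE.NAMES = FALSE)
}

.enumerate_words <- function(M, N) {
  if (N < 0 || N > M) stop("electron count out of range")
  if (N == 0) return(0L)
  combs <- utils::combn(M, N)
  words <- colSums(matrix(bitwShiftL(1L, combs - 1L), nrow = N))
  sort(as.integer(words))
}

#' Build a particle-number sector basis
#'
#' Enumerates all occupation words with exactly `N_sys` electrons among the
#' `M_sys` system spin-orbitals and `N_bath` among the `M_bath` bath
#' spin-orbitals, ordered by ascending integer value of the word.
#'
#' @param M_sys,M_bath spin-orbital counts of the two registers (`M_bath = 0`
#'   for a system-only basis)
#' @param N_sys,N_bath electron numbers in the two registers
#' @return object of class `sector_basis`
#' @export
build_sector_basis <- function(M_sys, M_bath = 0L, N_sys, N_bath = 0L) {
  M_sys <- as.integer(M_sys); M_bath <- as.integer(M_bath)
  N_sys <- as.integer(N_sys); N_bath <- as.integer(N_bath)
  if (N_sys < 0L || N_sys > M_sys)
    stop("system register: electron count ", N_sys,
         " out of range for ", M_sys, " spin-orbitals")
  if (N_bath < 0L || N_bath > M_bath)
    stop("bath register: electron count ", N_bath,
         " out of range for ", M_bath, " spin-orbitals")
  sys_words <- .enumerate_words(M_sys, N_sys)
  if (M_bath > 0L) {
    bath_words <- .enumerate_words(M_bath, N_bath)
    words <- sort(as.integer(outer(sys_words, bitwShiftL(bath_words, M_sys), "+")))
  } else {
    words <- sys_words
  }
  b <- list(M_sys = M_sys, M_bath = M_bath, M = M_sys + M_bath,
            N_sys = N_sys, N_bath = N_bath,
            states = words, dim = length(words), cache = new.env(parent = emptyenv()))
  class(b) <- "sector_basis"
  b
}

#' @export
print.sector_basis <- function(x, ...) {
  cat(sprintf("<sector_basis> %d states | system %de in %d spin-orbitals",
              x$dim, x$N_sys, x$M_sys))
  if (x$M_bath > 0)
    cat(sprintf(" | bath %de in %d spin-orbitals", x$N_bath, x$M_bath))
  cat("\n")
  invisible(x)
}

#' Positions of occupation words in a sector basis
#'
#' @param basis a `sector_basis`
#' @param words integer occupation words
#' @return integer positions (0 for words outside the basis)
#' @export
word_index <- function(basis, words) {
  idx <- findInterval(words, basis$states)
  ok <- idx >= 1L & basis$states[pmax(idx, 1L)] == words
  idx[!ok] <- 0L
  idx
}

#' Slater determinant as a statevector
#'
#' @param basis a `sector_basis`
#' @param occupied occupied spin orbitals: integer global indices or labels
#'   accepted by [parse_orbitals()]
#' @return object of class `state_vector` (unit amplitude on one word)
#' @export
slater_determinant <- function(basis, occupied) {
  occ <- parse_orbitals(occupied, M_sys = basis$M_sys)
  if (anyDuplicated(occ))
    stop("duplicate spin-orbital in determinant (Pauli exclusion)")
  if (any(occ < 1L | occ > basis$M)) stop("spin-orbital index out of range")
  n_sys <- sum(occ <= basis$M_sys)
  n_bath <- length(occ) - n_sys
  if (n_sys != basis$N_sys)
    stop("determinant has ", n_sys, " system electrons; sector requires ", basis$N_sys)
  if (n_bath != basis$N_bath)
    stop("determinant has ", n_bath, " bath electrons; sector requires ", basis$N_bath)
  w <- sum(bitwShiftL(1L, occ - 1L))
  k <- word_index(basis, as.integer(w))
  amp <- numeric(basis$dim)
  amp[k] <- 1
  state_vector(basis, amp)
}

#' Construct a statevector over a sector basis
#'
#' @param basis a `sector_basis`
#' @param amplitudes real amplitude vector of length `basis$dim`
#' @param normalize divide by the norm (default FALSE)
#' @return object of class `state_vector`
#' @export
state_vector <- function(basis, amplitudes, normalize = FALSE) {
  stopifnot(inherits(basis, "sector_basis"), length(amplitudes) == basis$dim)
  a <- as.numeric(amplitudes)
  if (normalize) a <- a / sqrt(sum(a^2))
  structure(list(basis = basis, amplitudes = a), class = "state_vector")
}

#' @export
print.state_vector <- function(x, n = 8, ...) {
  cat(sprintf("<state_vector> dim %d, norm %.10f\n", x$basis$dim,
              sqrt(sum(x$amplitudes^2))))
  ord <- order(abs(x$amplitudes), decreasing = TRUE)
  ord <- ord[abs(x$amplitudes[ord]) > 1e-12][seq_len(min(n, x$basis$dim))]
  ord <- ord[!is.na(ord)]
  for (k in ord) {
    w <- x$basis$states[k]
    occ <- which(bitwAnd(bitwShiftR(w, 0:(x$basis$M - 1L)), 1L) == 1L)
    lab <- paste(vapply(occ, function(g) {
      d <- spin_orbital(g, x$basis$M_sys)
      paste0(if (d$register == "bath") "~" else "", d$spatial,
             substr(d$spin, 1, 1))
    }, character(1)), collapse = " ")
    cat(sprintf("  %+.6f |%s>\n", x$amplitudes[k], lab))
  }
  invisible(x)
}

#' Squared norm of a statevector
#' @param psi a `state_vector`
#' @return numeric scalar
#' @export
state_norm2 <- function(psi) sum(psi$amplitudes^2)

#' Inner product of two statevectors on the same basis
#' @param x,y `state_vector`s sharing a basis
#' @return numeric scalar
#' @export
state_dot <- function(x, y) sum(x$amplitudes * y$amplitudes)
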