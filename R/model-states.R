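# Target and initial states for the zero-temperature model systems
# ----------------------------------------------------------------
# Targets are p-RDMs of convex mixtures rho = sum_i w_i |phi_i><phi_i| of
# Slater determinants; ensemble runs start from the product purification
# |phi_0> (x) |phi_0> in the doubled orbital space and must discover the
# entangled purification themselves.

#' Specify a convex mixture of Slater determinants
#'
#' @param components list of components, each a list with elements `occupied`
#'   (orbital labels or indices, see [parse_orbitals()]) and `weight`
#' @return object of class `mixture_spec`
#' @export
mixture_spec <- function(components) {
  w <- vapply(components, function(c) as.numeric(c$weight), numeric(1))
  if (any(w < 0)) stop("mixture weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    stop("mixture weights must sum to 1 (got ", sum(w), ")")
  ns <- vapply(components, function(c) length(c$occupied), integer(1))
  if (length(unique(ns)) != 1L)
    stop("all mixture components must share one electron count")
  structure(list(components = components, N = ns[1]), class = "mixture_spec")
}

#' Two-component mixture `(1 - w) * rho1 + w * rho2`
#'
#' `occ1` is the reference determinant and `occ2` the substituted one; `w` is
#' the admixture weight of the substituted determinant, so `w = 0` gives the
#' pure reference state and `w = 0.5` the equal-weight mixture.
#'
#' @param occ1,occ2 occupied orbitals of the two determinants
#' @param w admixture weight of `occ2`, in `[0, 1]`
#' @return a [mixture_spec()]
#' @export
two_state_mixture <- function(occ1, occ2, w) {
  if (w < 0 || w > 1) stop("weight must lie in [0, 1]")
  mixture_spec(list(list(occupied = occ1, weight = 1 - w),
                    list(occupied = occ2, weight = w)))
}

#' p-RDM of a determinant mixture
#'
#' Builds `sum_i w_i rho_p(phi_i)` over `M_sys` system spin-orbitals with the
#' trace-`p! C(N, p)` normalization.
#'
#' @param spec a [mixture_spec()]
#' @param p 1 or 2
#' @param M_sys number of system spin-orbitals
#' @return an [rdm()]
#' @export
mixture_target <- function(spec, p, M_sys) {
  stopifnot(inherits(spec, "mixture_spec"))
  basis <- build_sector_basis(M_sys, 0L, spec$N, 0L)
  acc <- NULL
  for (cmp in spec$components) {
    phi <- slater_determinant(basis, cmp$occupied)
    r <- compute_rdm(phi, p)
    acc <- if (is.null(acc)) cmp$weight * r$matrix else acc + cmp$weight * r$matrix
  }
  rdm(p, M_sys, spec$N, acc)
}

#' Product purification of a system state
#'
#' Embeds a normalized N-electron system state `|phi0>` as
#' `|phi0> (x) |phi0>` in the extended space whose bath register mirrors the
#' system orbitals one-to-one; tracing the bath recovers the pure density
#' `|phi0><phi0|`.
#'
#' @param phi0 `state_vector` on a system-only sector basis
#' @return `state_vector` on the extended sector `(N, N)`
#' @export
purify_product <- function(phi0) {
  b <- phi0$basis
  if (b$M_bath != 0L) stop("phi0 must live in a system-only sector")
  if (abs(state_norm2(phi0) - 1) > 1e-10) stop("phi0 must be normalized")
  ext <- build_sector_basis(b$M_sys, b$M_sys, b$N_sys, b$N_sys)
  amp <- numeric(ext$dim)
  # extended word = system word | bath word << M_sys; the canonical ordering
  # (system creation operators first, ascending) introduces no extra sign
  for (ks in seq_len(b$dim)) {
    a <- phi0$amplitudes[ks]
    if (a == 0) next
    words <- b$states[ks] + bitwShiftL(b$states, b$M_sys)
    idx <- word_index(ext, words)
    amp[idx] <- amp[idx] + a * phi0$amplitudes
  }
  state_vector(ext, amp)
}

#' Exact purification of a determinant mixture
#'
#' Realizes `|Psi> = sum_i sqrt(w_i) |phi_i> (x) |b_i>` with orthonormal bath
#' tags `b_i`.  The tags are Slater determinants with N bath electrons taken,
#' by default, in basis order from the bath sector; determinant tags keep the
#' state inside one particle-number sector, and orthonormality is all the
#' purification requires.
#'
#' @param spec a [mixture_spec()]
#' @param M_sys number of system spin-orbitals
#' @param tags optional list of bath occupation vectors (bath-local indices
#'   1..M_sys) overriding the default tag choice
#' @return `state_vector` on the extended sector `(N, N)`
#' @export
purify_mixture <- function(spec, M_sys, tags = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  N <- spec$N
  ext <- build_sector_basis(M_sys, M_sys, N, N)
  K <- length(spec$components)
  bath_words <- .enumerate_words(M_sys, N)
  if (is.null(tags)) {
    tag_words <- bath_words[seq_len(K)]
  } else {
    tag_words <- vapply(tags, function(t) sum(bitwShiftL(1L, as.integer(t) - 1L)),
                        numeric(1))
    if (anyDuplicated(tag_words)) stop("bath tags must be distinct determinants")
  }
  sys_basis <- build_sector_basis(M_sys, 0L, N, 0L)
  amp <- numeric(ext$dim)
  for (m in seq_len(K)) {
    cmp <- spec$components[[m]]
    phi <- slater_determinant(sys_basis, cmp$occupied)
    ks <- which(phi$amplitudes != 0)
    words <- sys_basis$states[ks] + bitwShiftL(as.integer(tag_words[m]), M_sys)
    idx <- word_index(ext, words)
    amp[idx] <- amp[idx] + sqrt(cmp$weight) * phi$amplitudes[ks]
  }
  state_vector(ext, amp)
}

#' Initial state for a pure or ensemble run
#'
#' Pure runs start from the reference determinant itself (system-only
#' sector); ensemble runs start from its product purification.
#'
#' @param scenario `"pure"` or `"ensemble"`
#' @param occupied occupied orbitals of the reference determinant
#' @param M_sys number of system spin-orbitals
#' @return a `state_vector`
#' @export
initial_state <- function(scenario = c("pure", "ensemble"), occupied, M_sys) {
  scenario <- match.arg(scenario)
  occ <- parse_orbitals(occupied, M_sys = M_sys)
  basis <- build_sector_basis(M_sys, 0L, length(occ), 0L)
  phi0 <- slater_determinant(basis, occ)
  if (scenario == "pure") phi0 else purify_product(phi0)
}
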