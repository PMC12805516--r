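# Independent N-representability audits of 1-RDM spectra
# -------------------------------------------------------
# Coleman's ensemble conditions (eigenvalues in [0, 1], trace N) and the
# generalized Pauli (Klyachko) pure-state conditions for N = 4 electrons in
# 8 spin-orbitals.  The inequality list ships as a plain-text data file;
# spectra from smaller orbital counts are padded with zeros, so the same 15
# inequalities audit both model systems.

#' Coleman ensemble N-representability check of a 1-RDM
#'
#' @param x an [rdm()] with p = 1
#' @param tol numerical tolerance
#' @return list with `ok`, `eigenvalues` (descending), `trace`, `violations`
#'   (character vector, empty when `ok`)
#' @export
coleman_check <- function(x, tol = 1e-8) {
  stopifnot(inherits(x, "rdm"), x$p == 1L)
  m <- (x$matrix + Conj(t(x$matrix))) / 2
  ev <- sort(Re(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
             decreasing = TRUE)
  tr <- Re(sum(diag(x$matrix)))
  viol <- character(0)
  herm <- max(abs(x$matrix - Conj(t(x$matrix))))
  if (herm > tol) viol <- c(viol, sprintf("not Hermitian (residual %.2e)", herm))
  if (min(ev) < -tol) viol <- c(viol, sprintf("negative eigenvalue %.3e", min(ev)))
  if (max(ev) > 1 + tol) viol <- c(viol, sprintf("eigenvalue %.3e exceeds 1", max(ev)))
  if (abs(tr - x$N) > tol) viol <- c(viol, sprintf("trace %.6f != N = %d", tr, x$N))
  list(ok = length(viol) == 0L, eigenvalues = ev, trace = tr, violations = viol)
}

#' Load the packaged generalized Pauli inequality list
#'
#' The file stores one inequality per row, `sum_i a_i lambda_i <= b` on the
#' descending spectrum, with a `kind` tag (`pauli` for the ordinary Pauli
#' bound, `gpc` for a generalized Pauli constraint facet).
#'
#' @param n_electrons,n_spin_orbitals setting; only (4, 8) ships with the
#'   package
#' @return data.frame with columns `kind`, `b`, `a1`..`a8`
#' @export
load_inequalities <- function(n_electrons = 4L, n_spin_orbitals = 8L) {
  fn <- sprintf("klyachko_%d_%d.txt", n_electrons, n_spin_orbitals)
  path <- system.file("extdata", fn, package = "ensrep")
  if (!nzchar(path))
    stop("no packaged inequality list for N = ", n_electrons, ", M = ",
         n_spin_orbitals)
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Klyachko (generalized Pauli) pure N-representability audit
#'
#' Evaluates every packaged inequality on the descending eigenvalue vector
#' (padded with zeros up to the inequality arity) and reports how many are
#' satisfied.  A spectrum violating any inequality cannot come from a single
#' N-electron wave function; satisfying all of them certifies that some pure
#' state has this spectrum.
#'
#' @param eigenvalues numeric vector of 1-RDM eigenvalues (any order), or an
#'   [rdm()] with p = 1
#' @param tol slack allowed before an inequality counts as violated
#' @param inequalities optional data.frame overriding [load_inequalities()]
#' @return list with `n_satisfied`, `n_total`, `ok` (all satisfied),
#'   `details` (data.frame with kind, value, bound, margin, satisfied)
#' @export
klyachko_check <- function(eigenvalues, tol = 1e-8, inequalities = NULL) {
  if (inherits(eigenvalues, "rdm")) {
    stopifnot(eigenvalues$p == 1L)
    m <- (eigenvalues$matrix + Conj(t(eigenvalues$matrix))) / 2
    eigenvalues <- Re(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }
  ineq <- if (is.null(inequalities)) load_inequalities() else inequalities
  acols <- grep("^a[0-9]+$", names(ineq))
  arity <- length(acols)
  lam <- sort(as.numeric(eigenvalues), decreasing = TRUE)
  if (length(lam) > arity)
    stop("spectrum has ", length(lam), " eigenvalues; inequalities take ", arity)
  lam <- c(lam, rep(0, arity - length(lam)))
  A <- as.matrix(ineq[, acols])
  val <- as.numeric(A %*% lam)
  margin <- ineq$b - val
  sat <- margin >= -tol
  details <- data.frame(kind = ineq$kind, value = val, bound = ineq$b,
                        margin = margin, satisfied = sat,
                        stringsAsFactors = FALSE)
  list(n_satisfied = sum(sat), n_total = nrow(ineq), ok = all(sat),
       details = details)
}

#' Combined representability audit of a 1-RDM
#'
#' @param x an [rdm()] with p = 1
#' @param tol numerical tolerance
#' @return object of class `audit_report` with the Coleman and Klyachko
#'   results
#' @export
audit_rdm <- function(x, tol = 1e-8) {
  cl <- coleman_check(x, tol)
  kl <- tryCatch(klyachko_check(cl$eigenvalues, tol),
                 error = function(e) NULL)
  structure(list(coleman = cl, klyachko = kl), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n  Coleman (ensemble):",
      if (x$coleman$ok) "satisfied" else paste(x$coleman$violations, collapse = "; "),
      "\n")
  cat("  eigenvalues:", paste(sprintf("%.4f", x$coleman$eigenvalues), collapse = " "), "\n")
  if (!is.null(x$klyachko))
    cat(sprintf("  Klyachko (pure): %d of %d inequalities satisfied\n",
                x$klyachko$n_satisfied, x$klyachko$n_total))
  invisible(x)
}
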