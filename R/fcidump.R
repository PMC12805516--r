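# FCIDUMP reading and writing
# ---------------------------
# Standard FCIDUMP plain-text format: a &FCI NAMELIST header (NORB, NELEC,
# MS2, ORBSYM, ISYM) followed by one record per integral,
#   value i j k l
# with chemist-notation two-electron integrals (ij|kl) for i,j,k,l > 0,
# one-electron h[i,k] as (i, k, 0, 0), and the core (nuclear repulsion)
# energy as (0, 0, 0, 0).  Only the permutationally unique records are
# stored; spatial-orbital indices.

#' Write integrals to an FCIDUMP file
#'
#' @param h one-electron integral matrix (spatial MO basis)
#' @param eri 4-index chemist-notation array `(ij|kl)`
#' @param enuc core energy
#' @param nelec electron count recorded in the header
#' @param file path
#' @param ms2 twice the spin projection recorded in the header
#' @param tol drop records smaller than this in absolute value
#' @return the path, invisibly
#' @export
write_fcidump <- function(h, eri, enuc, nelec, file, ms2 = 0L, tol = 1e-12) {
  n <- nrow(h)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n, nelec, ms2),
               paste0("  ORBSYM=", paste(rep("1,", n), collapse = "")),
               "  ISYM=1,", " &END"), con)
  fmt <- function(v, i, j, k, l) sprintf("%24.16E %3d %3d %3d %3d", v, i, j, k, l)
  out <- character(0)
  # unique (ij|kl): i>=j, k>=l, (ij) >= (kl) as packed pair indices
  pk <- function(i, j) i * (i - 1) / 2 + j
  for (i in seq_len(n)) for (j in seq_len(i))
    for (k in seq_len(n)) for (l in seq_len(k)) {
      if (pk(i, j) < pk(k, l)) next
      v <- eri[i, j, k, l]
      if (abs(v) > tol) out <- c(out, fmt(v, i, j, k, l))
    }
  for (i in seq_len(n)) for (j in seq_len(i))
    if (abs(h[i, j]) > tol) out <- c(out, fmt(h[i, j], i, j, 0L, 0L))
  out <- c(out, fmt(enuc, 0L, 0L, 0L, 0L))
  writeLines(out, con)
  invisible(file)
}

#' Read an FCIDUMP file
#'
#' Restores the full permutational symmetry of the stored unique records
#' (real orbitals: 8-fold for the two-electron integrals, Hermitian for the
#' one-electron part).
#'
#' @param file path
#' @return list with `h`, `eri` (chemist notation), `enuc`, `norb`, `nelec`,
#'   `ms2`
#' @export
read_fcidump <- function(file) {
  lines <- readLines(file)
  hdr_end <- grep("&END|/\\s*$", lines)[1]
  if (is.na(hdr_end)) stop("malformed FCIDUMP: no &END terminator")
  hdr <- paste(lines[seq_len(hdr_end)], collapse = " ")
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*-?[0-9]+"), hdr))
    if (!length(m)) stop("FCIDUMP header lacks ", key)
    as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
  }
  norb <- grab("NORB"); nelec <- grab("NELEC")
  ms2 <- tryCatch(grab("MS2"), error = function(e) 0L)
  h <- matrix(0, norb, norb)
  eri <- array(0, c(norb, norb, norb, norb))
  enuc <- 0
  for (ln in lines[-seq_len(hdr_end)]) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\\s+")[[1]]
    v <- as.numeric(sub("[dD]", "E", f[1]))
    ix <- as.integer(f[2:5])
    i <- ix[1]; j <- ix[2]; k <- ix[3]; l <- ix[4]
    if (i == 0) {
      enuc <- v
    } else if (k == 0) {
      h[i, j] <- v; h[j, i] <- v
    } else {
      for (p in list(c(i, j, k, l), c(j, i, k, l), c(i, j, l, k), c(j, i, l, k),
                     c(k, l, i, j), c(l, k, i, j), c(k, l, j, i), c(l, k, j, i)))
        eri[p[1], p[2], p[3], p[4]] <- v
    }
  }
  list(h = h, eri = eri, enuc = enuc, norb = norb, nelec = nelec, ms2 = ms2)
}
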