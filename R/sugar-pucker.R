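# Furanose ring torsions, Altona-Sundaralingam pseudorotation and named
# pucker classes, and the sugar-phosphate backbone torsions.

PUCKER_WHEEL <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                  "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

# Finer 20-name wheel (envelope/twist alternation at 18-degree spacing).
PUCKER_WHEEL20 <- c("C3'-endo", "C3'-endo-C4'-exo", "C4'-exo",
                    "C4'-exo-O4'-endo", "O4'-endo", "O4'-endo-C1'-exo",
                    "C1'-exo", "C1'-exo-C2'-endo", "C2'-endo",
                    "C2'-endo-C3'-exo", "C3'-exo", "C3'-exo-C4'-endo",
                    "C4'-endo", "C4'-endo-O4'-exo", "O4'-exo",
                    "O4'-exo-C1'-endo", "C1'-endo", "C1'-endo-C2'-exo",
                    "C2'-exo", "C2'-exo-C3'-endo")

#' Furanose ring torsions
#'
#' The five endocyclic torsions of the deoxyribose ring:
#' nu0 = C4'-O4'-C1'-C2', nu1 = O4'-C1'-C2'-C3', nu2 = C1'-C2'-C3'-C4',
#' nu3 = C2'-C3'-C4'-O4', nu4 = C3'-C4'-O4'-C1', each the signed dihedral
#' in (-180, 180].
#'
#' @param residue a `nucleotide` with sugar atoms C1'-C4' and O4'.
#' @return Named numeric `nu0`..`nu4`, degrees.
#' @export
ring_torsions <- function(residue) {
  stopifnot(inherits(residue, "nucleotide"))
  pos <- lapply(SUGAR_RING, residue_atom, res = residue, required = FALSE)
  names(pos) <- SUGAR_RING
  miss <- vapply(pos, is.null, logical(1))
  if (any(miss))
    stop("missing sugar atom(s) in residue ", residue$base, residue$resno,
         ": ", paste(SUGAR_RING[miss], collapse = ", "))
  tors <- function(a, b, c, d) dihedral4(pos[[a]], pos[[b]], pos[[c]],
                                         pos[[d]])
  c(nu0 = tors("C4'", "O4'", "C1'", "C2'"),
    nu1 = tors("O4'", "C1'", "C2'", "C3'"),
    nu2 = tors("C1'", "C2'", "C3'", "C4'"),
    nu3 = tors("C2'", "C3'", "C4'", "O4'"),
    nu4 = tors("C3'", "C4'", "O4'", "C1'"))
}

#' Pseudorotation phase and amplitude
#'
#' Altona-Sundaralingam parameters from the five ring torsions:
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' with the quadrant fixed by the sign of nu2 (so `nu2 / cos(P)` is
#' non-negative).  The amplitude is recovered by orthogonal projection of
#' the torsions onto `nu_j = tau_m * cos(P + 144 (j - 2))`, which equals
#' `nu2 / cos(P)` for an exact sinusoid but remains stable where `cos(P)`
#' vanishes.
#'
#' @param nu named or plain numeric of the five torsions nu0..nu4, degrees.
#' @return Named numeric: `P` (degrees in [0, 360)), `tau_m` (degrees).
#' @export
pseudorotation <- function(nu) {
  nu <- as.numeric(nu)
  stopifnot(length(nu) == 5)
  if (all(abs(nu) < 1e-9))
    stop("planar ring: pseudorotation phase undefined")
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * DEG) + sin(72 * DEG))
  P <- atan2(num, den) / DEG  # quadrant follows the sign of nu2 via den
  # amplitude by orthogonal projection onto the cosine/sine components of
  # nu_j = tau_m cos(P + 144 (j - 2)); equals nu2 / cos(P) for an exact
  # sinusoid but stays stable where cos(P) vanishes (P near 90/270)
  j <- 144 * ((0:4) - 2) * DEG
  a <- sum(nu * cos(j)) / sum(cos(j)^2)
  b <- sum(nu * sin(j)) / sum(sin(j)^2)
  tau <- sqrt(a^2 + b^2)
  P <- P %% 360
  c(P = P, tau_m = tau)
}

#' Named pucker class of a pseudorotation phase
#'
#' The pseudorotation wheel is divided into 36-degree sectors centred at
#' 18 + 36 k degrees (C3'-endo at 18, C4'-exo at 54, O4'-endo at 90,
#' C1'-exo at 126, C2'-endo at 162, C3'-exo at 198, ...), each half-open
#' `[centre - 18, centre + 18)`.  `fine = TRUE` switches to the 20-name
#' wheel of 18-degree sectors.
#'
#' @param P pseudorotation phase, degrees in [0, 360); vectorized.
#' @param fine use the finer 20-class wheel.
#' @return Character vector of conformer names.
#' @export
classify_pucker <- function(P, fine = FALSE) {
  P <- as.numeric(P) %% 360
  if (fine) {
    idx <- floor(((P - 9) %% 360) / 18) + 1
    PUCKER_WHEEL20[idx]
  } else {
    idx <- floor(P / 36) + 1
    PUCKER_WHEEL[idx]
  }
}

#' Pucker analysis of one residue
#'
#' @param residue a `nucleotide`.
#' @param fine use the 20-class wheel in the label.
#' @return Object of class `pucker_result`: list with `nu` (named numeric),
#'   `P`, `tau_m`, `label`.
#' @export
sugar_pucker <- function(residue, fine = FALSE) {
  nu <- ring_torsions(residue)
  ps <- pseudorotation(nu)
  structure(list(nu = nu, P = unname(ps["P"]), tau_m = unname(ps["tau_m"]),
                 label = classify_pucker(ps["P"], fine = fine)),
            class = "pucker_result")
}

#' @export
print.pucker_result <- function(x, ...) {
  cat("<pucker_result> P = ", sprintf("%.1f", x$P), " deg, tau_m = ",
      sprintf("%.1f", x$tau_m), " deg (", x$label, ")\n", sep = "")
  invisible(x)
}

#' Backbone and glycosidic torsions of a strand
#'
#' alpha (O3'[i-1]-P-O5'-C5'), beta (P-O5'-C5'-C4'), gamma
#' (O5'-C5'-C4'-C3'), delta (C5'-C4'-C3'-O3'), epsilon
#' (C4'-C3'-O3'-P[i+1]), zeta (C3'-O3'-P[i+1]-O5'[i+1]) and chi
#' (O4'-C1'-N9-C4 for purines, O4'-C1'-N1-C2 for pyrimidines).  Angles at
#' chain termini or with missing atoms are returned as `NA` with a warning,
#' not as errors.
#'
#' @param structure a [nucleic_structure()].
#' @param chain chain identifier.
#' @param model model number.
#' @return data.frame with columns `resno`, `base`, `alpha`..`zeta`, `chi`
#'   (degrees in (-180, 180] or `NA`).
#' @export
backbone_torsions <- function(structure, chain, model = 1) {
  res <- strand_residues(structure, chain, model)
  n <- length(res)
  get <- function(i, name) {
    if (i < 1 || i > n) return(NULL)
    residue_atom(res[[i]], name, required = FALSE)
  }
  tors <- function(a, b, c, d) {
    if (is.null(a) || is.null(b) || is.null(c) || is.null(d))
      return(NA_real_)
    dihedral4(a, b, c, d)
  }
  miss <- FALSE
  rows <- lapply(seq_len(n), function(i) {
    r <- res[[i]]
    gl <- GLYCOSIDIC[[r$base]]
    vals <- c(
      alpha = tors(get(i - 1, "O3'"), get(i, "P"), get(i, "O5'"),
                   get(i, "C5'")),
      beta = tors(get(i, "P"), get(i, "O5'"), get(i, "C5'"), get(i, "C4'")),
      gamma = tors(get(i, "O5'"), get(i, "C5'"), get(i, "C4'"),
                   get(i, "C3'")),
      delta = tors(get(i, "C5'"), get(i, "C4'"), get(i, "C3'"),
                   get(i, "O3'")),
      epsilon = tors(get(i, "C4'"), get(i, "C3'"), get(i, "O3'"),
                     get(i + 1, "P")),
      zeta = tors(get(i, "C3'"), get(i, "O3'"), get(i + 1, "P"),
                  get(i + 1, "O5'")),
      chi = tors(get(i, "O4'"), get(i, "C1'"), get(i, gl[["N"]]),
                 get(i, gl[["ref"]])))
    # termini are expected to lack alpha/epsilon/zeta; only interior gaps
    # are surprising
    interior_na <- (i > 1 && is.na(vals["alpha"])) ||
      any(is.na(vals[c("beta", "gamma", "delta", "chi")]))
    if (interior_na) miss <<- TRUE
    data.frame(resno = r$resno, base = r$base, t(vals),
               stringsAsFactors = FALSE)
  })
  if (miss)
    warning("missing backbone atoms: some torsions returned as NA")
  do.call(rbind, rows)
}
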