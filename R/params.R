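# Shipped parameter tables: standard base templates, fiber-model step
# parameters, atomic masses, ring-atom definitions and donor/acceptor
# chemistry.  Templates live in inst/extdata as documented TSV files and are
# parsed once per session into a package-local cache.

.nucgeom_cache <- new.env(parent = emptyenv())

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Ring atoms entering the least-squares frame fit (exocyclic substituents
# are part of the base but excluded from the fit).
RING_ATOMS <- list(
  A = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  G = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

# Glycosidic nitrogen and the chi reference atom (O4'-C1'-N9-C4 purines,
# O4'-C1'-N1-C2 pyrimidines).
GLYCOSIDIC <- list(
  A = c(N = "N9", ref = "C4"), G = c(N = "N9", ref = "C4"),
  C = c(N = "N1", ref = "C2"), T = c(N = "N1", ref = "C2")
)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

# Base hydrogen-bond donors: donor nitrogen -> heavy neighbours in the base
# (one neighbour = rotatable amino group carrying two H, two neighbours =
# ring imino carrying one H).
BASE_DONORS <- list(
  A = list(N6 = "C6"),
  C = list(N4 = "C4"),
  G = list(N1 = c("C2", "C6"), N2 = "C2"),
  T = list(N3 = c("C2", "C4"))
)

# Conventional base acceptors (used by the mock-trajectory generator when
# staging hydrogen-bond events; the detector itself scans all N/O atoms).
BASE_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"),
  C = c("O2", "N3"),
  G = c("O6", "N3", "N7"),
  T = c("O2", "O4")
)

SUGAR_RING <- c("C1'", "C2'", "C3'", "C4'", "O4'")
BACKBONE_ATOMS <- c("P", "O5'", "C5'", "O3'")

extdata_file <- function(name) {
  path <- system.file("extdata", name, package = "nucgeom")
  if (!nzchar(path)) stop("parameter file not found: ", name)
  path
}

#' Standard base template
#'
#' Heavy-atom coordinates of one canonical base (plus the C1' anchor)
#' expressed in the standard base reference frame, read from the shipped
#' template table.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z`.
#' @export
standard_base <- function(base) {
  base <- match.arg(base, c("A", "C", "G", "T"))
  key <- "standard_bases"
  if (is.null(.nucgeom_cache[[key]])) {
    tab <- utils::read.table(extdata_file("standard_bases.tsv"),
                             header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, comment.char = "#")
    .nucgeom_cache[[key]] <- tab
  }
  tab <- .nucgeom_cache[[key]]
  out <- tab[tab$base == base, c("atom", "element", "x", "y", "z")]
  names(out)[1] <- "name"
  rownames(out) <- NULL
  out
}

#' Fiber-model step parameters
#'
#' Uniform per-step rigid-body coordinates and sugar descriptors of the
#' canonical A and B fiber families, read from the shipped parameter table.
#'
#' @param form `"A"` or `"B"`.
#' @return list with `step` (named numeric: shift, slide, rise, tilt, roll,
#'   twist), `pucker_P`, `pucker_tau`, `chi`.
#' @export
fiber_parameters <- function(form) {
  form <- match.arg(toupper(form), c("A", "B"))
  key <- "fiber_steps"
  if (is.null(.nucgeom_cache[[key]])) {
    .nucgeom_cache[[key]] <- utils::read.table(
      extdata_file("fiber_steps.tsv"), header = TRUE, sep = "\t",
      quote = "", stringsAsFactors = FALSE, comment.char = "#")
  }
  tab <- .nucgeom_cache[[key]]
  row <- tab[tab$form == form, ]
  if (nrow(row) != 1) stop("unknown fiber form: ", form)
  list(step = c(shift = row$shift, slide = row$slide, rise = row$rise,
                tilt = row$tilt, roll = row$roll, twist = row$twist),
       pucker_P = row$pucker_P, pucker_tau = row$pucker_tau, chi = row$chi,
       delta = row$delta)
}

atom_mass <- function(element) {
  m <- ATOMIC_MASS[element]
  if (anyNA(m)) stop("no mass tabulated for element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# Expected element for a PDB atom name (first alphabetic character that is
# not a prime/digit; handles C1', O4', N9, P, C7, H41, ...).
element_from_name <- function(name) {
  el <- sub("^[0-9']*", "", name)
  substr(el, 1, 1)
}
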