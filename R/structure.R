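# Core data model: a nucleic-acid structure is a fixed atom topology plus
# one or more coordinate models (snapshots) sharing that topology, the
# layout used for NMR ensembles and trajectory output alike.

#' Construct a nucleic-acid structure
#'
#' @param atoms data.frame with one row per atom and columns `name`
#'   (PDB-style atom name, primed dialect), `element`, `chain`, `resno`
#'   (1-based residue index along the strand, 5'->3') and `base` (one of
#'   A/C/G/T).
#' @param models list of numeric n_atoms x 3 coordinate matrices (Angstrom),
#'   one per model; all models share the `atoms` topology.
#' @return An object of class `nucleic_structure`.
#' @export
nucleic_structure <- function(atoms, models) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "chain", "resno", "base") %in%
                  names(atoms)))
  if (!is.list(models) || length(models) < 1)
    stop("'models' must be a non-empty list of coordinate matrices")
  models <- lapply(models, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 3 || nrow(m) != nrow(atoms))
      stop("model coordinate matrix must be n_atoms x 3")
    if (!all(is.finite(m))) stop("non-finite coordinates in model")
    dimnames(m) <- NULL
    m
  })
  bad <- !atoms$base %in% c("A", "C", "G", "T")
  if (any(bad))
    stop("unknown base(s): ", paste(unique(atoms$base[bad]), collapse = ", "))
  atoms$name <- as.character(atoms$name)
  atoms$element <- as.character(atoms$element)
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, models = models,
                 chains = unique(atoms$chain)),
            class = "nucleic_structure")
}

#' @export
print.nucleic_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<nucleic_structure> ", length(x$chains), " strand(s), ",
      nrow(rt), " residues, ", nrow(x$atoms), " atoms, ",
      n_models(x), " model(s)\n", sep = "")
  for (ch in x$chains) {
    seq <- paste(rt$base[rt$chain == ch], collapse = "")
    cat("  strand ", ch, " 5'-", seq, "-3'\n", sep = "")
  }
  invisible(x)
}

#' Number of coordinate models
#' @param structure a `nucleic_structure`.
#' @return integer model count.
#' @export
n_models <- function(structure) length(structure$models)

#' Residue table of a structure
#'
#' @param structure a `nucleic_structure`.
#' @return data.frame with columns `chain`, `resno`, `base`, one row per
#'   residue in strand order (5'->3' within each chain).
#' @export
residue_table <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno)
  idx <- !duplicated(key)
  out <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                    base = a$base[idx], stringsAsFactors = FALSE)
  out[order(match(out$chain, structure$chains), out$resno), , drop = FALSE]
}

#' Extract one nucleotide residue
#'
#' @param structure a `nucleic_structure`.
#' @param chain chain identifier.
#' @param resno residue index within the chain.
#' @param model model number (default 1).
#' @return An object of class `nucleotide`: list with `base`, `chain`,
#'   `resno` and `atoms` (data.frame `name`, `element`, `x`, `y`, `z`).
#' @export
get_residue <- function(structure, chain, resno, model = 1) {
  sel <- structure$atoms$chain == chain & structure$atoms$resno == resno
  if (!any(sel)) stop("no residue ", resno, " in chain ", chain)
  xyz <- structure$models[[model]][sel, , drop = FALSE]
  at <- structure$atoms[sel, c("name", "element"), drop = FALSE]
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  rownames(at) <- NULL
  structure(list(base = structure$atoms$base[sel][1], chain = chain,
                 resno = as.integer(resno), atoms = at),
            class = "nucleotide")
}

#' @export
print.nucleotide <- function(x, ...) {
  cat("<nucleotide> ", x$base, " chain ", x$chain, " resno ", x$resno,
      " (", nrow(x$atoms), " atoms)\n", sep = "")
  invisible(x)
}

#' All residues of a strand
#'
#' @inheritParams get_residue
#' @return list of `nucleotide` objects in 5'->3' order.
#' @export
strand_residues <- function(structure, chain, model = 1) {
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  lapply(rt$resno, function(i) get_residue(structure, chain, i, model))
}

# Coordinates of one named atom of a nucleotide; errors with residue/atom
# context when absent (used by end_to_end and the torsion code).
residue_atom <- function(res, name, required = TRUE) {
  i <- match(name, res$atoms$name)
  if (is.na(i)) {
    if (required)
      stop("atom ", name, " missing in residue ", res$base, res$resno,
           " (chain ", res$chain, ")")
    return(NULL)
  }
  as.numeric(res$atoms[i, c("x", "y", "z")])
}

# Base atoms of a residue (ring + exocyclic substituents, sugar and
# phosphate excluded); optionally with hydrogens.
base_atoms <- function(res, hydrogens = TRUE) {
  nm <- res$atoms$name
  is_sugar <- grepl("'", nm, fixed = TRUE) | nm %in% c("P", "OP1", "OP2")
  keep <- !is_sugar
  if (!hydrogens) keep <- keep & res$atoms$element != "H"
  res$atoms[keep, , drop = FALSE]
}

#' Sequence of a strand
#' @inheritParams get_residue
#' @return character scalar, bases 5'->3'.
#' @export
strand_sequence <- function(structure, chain) {
  rt <- residue_table(structure)
  paste(rt$base[rt$chain == chain], collapse = "")
}

# Validate duplex pairing: equal lengths and antiparallel complementary
# sequences (strand II residue k pairs strand I residue n + 1 - k).
check_duplex <- function(structure, allow_mismatch = FALSE) {
  if (length(structure$chains) != 2)
    stop("duplex operation requires a two-strand structure")
  s1 <- strand_sequence(structure, structure$chains[1])
  s2 <- strand_sequence(structure, structure$chains[2])
  if (nchar(s1) != nchar(s2))
    stop("duplex strands differ in length (", nchar(s1), " vs ",
         nchar(s2), ")")
  if (!identical(reverse_complement(s1), s2) && !allow_mismatch)
    stop("strands are not antiparallel complements; ",
         "use allow_mismatch = TRUE to override")
  invisible(TRUE)
}
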