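# PDB input/output (via bio3d) and the compact sequence mini-language.

RESIDUE_ALIASES <- c(
  DA = "A", DC = "C", DG = "G", DT = "T",
  A = "A", C = "C", G = "G", T = "T",
  DA5 = "A", DC5 = "C", DG5 = "G", DT5 = "T",
  DA3 = "A", DC3 = "C", DG3 = "G", DT3 = "T",
  ADE = "A", CYT = "C", GUA = "G", THY = "T"
)

SOLVENT_RESIDUES <- c("HOH", "WAT", "NA", "MG", "K", "CL", "ZN", "MN")

# Normalize atom-name dialects: asterisk primes (legacy entries) to primed
# form, O1P/O2P to OP1/OP2, thymine C5M to C7.
normalize_atom_name <- function(name) {
  name <- gsub("*", "'", trimws(name), fixed = TRUE)
  name[name == "O1P"] <- "OP1"
  name[name == "O2P"] <- "OP2"
  name[name == "C5M"] <- "C7"
  name
}

#' Expand a compact sequence specification
#'
#' Parses the compact notation in which a digit run repeats the immediately
#' preceding base: `"A2C2A2"` expands to `"AACCAA"`, `"CTG4ACT3C2AG2"` to
#' `"CTGGGGACTTTCCAGG"`.
#'
#' @param spec character scalar over bases `A`, `C`, `G`, `T`, each
#'   optionally followed by a positive integer repeat count.
#' @return Expanded base string, 5'->3'.
#' @export
#' @examples
#' parse_sequence_spec("C6")
#' parse_sequence_spec("A2C2A2")
parse_sequence_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  chars <- strsplit(spec, "")[[1]]
  if (length(chars) == 0) stop("empty sequence specification")
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    b <- chars[i]
    if (!b %in% c("A", "C", "G", "T"))
      stop("malformed sequence spec at position ", i, ": '", b,
           "' (expected one of A, C, G, T)")
    j <- i + 1
    while (j <= length(chars) && grepl("[0-9]", chars[j])) j <- j + 1
    n <- 1L
    if (j > i + 1) {
      n <- as.integer(paste(chars[(i + 1):(j - 1)], collapse = ""))
      if (is.na(n) || n < 1)
        stop("malformed repeat count at position ", i + 1)
    }
    out <- c(out, rep(b, n))
    i <- j
  }
  paste(out, collapse = "")
}

#' Reverse complement of a base string
#' @param seq character scalar over A/C/G/T.
#' @return The Watson-Crick reverse complement, 5'->3'.
#' @export
reverse_complement <- function(seq) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  chars <- rev(strsplit(seq, "")[[1]])
  bad <- !chars %in% names(comp)
  if (any(bad)) stop("unknown base(s): ", paste(unique(chars[bad]),
                                                collapse = ", "))
  paste(comp[chars], collapse = "")
}

#' Read a nucleic-acid structure from a PDB file
#'
#' Reads ATOM/HETATM records (MODEL/ENDMDL blocks become coordinate
#' models), maps canonical deoxynucleotide residue names (DA/DC/DG/DT,
#' bare-letter and 5'/3'-terminal variants) to the four bases, normalizes
#' legacy atom-name dialects (`C1*` -> `C1'`), drops common solvent/ion
#' residues, and renumbers residues 1..n per chain in the 5'->3' direction.
#' Strand direction is inferred from O3'(i)->P(i+1) connectivity, falling
#' back to author ordering when phosphates are absent.
#'
#' @param path PDB file path.
#' @param model_limit optional maximum number of models to retain.
#' @return A [nucleic_structure()].
#' @export
read_structure <- function(path, model_limit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  resid <- toupper(trimws(at$resid))
  keep <- !resid %in% SOLVENT_RESIDUES
  at <- at[keep, , drop = FALSE]
  resid <- resid[keep]
  if (nrow(at) == 0) stop("no nucleic-acid atoms in ", path)
  base <- RESIDUE_ALIASES[resid]
  if (anyNA(base)) {
    bad <- unique(resid[is.na(base)])
    stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (anyNA(xyz))
    stop("models with inconsistent atom records in ", path)
  keep_xyz <- as.vector(t(outer(which(keep), c(2, 1, 0),
                                function(i, o) 3 * i - o)))
  xyz <- xyz[, keep_xyz, drop = FALSE]
  if (!is.null(model_limit)) {
    model_limit <- as.integer(model_limit)
    xyz <- xyz[seq_len(min(nrow(xyz), model_limit)), , drop = FALSE]
  }
  chain <- as.character(at$chain)
  chain[is.na(chain) | chain == ""] <- "A"
  name <- normalize_atom_name(at$elety)
  element <- trimws(as.character(at$elesy))
  no_el <- is.na(element) | element == ""
  element[no_el] <- element_from_name(name[no_el])
  # group atoms into residues by (chain, author resno, insert)
  key <- paste(chain, at$resno, at$insert)
  res_first <- !duplicated(key)
  res_key <- match(key, key[res_first])
  atoms <- data.frame(name = name, element = element, chain = chain,
                      resno = res_key, base = unname(base),
                      stringsAsFactors = FALSE)
  # renumber per chain in author order, then fix direction per chain
  models <- lapply(seq_len(nrow(xyz)), function(m)
    matrix(xyz[m, ], ncol = 3, byrow = TRUE))
  atoms_resno <- integer(nrow(atoms))
  order_out <- integer(0)
  for (ch in unique(chain)) {
    sel <- which(atoms$chain == ch)
    rk <- unique(atoms$resno[sel])
    rk <- rk[order(match(rk, atoms$resno[sel]))]
    rk <- orient_strand(atoms, models[[1]], ch, rk)
    for (i in seq_along(rk)) {
      ri <- sel[atoms$resno[sel] == rk[i]]
      atoms_resno[ri] <- i
      order_out <- c(order_out, ri)
    }
  }
  atoms$resno <- atoms_resno
  atoms <- atoms[order_out, , drop = FALSE]
  models <- lapply(models, function(m) m[order_out, , drop = FALSE])
  nucleic_structure(atoms, models)
}

# Decide 5'->3' residue order of one chain from O3'(i) -> P(i+1) covalent
# connectivity (< 2.0 A); author ordering is kept when phosphates are
# absent or connectivity is inconclusive.
orient_strand <- function(atoms, xyz, ch, res_keys) {
  if (length(res_keys) < 2) return(res_keys)
  pos_of <- function(key, name) {
    i <- which(atoms$chain == ch & atoms$resno == key & atoms$name == name)
    if (length(i) == 0) return(NULL)
    xyz[i[1], ]
  }
  score <- function(keys) {
    s <- 0
    for (i in seq_len(length(keys) - 1)) {
      o3 <- pos_of(keys[i], "O3'")
      p <- pos_of(keys[i + 1], "P")
      if (!is.null(o3) && !is.null(p) && vnorm(o3 - p) < 2.0) s <- s + 1
    }
    s
  }
  fwd <- score(res_keys)
  rev_ <- score(rev(res_keys))
  if (rev_ > fwd) rev(res_keys) else res_keys
}

#' Write a nucleic-acid structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks.  Coordinates
#' are emitted at PDB fixed-width precision (1e-3 Angstrom), so a
#' write/read round trip reproduces the structure to that precision.
#'
#' @param structure a [nucleic_structure()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "nucleic_structure"))
  n <- nrow(structure$atoms)
  if (n > 99999)
    stop("structure has ", n, " atoms; PDB serial field overflows at 99999")
  xyz <- do.call(rbind, lapply(structure$models, function(m) as.vector(t(m))))
  bio3d::write.pdb(file = path,
                   xyz = xyz,
                   resno = structure$atoms$resno,
                   resid = paste0("D", structure$atoms$base),
                   chain = structure$atoms$chain,
                   elety = structure$atoms$name,
                   elesy = structure$atoms$element)
  invisible(path)
}
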