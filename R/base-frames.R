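# Base reference frames: least-squares fit of the standard base geometry to
# observed ring atoms.  The frame's z-axis is the base normal entering the
# stacking criterion; chained frames feed the step-parameter algorithm.

#' Construct a base frame object
#'
#' @param origin length-3 numeric, Angstrom.
#' @param axes 3x3 proper rotation; columns are the frame x, y, z axes.
#' @param fit_rmsd non-negative fit residual, Angstrom.
#' @param residue_ref identifier of the fitted residue (free-form).
#' @return Object of class `base_frame`.
#' @export
base_frame <- function(origin, axes, fit_rmsd = 0, residue_ref = NA) {
  axes <- as.matrix(axes)
  if (!is_rotation(axes))
    stop("axes must be a proper rotation (orthonormal, det +1)")
  structure(list(origin = as.numeric(origin), axes = axes,
                 fit_rmsd = fit_rmsd, residue_ref = residue_ref),
            class = "base_frame")
}

#' @export
print.base_frame <- function(x, ...) {
  cat("<base_frame> origin (", paste(sprintf("%.3f", x$origin),
                                     collapse = ", "),
      ") fit_rmsd ", sprintf("%.4f", x$fit_rmsd), "\n", sep = "")
  invisible(x)
}

#' Fit the standard base reference frame to a residue
#'
#' Least-squares (Kabsch) superposition of the standard base's ring atoms,
#' in their embedded reference frame, onto the observed ring atoms.  The
#' recovered rotation and translation are the frame axes and origin; mirror
#' solutions are rejected so the rotation is always proper.
#'
#' @param residue a `nucleotide` (see [get_residue()]).
#' @return A [base_frame()] with the superposition residual in `fit_rmsd`.
#' @export
fit_base_frame <- function(residue) {
  stopifnot(inherits(residue, "nucleotide"))
  ring <- RING_ATOMS[[residue$base]]
  std <- standard_base(residue$base)
  idx_obs <- match(ring, residue$atoms$name)
  if (anyNA(idx_obs))
    stop("missing ring atom(s) in residue ", residue$base, residue$resno,
         ": ", paste(ring[is.na(idx_obs)], collapse = ", "))
  obs <- as.matrix(residue$atoms[idx_obs, c("x", "y", "z")])
  ref <- as.matrix(std[match(ring, std$name), c("x", "y", "z")])
  fit <- kabsch(ref, obs)
  base_frame(origin = fit$t, axes = fit$R, fit_rmsd = fit$rmsd,
             residue_ref = paste0(residue$base, residue$resno, ":",
                                  residue$chain))
}

#' Unit normal of a base plane
#'
#' Least-squares plane normal through the ring heavy atoms, sign-matched to
#' the fitted frame z-axis.
#'
#' @param residue a `nucleotide`.
#' @return Unit length-3 vector.
#' @export
base_normal <- function(residue) {
  stopifnot(inherits(residue, "nucleotide"))
  ring <- RING_ATOMS[[residue$base]]
  idx <- match(ring, residue$atoms$name)
  if (anyNA(idx))
    stop("missing ring atom(s): ", paste(ring[is.na(idx)], collapse = ", "))
  xyz <- as.matrix(residue$atoms[idx, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  if (sv$d[2] < 1e-8)
    stop("degenerate (collinear) ring coordinates")
  n <- sv$v[, 3]
  z <- fit_base_frame(residue)$axes[, 3]
  if (sum(n * z) < 0) n <- -n
  unitv(n)
}

#' Geometric or mass-weighted center of a base
#'
#' Center of the nucleobase atoms (ring plus exocyclic substituents;
#' sugar and phosphate excluded).  Hydrogens are included when present.
#'
#' @param residue a `nucleotide`.
#' @param mass_weighted if `TRUE` (default) weight by standard atomic
#'   masses (center of mass); if `FALSE` the plain centroid.
#' @param hydrogens include hydrogens when present (default `TRUE`).
#' @return Length-3 numeric position.
#' @export
base_center <- function(residue, mass_weighted = TRUE, hydrogens = TRUE) {
  stopifnot(inherits(residue, "nucleotide"))
  at <- base_atoms(residue, hydrogens = hydrogens)
  if (nrow(at) == 0) stop("residue has no base atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  w <- if (mass_weighted) atom_mass(at$element) else rep(1, nrow(at))
  unname(colSums(xyz * w) / sum(w))
}

#' Watson-Crick base-pair frame
#'
#' The strand-II frame is flipped to the strand-I convention (y and z axes
#' negated, a 180-degree rotation about x) and the pair frame is the rigid
#' mean of the two: average origin, rotation midway along the geodesic
#' between the two orientations.
#'
#' @param frame_i,frame_j [base_frame()]s of paired bases on antiparallel
#'   strands (`frame_j` from strand II).
#' @return A [base_frame()] for the pair.
#' @export
pair_frame <- function(frame_i, frame_j) {
  stopifnot(inherits(frame_i, "base_frame"), inherits(frame_j, "base_frame"))
  flip <- diag(c(1, -1, -1))
  Rj <- frame_j$axes %*% flip
  if (sum(frame_i$axes[, 3] * Rj[, 3]) < 0)
    stop("z-axes subtend more than 90 degrees after flipping: ",
         "not a valid Watson-Crick pair")
  Rm <- rotation_mean(frame_i$axes, Rj)
  base_frame(origin = (frame_i$origin + frame_j$origin) / 2, axes = Rm,
             fit_rmsd = 0,
             residue_ref = paste(frame_i$residue_ref, frame_j$residue_ref,
                                 sep = "+"))
}

# Geodesic mean of two rotations: rotate R1 halfway along the relative
# rotation R2 R1^T (symmetric in its arguments up to numerical noise).
rotation_mean <- function(R1, R2) {
  rel <- R2 %*% t(R1)
  aa <- axis_angle(rel)
  rot_about(aa$axis, aa$angle / 2) %*% R1
}

#' Fit frames along a strand
#'
#' @param structure a [nucleic_structure()].
#' @param chain chain identifier.
#' @param model model number.
#' @return list of [base_frame()]s, 5'->3'.
#' @export
fit_frames <- function(structure, chain, model = 1) {
  lapply(strand_residues(structure, chain, model), fit_base_frame)
}

#' Idealized base hydrogens
#'
#' Adds amino/imino hydrogens to the nucleobase nitrogens of every residue
#' at idealized sp2 positions (N-H 1.01 Angstrom, in the base plane),
#' enabling hydrogen-bond detection on structures lacking explicit
#' hydrogens.  Residues already carrying hydrogens are left untouched.
#'
#' @param structure a [nucleic_structure()].
#' @return A new `nucleic_structure` with hydrogens appended per residue.
#' @export
add_base_hydrogens <- function(structure) {
  stopifnot(inherits(structure, "nucleic_structure"))
  atoms <- structure$atoms
  nm <- n_models(structure)
  new_atoms <- list(); new_xyz <- lapply(seq_len(nm), function(i) list())
  rt <- residue_table(structure)
  for (r in seq_len(nrow(rt))) {
    sel <- which(atoms$chain == rt$chain[r] & atoms$resno == rt$resno[r])
    new_atoms[[length(new_atoms) + 1]] <- atoms[sel, , drop = FALSE]
    for (m in seq_len(nm))
      new_xyz[[m]][[length(new_xyz[[m]]) + 1]] <-
        structure$models[[m]][sel, , drop = FALSE]
    if (any(atoms$element[sel] == "H")) next
    for (m in seq_len(nm)) {
      res <- get_residue(structure, rt$chain[r], rt$resno[r], m)
      h <- idealized_hydrogens(res)
      if (m == 1 && nrow(h) > 0) {
        new_atoms[[length(new_atoms) + 1]] <- data.frame(
          name = h$name, element = "H", chain = rt$chain[r],
          resno = rt$resno[r], base = rt$base[r], stringsAsFactors = FALSE)
      }
      if (nrow(h) > 0)
        new_xyz[[m]][[length(new_xyz[[m]]) + 1]] <-
          as.matrix(h[, c("x", "y", "z")])
    }
  }
  nucleic_structure(do.call(rbind, new_atoms),
                    lapply(new_xyz, function(l) do.call(rbind, l)))
}

# sp2 hydrogen positions for the donor nitrogens of one residue.
# Amino N (one heavy neighbour): two in-plane H at 120 degrees from the
# C-N bond; ring imino N (two neighbours): one H along the external
# bisector.  Returns data.frame(name, x, y, z).
idealized_hydrogens <- function(res) {
  donors <- BASE_DONORS[[res$base]]
  out <- list()
  z <- tryCatch(base_normal(res), error = function(e) NULL)
  for (dn in names(donors)) {
    N <- residue_atom(res, dn, required = FALSE)
    if (is.null(N)) next
    nb <- donors[[dn]]
    nbpos <- lapply(nb, residue_atom, res = res, required = FALSE)
    if (any(vapply(nbpos, is.null, logical(1)))) next
    if (length(nbpos) == 2) {
      u <- -(unitv(nbpos[[1]] - N) + unitv(nbpos[[2]] - N))
      h <- N + 1.01 * unitv(u)
      out[[length(out) + 1]] <- data.frame(
        name = paste0("H", sub("^N", "", dn)),
        x = h[1], y = h[2], z = h[3])
    } else {
      u <- unitv(N - nbpos[[1]])
      if (is.null(z)) next
      for (k in 1:2) {
        Rk <- rot_about(z, c(60, -60)[k])
        h <- N + 1.01 * as.vector(Rk %*% u)
        out[[length(out) + 1]] <- data.frame(
          name = paste0("H", sub("^N", "", dn), k),
          x = h[1], y = h[2], z = h[3])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(name = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0)))
  do.call(rbind, out)
}
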