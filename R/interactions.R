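# Geometric detection of base-base stacking and inter-base hydrogen bonds,
# and their aggregation over multi-model trajectories.
#
# Stacking criteria (all three required, strict inequalities):
#   (i)  minimum distance between any pair of base heavy atoms < 4 A;
#   (ii) distance between the base centers of mass < 5 A;
#   (iii) angle between the base-plane normals in [0, 45) or (135, 180] deg.
# Hydrogen-bond criteria for X...H-Y with X, Y base N/O heteroatoms of
# different nucleobases and H covalently bound to Y (< 1.2 A):
#   (i)  d(X, Y) < 3.3 A;  (ii) angle X-H-Y in (150, 180] degrees.

#' Default geometric thresholds
#'
#' @return Named list: `heavy` (4 Angstrom), `center` (5 Angstrom),
#'   `normal` (45 degrees; the allowed windows are `[0, normal)` and
#'   `(180 - normal, 180]`), `hbond_dist` (3.3 Angstrom), `hbond_angle`
#'   (150 degrees).
#' @export
default_thresholds <- function() {
  list(heavy = 4, center = 5, normal = 45, hbond_dist = 3.3,
       hbond_angle = 150)
}

#' Stacking test for two nucleobases
#'
#' Evaluates the three geometric stacking criteria; all diagnostics are
#' reported whether or not the pair is stacked.
#'
#' @param res_i,res_j `nucleotide` objects.
#' @param thresholds see [default_thresholds()].
#' @param mass_weighted use mass-weighted base centers (default) rather
#'   than plain centroids.
#' @return Object of class `stack_record`: list with `pair` (the two
#'   residue labels), `stacked`, `min_heavy_distance`, `center_distance`,
#'   `normal_angle` (degrees in [0, 180]).
#' @export
is_stacked <- function(res_i, res_j, thresholds = default_thresholds(),
                       mass_weighted = TRUE) {
  stopifnot(inherits(res_i, "nucleotide"), inherits(res_j, "nucleotide"))
  hi <- base_atoms(res_i, hydrogens = FALSE)
  hj <- base_atoms(res_j, hydrogens = FALSE)
  xi <- as.matrix(hi[, c("x", "y", "z")])
  xj <- as.matrix(hj[, c("x", "y", "z")])
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)
  min_d <- sqrt(max(min(d2), 0))
  ci <- base_center(res_i, mass_weighted = mass_weighted)
  cj <- base_center(res_j, mass_weighted = mass_weighted)
  cd <- vnorm(ci - cj)
  ang <- normal_angle(base_normal(res_i), base_normal(res_j))
  stacked <- (min_d < thresholds$heavy) && (cd < thresholds$center) &&
    (ang < thresholds$normal || ang > 180 - thresholds$normal)
  structure(list(pair = c(paste0(res_i$base, res_i$resno, ":", res_i$chain),
                          paste0(res_j$base, res_j$resno, ":", res_j$chain)),
                 stacked = stacked, min_heavy_distance = min_d,
                 center_distance = cd, normal_angle = ang),
            class = "stack_record")
}

#' @export
print.stack_record <- function(x, ...) {
  cat("<stack_record> ", x$pair[1], " / ", x$pair[2], ": ",
      if (x$stacked) "stacked" else "not stacked",
      sprintf(" (min %.2f A, centers %.2f A, normals %.1f deg)\n",
              x$min_heavy_distance, x$center_distance, x$normal_angle),
      sep = "")
  invisible(x)
}

# fold the angle between two (unsigned) plane normals into [0, 180]
normal_angle <- function(n1, n2) {
  ca <- min(1, max(-1, sum(unitv(n1) * unitv(n2))))
  acos(ca) / DEG
}

#' Inter-base hydrogen bonds in one model
#'
#' Reports every X...H-Y triple with X and Y nitrogen/oxygen heteroatoms of
#' different nucleobases, H covalently bound to Y, d(X, Y) below the
#' distance threshold and the X-H-Y angle above the angular threshold.
#'
#' @param structure a [nucleic_structure()].
#' @param model model number.
#' @param thresholds see [default_thresholds()].
#' @param idealize_h add idealized base hydrogens on the fly when the
#'   structure carries none.
#' @return data.frame with one row per bond: `donor_chain`, `donor_resno`,
#'   `donor_atom` (Y), `h_atom`, `acceptor_chain`, `acceptor_resno`,
#'   `acceptor_atom` (X), `distance_XY` (Angstrom), `angle_XHY` (degrees).
#' @export
find_hbonds <- function(structure, model = 1,
                        thresholds = default_thresholds(),
                        idealize_h = FALSE) {
  stopifnot(inherits(structure, "nucleic_structure"))
  if (!any(structure$atoms$element == "H")) {
    if (!idealize_h)
      stop("structure carries no hydrogens; supply explicit hydrogens or ",
           "set idealize_h = TRUE to place idealized base hydrogens")
    structure <- add_base_hydrogens(structure)
  }
  top <- hbond_topology(structure)
  hbonds_for_model(structure$models[[model]], top, thresholds)
}

# Precompute the donor (Y, H) pairs and acceptor candidates of a topology;
# covalent H-Y assignment uses the first model's geometry (< 1.2 A).
hbond_topology <- function(structure) {
  a <- structure$atoms
  xyz <- structure$models[[1]]
  is_base <- !(grepl("'", a$name, fixed = TRUE) |
                 a$name %in% c("P", "OP1", "OP2"))
  het <- which(is_base & a$element %in% c("N", "O"))
  hyd <- which(is_base & a$element == "H")
  donors <- list()
  for (h in hyd) {
    same_res <- het[a$chain[het] == a$chain[h] & a$resno[het] == a$resno[h]]
    if (length(same_res) == 0) next
    d <- sqrt(rowSums((xyz[same_res, , drop = FALSE] -
                         matrix(xyz[h, ], length(same_res), 3,
                                byrow = TRUE))^2))
    if (min(d) < 1.2)
      donors[[length(donors) + 1]] <- c(Y = same_res[which.min(d)], H = h)
  }
  donors <- if (length(donors)) do.call(rbind, donors) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("Y", "H")))
  # candidate (donor, acceptor) pairs on different residues
  pairs <- NULL
  if (nrow(donors) > 0 && length(het) > 0) {
    di <- rep(seq_len(nrow(donors)), each = length(het))
    xi <- rep(het, times = nrow(donors))
    Y <- donors[di, "Y"]
    keep <- !(a$chain[Y] == a$chain[xi] & a$resno[Y] == a$resno[xi])
    pairs <- cbind(Y = Y[keep], H = donors[di, "H"][keep], X = xi[keep])
  }
  list(atoms = a, pairs = pairs)
}

hbonds_for_model <- function(xyz, top, thresholds) {
  empty <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_atom = character(0), h_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_atom = character(0),
                      distance_XY = numeric(0), angle_XHY = numeric(0),
                      stringsAsFactors = FALSE)
  p <- top$pairs
  if (is.null(p) || nrow(p) == 0) return(empty)
  Y <- xyz[p[, "Y"], , drop = FALSE]
  H <- xyz[p[, "H"], , drop = FALSE]
  X <- xyz[p[, "X"], , drop = FALSE]
  dXY <- sqrt(rowSums((X - Y)^2))
  cand <- which(dXY < thresholds$hbond_dist)
  if (length(cand) == 0) return(empty)
  v1 <- X[cand, , drop = FALSE] - H[cand, , drop = FALSE]
  v2 <- Y[cand, , drop = FALSE] - H[cand, , drop = FALSE]
  ca <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, ca))) / DEG
  ok <- cand[ang > thresholds$hbond_angle]
  if (length(ok) == 0) return(empty)
  a <- top$atoms
  data.frame(donor_chain = a$chain[p[ok, "Y"]],
             donor_resno = a$resno[p[ok, "Y"]],
             donor_atom = a$name[p[ok, "Y"]],
             h_atom = a$name[p[ok, "H"]],
             acceptor_chain = a$chain[p[ok, "X"]],
             acceptor_resno = a$resno[p[ok, "X"]],
             acceptor_atom = a$name[p[ok, "X"]],
             distance_XY = dXY[ok],
             angle_XHY = ang[match(ok, cand)],
             stringsAsFactors = FALSE)
}

#' Stacking and hydrogen-bond statistics over a trajectory
#'
#' Evaluates the stacking criteria for every base pair (adjacent and
#' non-adjacent, within and between strands) in every model, and the
#' hydrogen-bond criteria per model when hydrogens are present.  Fractions
#' are stacked models / total models; persistence counts bonds (same X, H,
#' Y atoms) detected in consecutive models.
#'
#' @param traj a multi-model [nucleic_structure()] or a `mock_trajectory`.
#' @param thresholds see [default_thresholds()].
#' @param hbonds evaluate hydrogen bonds: `TRUE`, `FALSE`, or `"auto"`
#'   (only when hydrogens are present).
#' @param mass_weighted passed to the stacking center computation.
#' @return Object of class `trajectory_stats`: list with `n_models`,
#'   `stack_fractions` (data.frame per adjacent intra-strand pair:
#'   `chain`, `step`, `label`, `fraction`), `nonadjacent` (data.frame of
#'   stacked occurrence counts for all other pairs), `hbond_counts`
#'   (integer per model), `hbond_total`, `hbond_persistent` and `hbonds`
#'   (the per-model record tables, concatenated with a `model` column).
#' @export
trajectory_stats <- function(traj, thresholds = default_thresholds(),
                             hbonds = "auto", mass_weighted = TRUE) {
  if (inherits(traj, "mock_trajectory")) traj <- traj$structure
  stopifnot(inherits(traj, "nucleic_structure"))
  nm <- n_models(traj)
  rt <- residue_table(traj)
  n_res <- nrow(rt)
  a <- traj$atoms
  # per-residue precomputation on the fixed topology
  res_sel <- lapply(seq_len(n_res), function(r)
    which(a$chain == rt$chain[r] & a$resno == rt$resno[r]))
  heavy_idx <- lapply(res_sel, function(s) {
    nm_ <- a$name[s]
    s[!(grepl("'", nm_, fixed = TRUE) | nm_ %in% c("P", "OP1", "OP2")) &
        a$element[s] != "H"]
  })
  base_idx <- lapply(res_sel, function(s) {
    nm_ <- a$name[s]
    s[!(grepl("'", nm_, fixed = TRUE) | nm_ %in% c("P", "OP1", "OP2"))]
  })
  wts <- lapply(base_idx, function(s)
    if (mass_weighted) atom_mass(a$element[s]) else rep(1, length(s)))
  ring_idx <- lapply(seq_len(n_res), function(r) {
    ring <- RING_ATOMS[[rt$base[r]]]
    s <- res_sel[[r]]
    s[match(ring, a$name[s])]
  })
  pairs <- utils::combn(n_res, 2)
  adjacent <- rt$chain[pairs[1, ]] == rt$chain[pairs[2, ]] &
    abs(rt$resno[pairs[1, ]] - rt$resno[pairs[2, ]]) == 1
  stack_count <- integer(ncol(pairs))
  do_hb <- isTRUE(hbonds) ||
    (identical(hbonds, "auto") && any(a$element == "H"))
  top <- if (do_hb) hbond_topology(traj) else NULL
  hbond_counts <- integer(nm)
  hb_tables <- vector("list", nm)
  persistent <- 0L
  prev_keys <- character(0)
  for (m in seq_len(nm)) {
    xyz <- traj$models[[m]]
    normals <- lapply(ring_idx, function(s) {
      x <- xyz[s, , drop = FALSE]
      sv <- svd(sweep(x, 2, colMeans(x)))
      sv$v[, 3]
    })
    centers <- lapply(seq_len(n_res), function(r) {
      x <- xyz[base_idx[[r]], , drop = FALSE]
      colSums(x * wts[[r]]) / sum(wts[[r]])
    })
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      cd <- vnorm(centers[[i]] - centers[[j]])
      if (cd >= thresholds$center) next
      ang <- normal_angle(normals[[i]], normals[[j]])
      if (!(ang < thresholds$normal || ang > 180 - thresholds$normal)) next
      xi <- xyz[heavy_idx[[i]], , drop = FALSE]
      xj <- xyz[heavy_idx[[j]], , drop = FALSE]
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), `+`) - 2 * xi %*% t(xj)
      if (sqrt(max(min(d2), 0)) < thresholds$heavy)
        stack_count[k] <- stack_count[k] + 1L
    }
    if (do_hb) {
      hb <- hbonds_for_model(xyz, top, thresholds)
      hbond_counts[m] <- nrow(hb)
      if (nrow(hb) > 0) {
        hb$model <- m
        hb_tables[[m]] <- hb
        keys <- paste(hb$donor_chain, hb$donor_resno, hb$donor_atom,
                      hb$h_atom, hb$acceptor_chain, hb$acceptor_resno,
                      hb$acceptor_atom)
        persistent <- persistent + sum(keys %in% prev_keys)
        prev_keys <- keys
      } else prev_keys <- character(0)
    }
  }
  lab <- function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    paste0(rt$base[i], "(", rt$resno[i], ")/", rt$base[j], "(",
           rt$resno[j], ")")
  }
  adj_k <- which(adjacent)
  stack_fractions <- data.frame(
    chain = rt$chain[pairs[1, adj_k]],
    step = rt$resno[pairs[1, adj_k]],
    label = vapply(adj_k, lab, character(1)),
    fraction = stack_count[adj_k] / nm,
    stringsAsFactors = FALSE)
  stack_fractions <- stack_fractions[order(stack_fractions$chain,
                                           stack_fractions$step), ]
  rownames(stack_fractions) <- NULL
  non_k <- which(!adjacent)
  nonadjacent <- data.frame(
    chain_i = rt$chain[pairs[1, non_k]], resno_i = rt$resno[pairs[1, non_k]],
    chain_j = rt$chain[pairs[2, non_k]], resno_j = rt$resno[pairs[2, non_k]],
    label = vapply(non_k, lab, character(1)),
    count = stack_count[non_k],
    stringsAsFactors = FALSE)
  structure(list(n_models = nm,
                 stack_fractions = stack_fractions,
                 nonadjacent = nonadjacent,
                 hbond_counts = hbond_counts,
                 hbond_total = sum(hbond_counts),
                 hbond_persistent = persistent,
                 hbonds = if (do_hb)
                   do.call(rbind, hb_tables[!vapply(hb_tables, is.null,
                                                    logical(1))])
                 else NULL),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat("<trajectory_stats> ", x$n_models, " model(s)\n", sep = "")
  cat("adjacent-pair stacking fractions:\n")
  print(x$stack_fractions, row.names = FALSE)
  nz <- x$nonadjacent[x$nonadjacent$count > 0, , drop = FALSE]
  cat("non-adjacent stacked occurrences: ",
      if (nrow(nz)) paste(nz$label, nz$count, collapse = "; ") else "none",
      "\n", sep = "")
  cat("hydrogen bonds: ", x$hbond_total, " total, ", x$hbond_persistent,
      " persistent across consecutive models\n", sep = "")
  invisible(x)
}
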