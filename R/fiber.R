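# Fiber-model structure generator: ideal A-/B-form single strands and
# duplexes assembled by chaining per-step rigid transforms from the shipped
# fiber parameter table, plus perturbed conformers, deterministic unstacked
# conformers, and mock trajectories with programmed interaction statistics.

# ---- sugar construction ----------------------------------------------------

# Endocyclic torsions of a 5-ring given as a 5x3 matrix in ring order
# C1', C2', C3', C4', O4'.
ring5_torsions <- function(m) {
  ix <- function(i) m[(i - 1) %% 5 + 1, ]
  vapply(0:4, function(j) {
    # nu_j = torsion about the bond following atom j in the cycle
    # nu0 = C4'-O4'-C1'-C2' etc. (ring order shifted by convention)
    a <- switch(as.character(j),
                "0" = c(4, 5, 1, 2), "1" = c(5, 1, 2, 3),
                "2" = c(1, 2, 3, 4), "3" = c(2, 3, 4, 5),
                "4" = c(3, 4, 5, 1))
    dihedral4(m[a[1], ], m[a[2], ], m[a[3], ], m[a[4], ])
  }, numeric(1))
}

# Build furanose ring coordinates with a prescribed pseudorotation state.
# Atoms on a pentagon of radius r with out-of-plane displacements
# z_j = q cos(4 pi j / 5 + phi); (q, phi) are solved numerically so the
# Altona-Sundaralingam parameters of the resulting ring equal (P, tau_m).
make_sugar_ring <- function(P, tau_m, r = 1.26) {
  build <- function(q, phi) {
    j <- 0:4
    th <- 2 * pi * j / 5
    z <- q * cos(4 * pi * j / 5 + phi)
    cbind(r * cos(th), r * sin(th), z - mean(z))
  }
  measure <- function(q, phi) {
    nu <- ring5_torsions(build(q, phi))
    ps <- pseudorotation(nu)
    c(ps["P"], ps["tau_m"])
  }
  # coarse phase scan, then joint refinement
  phis <- seq(0, 2 * pi, length.out = 73)[-73]
  q0 <- 0.4
  dev <- vapply(phis, function(ph) {
    p <- measure(q0, ph)
    abs(wrap180(p[1] - P))
  }, numeric(1))
  phi0 <- phis[which.min(dev)]
  loss <- function(par) {
    p <- measure(par[1], par[2])
    wrap180(p[1] - P)^2 + (p[2] - tau_m)^2
  }
  opt <- stats::optim(c(q0, phi0), loss,
                      control = list(reltol = 1e-14, maxit = 2000))
  build(opt$par[1], opt$par[2])
}

# Full deoxyribonucleotide template for one base/form combination, in the
# standard base reference frame.  Atom order: P, O5', C5', C4', O4', C3',
# O3', C2', C1', base heavy atoms.  Cached per (base, form).
nucleotide_template <- function(base, form) {
  key <- paste0("tmpl_", base, "_", form)
  if (!is.null(.nucgeom_cache[[key]])) return(.nucgeom_cache[[key]])
  std <- standard_base(base)
  fp <- fiber_parameters(form)
  gl <- GLYCOSIDIC[[base]]
  p_C1 <- as.numeric(std[std$name == "C1'", c("x", "y", "z")])
  p_N <- as.numeric(std[std$name == gl[["N"]], c("x", "y", "z")])
  p_ref <- as.numeric(std[std$name == gl[["ref"]], c("x", "y", "z")])

  ring <- make_sugar_ring(fp$pucker_P, fp$pucker_tau)  # C1' C2' C3' C4' O4'
  # anchor: C1' at its template position, O4' and C2' at internal-coordinate
  # targets so the glycosidic torsion chi = O4'-C1'-N-ref is honoured
  t_O4 <- nerf_place(p_ref, p_N, p_C1, 1.42, 108.2, fp$chi)
  t_C2 <- nerf_place(p_ref, p_N, p_C1, 1.53, 114.0, fp$chi + 240)
  fit <- kabsch(ring[c(1, 5, 2), , drop = FALSE],
                rbind(p_C1, t_O4, t_C2))
  ring <- sweep(ring %*% t(fit$R), 2, fit$t, `+`)
  rownames(ring) <- c("C1'", "C2'", "C3'", "C4'", "O4'")

  # exocyclic substituents; beta-face selection places C5' on the base side
  # of the sugar ring and O3' on the opposite face
  ctr <- colMeans(ring)
  nrm <- unitv(pracma_cross(ring[2, ] - ring[1, ], ring[5, ] - ring[1, ]))
  face <- function(p) sign(sum((p - ctr) * nrm))
  base_side <- face(p_N)
  nu3 <- dihedral4(ring["C2'", ], ring["C3'", ], ring["C4'", ],
                   ring["O4'", ])
  cand <- lapply(c(-122, 122), function(s)
    nerf_place(ring["C2'", ], ring["C3'", ], ring["C4'", ], 1.51, 115.0,
               nu3 + s))
  side <- vapply(cand, face, numeric(1))
  pick <- which(side == base_side)
  if (length(pick) == 0) pick <- 1L
  C5p <- cand[[pick[1]]]
  # O3' placed by the form's canonical backbone delta torsion
  O3p <- nerf_place(C5p, ring["C4'", ], ring["C3'", ], 1.42, 110.5,
                    fp$delta)
  # The O5' and P placements have two free dihedrals (the gamma and beta
  # torsions); choose them so that, under the form's uniform step
  # transform, the next residue's P closes onto this residue's O3'
  # (covalent O3'-P link of the chained fiber).
  nxt <- build_step(identity_frame(), as.list(fp$step))
  place_p <- function(d) {
    O5p <- nerf_place(ring["C3'", ], ring["C4'", ], C5p, 1.44, 110.0, d[1])
    list(O5 = O5p,
         P = nerf_place(ring["C4'", ], C5p, O5p, 1.60, 119.0, d[2]))
  }
  closure <- function(d) {
    pp <- place_p(d)
    p_next <- as.vector(nxt$axes %*% pp$P + nxt$origin)
    abs(vnorm(p_next - O3p) - 1.60)  # target the O3'-P bond length
  }
  starts <- list(c(38, -147), c(54, 180), c(-60, 60), c(180, -60))
  opts <- lapply(starts, function(s)
    stats::optim(s, closure, control = list(reltol = 1e-12, maxit = 1000)))
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  pp <- place_p(opt$par)
  O5p <- pp$O5
  Pat <- pp$P

  bk <- rbind(P = Pat, `O5'` = O5p, `C5'` = C5p, `C4'` = ring["C4'", ],
              `O4'` = ring["O4'", ], `C3'` = ring["C3'", ], `O3'` = O3p,
              `C2'` = ring["C2'", ], `C1'` = ring["C1'", ])
  bk_df <- data.frame(name = rownames(bk),
                      element = element_from_name(rownames(bk)),
                      x = bk[, 1], y = bk[, 2], z = bk[, 3],
                      stringsAsFactors = FALSE)
  base_df <- std[std$name != "C1'", ]
  out <- rbind(bk_df, base_df)
  rownames(out) <- NULL
  .nucgeom_cache[[key]] <- out
  out
}

# ---- structure assembly ----------------------------------------------------

identity_frame <- function() base_frame(c(0, 0, 0), diag(3))

# Place a residue template into a world frame; returns the coordinate block.
place_template <- function(tmpl, frame) {
  xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  sweep(xyz %*% t(frame$axes), 2, frame$origin, `+`)
}

resolve_overrides <- function(step_overrides, n_steps) {
  # returns function(i) -> named numeric of parameter deltas-free overrides
  if (is.null(step_overrides)) return(function(i) NULL)
  so <- as.data.frame(step_overrides)
  if (!"step" %in% names(so))
    stop("step_overrides must contain a 'step' column")
  if (any(so$step < 1 | so$step > n_steps))
    stop("step override index out of range [1, ", n_steps, "]")
  function(i) {
    row <- so[so$step == i, setdiff(names(so), "step"), drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    unlist(row[1, ])
  }
}

#' Build an ideal fiber-model DNA structure
#'
#' Places every base by chaining per-step rigid transforms built from the
#' form's canonical fiber step parameters ([fiber_parameters()]); a duplex
#' adds the antiparallel complementary strand by Watson-Crick frame pairing
#' (the partner frame is the strand-I frame rotated 180 degrees about its
#' x-axis).  Sugars use form-appropriate pucker templates (B: C2'-endo,
#' A: C3'-endo).
#'
#' @param sequence base string 5'->3'; compact repeat notation is accepted
#'   and expanded via [parse_sequence_spec()].
#' @param form `"B"` (default) or `"A"`.
#' @param duplex build the complementary strand as chain B.
#' @param step_overrides optional data.frame with a `step` column (1-based
#'   step index) and any of the six step-parameter columns, replacing the
#'   canonical values at those steps.
#' @param add_hydrogens place idealized base hydrogens ([add_base_hydrogens()]).
#' @return A [nucleic_structure()] (chain `"A"`, plus `"B"` for duplexes,
#'   both 5'->3').
#' @export
#' @examples
#' b <- build_fiber("C6")
#' d <- build_fiber("A4", duplex = TRUE)
build_fiber <- function(sequence, form = "B", duplex = FALSE,
                        step_overrides = NULL, add_hydrogens = FALSE) {
  seq <- parse_sequence_spec(sequence)
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  form <- match.arg(toupper(form), c("A", "B"))
  fp <- fiber_parameters(form)
  override <- resolve_overrides(step_overrides, max(n - 1, 1))
  frames <- vector("list", n)
  frames[[1]] <- identity_frame()
  if (n > 1) for (i in seq_len(n - 1)) {
    p <- fp$step
    ov <- override(i)
    if (!is.null(ov)) p[names(ov)] <- ov
    frames[[i + 1]] <- build_step(frames[[i]], as.list(p))
  }
  atoms <- list(); xyz <- list()
  for (i in seq_len(n)) {
    tmpl <- nucleotide_template(bases[i], form)
    atoms[[i]] <- data.frame(name = tmpl$name, element = tmpl$element,
                             chain = "A", resno = i, base = bases[i],
                             stringsAsFactors = FALSE)
    xyz[[i]] <- place_template(tmpl, frames[[i]])
  }
  if (duplex) {
    flip <- diag(c(1, -1, -1))
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    # strand II residue k pairs strand I residue n + 1 - k
    for (k in seq_len(n)) {
      i <- n + 1 - k
      b2 <- comp[[bases[i]]]
      fr2 <- base_frame(frames[[i]]$origin, frames[[i]]$axes %*% flip)
      tmpl <- nucleotide_template(b2, form)
      atoms[[n + k]] <- data.frame(name = tmpl$name, element = tmpl$element,
                                   chain = "B", resno = k, base = b2,
                                   stringsAsFactors = FALSE)
      xyz[[n + k]] <- place_template(tmpl, fr2)
    }
  }
  out <- nucleic_structure(do.call(rbind, atoms), list(do.call(rbind, xyz)))
  if (add_hydrogens) out <- add_base_hydrogens(out)
  out
}

#' Build a deterministic fully-unstacked conformer
#'
#' Elongated single strand in which consecutive bases are separated by a
#' 7 Angstrom rise and rolled by 60 degrees with alternating sign, so that
#' no adjacent pair satisfies any of the three stacking criteria.
#'
#' @param sequence base string (compact notation accepted).
#' @param rise,roll the per-step separation (Angstrom) and alternating
#'   bending (degrees).
#' @return A single-strand [nucleic_structure()].
#' @export
build_unstacked <- function(sequence, rise = 7, roll = 60) {
  seq <- parse_sequence_spec(sequence)
  n <- nchar(seq)
  if (n < 2) return(build_fiber(seq, form = "B"))
  ov <- data.frame(step = seq_len(n - 1), shift = 0, slide = 0,
                   rise = rise, tilt = 0,
                   roll = roll * (-1)^(seq_len(n - 1) - 1),
                   twist = fiber_parameters("B")$step[["twist"]])
  build_fiber(seq, form = "B", step_overrides = ov)
}

# Relative rigid transform of a step expressed in the 5' frame:
# list(R = R1^T R2, t = R1^T (o2 - o1)).
relative_transform <- function(frame_i, frame_j) {
  list(R = t(frame_i$axes) %*% frame_j$axes,
       t = as.vector(t(frame_i$axes) %*% (frame_j$origin - frame_i$origin)))
}

apply_transform <- function(frame, rel) {
  base_frame(origin = frame$origin + as.vector(frame$axes %*% rel$t),
             axes = frame$axes %*% rel$R)
}

#' Perturb the step parameters of a single strand
#'
#' Measures the base frames and step parameters of the input, adds the
#' requested offsets, and rebuilds the strand by chaining the perturbed
#' steps from the first frame; each residue's atoms are carried rigidly
#' from the old frame to the new one, so intra-residue geometry (sugars,
#' hydrogens) is preserved and the recomputed step parameters equal
#' original + deltas to numerical precision.
#'
#' @param structure single-model, single-strand [nucleic_structure()].
#' @param deltas data.frame with a `step` column and any of `shift`,
#'   `slide`, `rise`, `tilt`, `roll`, `twist`: additive offsets.  May be
#'   `NULL` when only `jitter` is used.
#' @param jitter optional named numeric of standard deviations for random
#'   offsets drawn per step on the named coordinates.
#' @param seed integer seed for `jitter` (results are reproducible).
#' @return A new `nucleic_structure`.
#' @export
perturb_steps <- function(structure, deltas = NULL, jitter = NULL,
                          seed = NULL) {
  stopifnot(inherits(structure, "nucleic_structure"))
  if (n_models(structure) != 1)
    stop("perturb_steps operates on single-model structures")
  if (length(structure$chains) != 1)
    stop("perturb_steps operates on single strands")
  ch <- structure$chains[1]
  frames <- fit_frames(structure, ch)
  n <- length(frames)
  if (n < 2) return(structure)
  steps <- step_series(frames)
  cols <- c("shift", "slide", "rise", "tilt", "roll", "twist")
  delta_m <- matrix(0, n - 1, 6, dimnames = list(NULL, cols))
  if (!is.null(deltas)) {
    d <- as.data.frame(deltas)
    if (!"step" %in% names(d)) stop("deltas must contain a 'step' column")
    if (any(d$step < 1 | d$step > n - 1))
      stop("step index out of range [1, ", n - 1, "]")
    for (cc in intersect(names(d), cols))
      delta_m[d$step, cc] <- delta_m[d$step, cc] + d[[cc]]
  }
  if (!is.null(jitter)) {
    if (!is.null(seed)) set.seed(seed)
    for (cc in intersect(names(jitter), cols))
      delta_m[, cc] <- delta_m[, cc] +
        stats::rnorm(n - 1, 0, jitter[[cc]])
  }
  if (!all(is.finite(delta_m))) stop("non-finite deltas")
  new_frames <- vector("list", n)
  new_frames[[1]] <- frames[[1]]
  for (i in seq_len(n - 1)) {
    p <- as.list(unlist(steps[i, cols]) + delta_m[i, ])
    new_frames[[i + 1]] <- build_step(new_frames[[i]], p)
  }
  xyz <- structure$models[[1]]
  out <- xyz
  for (i in seq_len(n)) {
    sel <- structure$atoms$chain == ch & structure$atoms$resno == i
    local <- sweep(xyz[sel, , drop = FALSE], 2,
                   frames[[i]]$origin) %*% frames[[i]]$axes
    out[sel, ] <- sweep(local %*% t(new_frames[[i]]$axes), 2,
                        new_frames[[i]]$origin, `+`)
  }
  nucleic_structure(structure$atoms, list(out))
}

# ---- mock trajectories -----------------------------------------------------

#' Mock trajectory with programmed interaction statistics
#'
#' Generates a multi-model structure from a single-strand template: each
#' snapshot independently samples, per adjacent step, a stacked state
#' (the template's own step geometry) versus an unstacked state (replaced
#' rise/roll, as in [build_unstacked()]) with the programmed probability,
#' then adds isotropic Gaussian coordinate noise.  Hydrogen-bond events are
#' inserted at the programmed per-snapshot rate by rigidly translating the
#' 3'-terminal residue so one of its acceptors sits in ideal geometry
#' against the 5' residue's donor; the affected final step is unstacked in
#' those snapshots and the returned ground truth records this.  Events are
#' never placed in consecutive snapshots, so true persistence is zero.
#'
#' @param base single-model, single-strand [nucleic_structure()] (typically
#'   from [build_fiber()]).  Idealized hydrogens are added automatically
#'   when `hbond_rate > 0` and none are present.
#' @param n_snapshots number of models to generate.
#' @param p_stack per-step stacking probabilities in `[0, 1]` (recycled to
#'   the number of steps).
#' @param sigma coordinate noise standard deviation, Angstrom.
#' @param unstack named numeric with the unstacked-state `rise` and `roll`.
#' @param hbond_rate expected hydrogen-bond events per snapshot in `[0, 1]`.
#' @param seed integer seed; the generator is fully reproducible.
#' @return Object of class `mock_trajectory`: list with `structure` (the
#'   multi-model [nucleic_structure()]) and `truth` (list with `stacked`,
#'   an `n_snapshots` x n_steps logical matrix, and `hbond`, a logical
#'   event vector per snapshot).
#' @export
make_mock_trajectory <- function(base, n_snapshots, p_stack, sigma = 0.05,
                                 unstack = c(rise = 7, roll = 60),
                                 hbond_rate = 0, seed = 1) {
  stopifnot(inherits(base, "nucleic_structure"))
  if (n_models(base) != 1) stop("base must be single-model")
  if (length(base$chains) != 1) stop("base must be a single strand")
  if (n_snapshots < 1) stop("n_snapshots must be >= 1")
  if (any(p_stack < 0 | p_stack > 1)) stop("probabilities must lie in [0, 1]")
  if (hbond_rate < 0 || hbond_rate > 1)
    stop("hbond_rate must lie in [0, 1] (expected events per snapshot)")
  if (hbond_rate > 0 && !any(base$atoms$element == "H"))
    base <- add_base_hydrogens(base)
  ch <- base$chains[1]
  rt <- residue_table(base)
  n <- nrow(rt)
  if (n < 2) stop("base must contain at least 2 residues")
  n_steps <- n - 1
  p_stack <- rep_len(p_stack, n_steps)
  frames <- fit_frames(base, ch)
  rel_stacked <- lapply(seq_len(n_steps), function(i)
    relative_transform(frames[[i]], frames[[i + 1]]))
  steps <- step_series(frames)
  rel_unstacked <- lapply(seq_len(n_steps), function(i) {
    p <- list(shift = 0, slide = 0, rise = unstack[["rise"]], tilt = 0,
              roll = unstack[["roll"]] * (-1)^(i - 1),
              twist = steps$twist[i])
    f2 <- build_step(identity_frame(), p)
    relative_transform(identity_frame(), f2)
  })
  # per-residue local coordinates (in the residue's own frame)
  sel_res <- lapply(seq_len(n), function(i)
    which(base$atoms$chain == ch & base$atoms$resno == i))
  local <- lapply(seq_len(n), function(i)
    sweep(base$models[[1]][sel_res[[i]], , drop = FALSE], 2,
          frames[[i]]$origin) %*% frames[[i]]$axes)
  # hydrogen-bond staging: first residue's first donor H, last residue's
  # first conventional acceptor
  hb <- NULL
  if (hbond_rate > 0) {
    res1 <- get_residue(base, ch, 1)
    donors <- BASE_DONORS[[res1$base]]
    dn <- names(donors)[1]
    hnames <- res1$atoms$name[res1$atoms$element == "H" &
                                grepl(paste0("^H", sub("^N", "", dn)),
                                      res1$atoms$name)]
    resN <- get_residue(base, ch, n)
    acc <- intersect(BASE_ACCEPTORS[[resN$base]], resN$atoms$name)[1]
    if (length(hnames) == 0 || is.na(acc))
      stop("cannot stage hydrogen-bond events: donor hydrogen or acceptor ",
           "not found")
    hb <- list(donor_res = 1L, donor_N = dn, donor_H = hnames[1],
               acceptor_res = n, acceptor_atom = acc,
               acc_local_idx = match(acc, base$atoms$name[sel_res[[n]]]),
               top = hbond_topology(base))
  }
  set.seed(seed)
  stacked_draw <- matrix(stats::runif(n_snapshots * n_steps) <
                           rep(p_stack, each = n_snapshots),
                         n_snapshots, n_steps)
  hbond_event <- rep(FALSE, n_snapshots)
  if (hbond_rate > 0) {
    hbond_event <- stats::runif(n_snapshots) < hbond_rate
    if (n_snapshots > 1)
      for (s in 2:n_snapshots)
        if (hbond_event[s] && hbond_event[s - 1]) hbond_event[s] <- FALSE
  }
  n_atoms <- nrow(base$atoms)
  models <- vector("list", n_snapshots)
  truth_stacked <- stacked_draw
  for (s in seq_len(n_snapshots)) {
    fr <- vector("list", n)
    fr[[1]] <- frames[[1]]
    for (i in seq_len(n_steps)) {
      rel <- if (stacked_draw[s, i]) rel_stacked[[i]] else rel_unstacked[[i]]
      fr[[i + 1]] <- apply_transform(fr[[i]], rel)
    }
    xyz <- matrix(0, n_atoms, 3)
    for (i in seq_len(n))
      xyz[sel_res[[i]], ] <- sweep(local[[i]] %*% t(fr[[i]]$axes), 2,
                                   fr[[i]]$origin, `+`)
    if (hbond_event[s]) {
      # translate the terminal residue so its acceptor sits 2.9 A from the
      # donor N along the N-H direction (angle X-H-Y = 180), then rotate
      # it about that axis until exactly one bond satisfies the criteria
      # (the unrotated placement can create a reciprocal second bond)
      iY <- sel_res[[1]][match(hb$donor_N, base$atoms$name[sel_res[[1]]])]
      iH <- sel_res[[1]][match(hb$donor_H, base$atoms$name[sel_res[[1]]])]
      Y <- xyz[iY, ]; H <- xyz[iH, ]
      u <- unitv(H - Y)
      target <- Y + 2.9 * u
      iX <- sel_res[[n]][hb$acc_local_idx]
      shift <- target - xyz[iX, ]
      block0 <- sweep(xyz[sel_res[[n]], , drop = FALSE], 2, shift, `+`)
      for (theta in c(90, 45, 135, 180, 270, 0)) {
        Rz <- rot_about(u, theta)
        block <- sweep(sweep(block0, 2, target) %*% t(Rz), 2, target, `+`)
        xyz[sel_res[[n]], ] <- block
        if (nrow(hbonds_for_model(xyz, hb$top, default_thresholds())) == 1)
          break
      }
      truth_stacked[s, n_steps] <- FALSE
    }
    if (sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * n_atoms, 0, sigma), n_atoms, 3)
    models[[s]] <- xyz
  }
  structure(list(structure = nucleic_structure(base$atoms, models),
                 truth = list(stacked = truth_stacked,
                              hbond = hbond_event,
                              p_stack = p_stack,
                              hbond_rate = hbond_rate)),
            class = "mock_trajectory")
}

#' @export
print.mock_trajectory <- function(x, ...) {
  cat("<mock_trajectory> ", n_models(x$structure), " snapshots, ",
      ncol(x$truth$stacked), " steps, ", sum(x$truth$hbond),
      " staged H-bond events\n", sep = "")
  invisible(x)
}
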