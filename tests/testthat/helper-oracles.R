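# Independent reference implementations and fixture builders used as
# oracles by the test suite.  These deliberately avoid the package's own
# computational paths wherever a check is meant to be independent.

# random proper rotation + translation
rand_rigid <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, -180, 180) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  list(R = R, t = rnorm(3, sd = 8))
}

apply_rigid_structure <- function(s, rig) {
  nucleic_structure(s$atoms, lapply(s$models, function(m)
    sweep(m %*% t(rig$R), 2, rig$t, `+`)))
}

apply_rigid_residue <- function(res, rig) {
  xyz <- as.matrix(res$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rig$R), 2, rig$t, `+`)
  res$atoms$x <- xyz[, 1]; res$atoms$y <- xyz[, 2]; res$atoms$z <- xyz[, 3]
  res
}

# analytic ring torsions for a pseudorotation state (the convention
# consistent with the Altona-Sundaralingam phase formula)
nu_from_P <- function(P, tau_m) {
  j <- 0:4
  tau_m * cos((P + 144 * (j - 2)) * pi / 180)
}

# brute-force stacking reference: plain double/triple loops, with the base
# normal computed by averaging cross products around the ring (a method
# independent of the SVD plane fit used by the package)
brute_normal <- function(xyz) {
  n <- nrow(xyz)
  ctr <- colMeans(xyz)
  acc <- c(0, 0, 0)
  for (i in seq_len(n)) {
    a <- xyz[i, ] - ctr
    b <- xyz[i %% n + 1, ] - ctr
    acc <- acc + c(a[2] * b[3] - a[3] * b[2],
                   a[3] * b[1] - a[1] * b[3],
                   a[1] * b[2] - a[2] * b[1])
  }
  acc / sqrt(sum(acc^2))
}

brute_stacked_pairs <- function(s, model = 1, thr = default_thresholds()) {
  rt <- residue_table(s)
  n <- nrow(rt)
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)
  ring_sets <- list(
    A = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
    G = c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
    C = c("N1", "C2", "N3", "C4", "C5", "C6"),
    T = c("N1", "C2", "N3", "C4", "C5", "C6"))
  res_info <- lapply(seq_len(n), function(r) {
    res <- get_residue(s, rt$chain[r], rt$resno[r], model)
    at <- res$atoms
    is_base <- !grepl("'", at$name, fixed = TRUE) &
      !at$name %in% c("P", "OP1", "OP2")
    bh <- at[is_base & at$element != "H", ]
    ba <- at[is_base, ]
    w <- masses[ba$element]
    com <- colSums(as.matrix(ba[, c("x", "y", "z")]) * w) / sum(w)
    ring <- at[match(ring_sets[[res$base]], at$name), c("x", "y", "z")]
    list(heavy = as.matrix(bh[, c("x", "y", "z")]), com = com,
         normal = brute_normal(as.matrix(ring)))
  })
  out <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- res_info[[i]]; b <- res_info[[j]]
    mind <- Inf
    for (p in seq_len(nrow(a$heavy))) for (q in seq_len(nrow(b$heavy)))
      mind <- min(mind, sqrt(sum((a$heavy[p, ] - b$heavy[q, ])^2)))
    cd <- sqrt(sum((a$com - b$com)^2))
    ca <- sum(a$normal * b$normal)
    ang <- acos(min(1, max(-1, ca))) * 180 / pi
    out[i, j] <- (mind < thr$heavy) && (cd < thr$center) &&
      (ang < thr$normal || ang > 180 - thr$normal)
  }
  out
}

brute_hbonds <- function(s, model = 1, thr = default_thresholds()) {
  a <- s$atoms
  xyz <- s$models[[model]]
  is_base <- !grepl("'", a$name, fixed = TRUE) &
    !a$name %in% c("P", "OP1", "OP2")
  het <- which(is_base & a$element %in% c("N", "O"))
  hyd <- which(is_base & a$element == "H")
  count <- 0
  for (h in hyd) for (y in het) {
    if (a$chain[y] != a$chain[h] || a$resno[y] != a$resno[h]) next
    if (sqrt(sum((xyz[y, ] - xyz[h, ])^2)) >= 1.2) next
    # h is covalently bound to y; but only the closest heteroatom owns it
    dists <- sapply(het[a$chain[het] == a$chain[h] &
                          a$resno[het] == a$resno[h]],
                    function(k) sqrt(sum((xyz[k, ] - xyz[h, ])^2)))
    if (sqrt(sum((xyz[y, ] - xyz[h, ])^2)) > min(dists) + 1e-12) next
    for (x in het) {
      if (a$chain[x] == a$chain[y] && a$resno[x] == a$resno[y]) next
      dxy <- sqrt(sum((xyz[x, ] - xyz[y, ])^2))
      if (dxy >= thr$hbond_dist) next
      v1 <- xyz[x, ] - xyz[h, ]; v2 <- xyz[y, ] - xyz[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > thr$hbond_angle) count <- count + 1
    }
  }
  count
}

# hand-written PDB fixtures -------------------------------------------------

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     element) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          resid, chain, resno, x, y, z, element)
}

write_single_cytosine_pdb <- function(path) {
  std <- standard_base("C")
  lines <- vapply(seq_len(nrow(std)), function(i)
    pdb_line(i, std$name[i], "DC", "A", 1, std$x[i], std$y[i], std$z[i],
             std$element[i]), character(1))
  writeLines(c(lines, "END"), path)
  nrow(std)
}

write_multimodel_pdb <- function(path, n_models = 3) {
  std <- standard_base("C")
  out <- character(0)
  for (m in seq_len(n_models)) {
    out <- c(out, sprintf("MODEL     %4d", m))
    out <- c(out, vapply(seq_len(nrow(std)), function(i)
      pdb_line(i, std$name[i], "DC", "A", 1, std$x[i] + 0.1 * (m - 1),
               std$y[i], std$z[i], std$element[i]), character(1)))
    out <- c(out, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
}

write_unknown_residue_pdb <- function(path) {
  lines <- c(pdb_line(1, "C1'", "XYZ", "A", 1, 0, 0, 0, "C"),
             pdb_line(2, "N1", "XYZ", "A", 1, 1.4, 0, 0, "N"),
             "END")
  writeLines(lines, path)
}

# counts of homo-dinucleotide steps in a base string (string-level oracle)
homo_step_count <- function(seq, type) {
  chars <- strsplit(seq, "")[[1]]
  b <- substr(type, 1, 1)
  sum(chars[-length(chars)] == b & chars[-1] == b)
}
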