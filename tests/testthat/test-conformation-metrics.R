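# Aggregated descriptors: averages, end-to-end, RMSD, A/B classification,
# and the assembled structure report.

test_that("step averages are plain arithmetic means", {
  f1 <- base_frame(c(0, 0, 0), diag(3))
  s30 <- step_parameters(f1, build_step(f1, list(shift = 0, slide = 0,
                                                 rise = 3.2, tilt = 0,
                                                 roll = 0, twist = 30)))
  s42 <- step_parameters(f1, build_step(f1, list(shift = 0, slide = 0,
                                                 rise = 3.6, tilt = 0,
                                                 roll = 0, twist = 42)))
  expect_equal(unname(average_step_params(list(s30))["twist"]), 30)
  av <- average_step_params(list(s30, s42))
  expect_equal(unname(av["twist"]), 36)
  expect_equal(unname(av["rise"]), 3.4)
  expect_error(average_step_params(list()), "no steps")
})

test_that("end-to-end follows the C5'/C3' definition", {
  s <- build_fiber("C6")
  one <- build_fiber("A1")
  r <- get_residue(one, "A", 1)
  manual <- sqrt(sum((nucgeom:::residue_atom(r, "C5'") -
                        nucgeom:::residue_atom(r, "C3'"))^2))
  expect_equal(end_to_end(one), manual, tolerance = 1e-12)
  # rigid motions leave it unchanged
  e0 <- end_to_end(s)
  for (seed in 1:3)
    expect_equal(end_to_end(apply_rigid_structure(s, rand_rigid(seed))),
                 e0, tolerance = 1e-9)
  # missing atoms are reported with context
  s2 <- s
  keep <- !(s2$atoms$resno == 6 & s2$atoms$name == "C3'")
  s2 <- nucleic_structure(s2$atoms[keep, ],
                          list(s2$models[[1]][keep, ]))
  expect_error(end_to_end(s2), "C3'")
})

test_that("superposed RMSD removes rigid motions and is minimal", {
  s <- build_fiber("A2C2")
  expect_equal(rmsd_superposed(s, s), 0, tolerance = 1e-12)
  rig <- rand_rigid(17)
  expect_equal(rmsd_superposed(s, apply_rigid_structure(s, rig)), 0,
               tolerance = 1e-9)
  # single displaced atom: superposition can only lower d/sqrt(N)
  m2 <- s$models[[1]]
  d <- 2.0
  m2[10, ] <- m2[10, ] + c(d, 0, 0)
  s2 <- nucleic_structure(s$atoms, list(m2))
  expect_lte(rmsd_superposed(s, s2), d / sqrt(nrow(m2)) + 1e-9)
  expect_error(rmsd_superposed(s, s2, selection = "P"),
               NA)  # named selections map one-to-one here
  expect_error(rmsd_superposed(s, build_fiber("A2C2A2")), "mismatch")
})

test_that("superposition agrees with the independent bio3d solver", {
  s <- build_fiber("ACGT")
  set.seed(23)
  m2 <- s$models[[1]] + matrix(rnorm(3 * nrow(s$models[[1]]), 0, 0.4),
                               ncol = 3)
  s2 <- nucleic_structure(s$atoms, list(m2))
  ours <- rmsd_superposed(s, s2)
  xyz1 <- as.vector(t(s$models[[1]]))
  xyz2 <- as.vector(t(m2))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz2, mobile = xyz1))
  oracle <- sqrt(mean(colSums(matrix((fitted - xyz2)^2, nrow = 3))))
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("the slide-roll boundary separates the canonical forms", {
  cls <- classify_form(data.frame(slide = c(0.4, -1.5), roll = c(0.6, 12)))
  expect_equal(cls$form, c("B", "A"))
  # a point exactly on the line classifies B
  on_line <- classify_form(data.frame(slide = 1, roll = 0))
  expect_equal(on_line$form, "B")
  # the generator's own A and B steps land on their sides
  stb <- step_series(fit_frames(build_fiber("C6", "B"), "A"))
  expect_true(all(classify_form(stb)$form == "B"))
  sta <- step_series(fit_frames(build_fiber("C6", "A"), "A"))
  expect_true(all(classify_form(sta)$form == "A"))
})

test_that("duplex reports carry n-1 pair steps with exact averages", {
  d <- build_fiber("CATGGC", duplex = TRUE)
  rep_ <- analyze_structure(d, mode = "base-pair-steps")
  expect_equal(nrow(rep_$steps), 5)
  expect_equal(unname(rep_$averages["twist"]), 36, tolerance = 1e-6)
  # report averages equal recomputed means of the table (exact)
  expect_identical(unname(rep_$averages),
                   unname(colMeans(as.matrix(
                     rep_$steps[, nucgeom:::STEP_COLS]))))
  rep2 <- analyze_structure(d, mode = "per-strand")
  expect_equal(sum(rep2$steps$chain == "A"), 5)
  expect_equal(sum(rep2$steps$chain == "B"), 5)
  expect_error(analyze_structure(build_fiber("C4"),
                                 mode = "base-pair-steps"),
               "two-strand")
})

test_that("per-strand and pair-step descriptors agree on fiber duplexes", {
  d <- build_fiber("GACT2G", duplex = TRUE)
  r1 <- analyze_structure(d, mode = "per-strand")
  r2 <- analyze_structure(d, mode = "base-pair-steps")
  expect_equal(unname(r1$averages["twist"]), unname(r2$averages["twist"]),
               tolerance = 0.1)
  expect_equal(unname(r1$averages["rise"]), unname(r2$averages["rise"]),
               tolerance = 0.05)
})

test_that("homo-dinucleotide groups pool the expected steps", {
  seq <- parse_sequence_spec("CTG4ACT3C2AG2")
  d <- build_fiber(seq, duplex = TRUE)
  rep_ <- analyze_structure(d, mode = "per-strand")
  hg <- rep_$homo_groups
  # string-level oracle: counts on the strand and its reverse complement
  rc <- reverse_complement(seq)
  for (tp in c("A/A", "C/C", "G/G", "T/T")) {
    expected <- homo_step_count(seq, tp) + homo_step_count(rc, tp)
    got <- hg$n_steps[hg$step_type == tp]
    expect_equal(if (length(got)) got else 0L, expected,
                 info = tp)
  }
  # every pooled average equals the generator's uniform parameters
  expect_equal(hg$twist, rep(36, nrow(hg)), tolerance = 1e-6)
})

test_that("reports serialize to the documented TSV layout", {
  d <- build_fiber("G4", duplex = TRUE)
  rep_ <- analyze_structure(d, mode = "base-pair-steps",
                            reference = build_fiber("G4", duplex = TRUE))
  prefix <- tempfile()
  files <- write_report(rep_, prefix)
  expect_true(all(file.exists(files)))
  steps <- read.delim(paste0(prefix, "_steps.tsv"))
  expect_identical(names(steps)[1:10],
                   c("chain", "step_label", "shift", "slide", "rise",
                     "tilt", "roll", "twist", "h_rise", "h_twist"))
  summary_txt <- readLines(paste0(prefix, "_summary.txt"))
  expect_true(any(grepl("^mean_twist\t", summary_txt)))
  expect_true(any(grepl("^rmsd\t", summary_txt)))
})
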