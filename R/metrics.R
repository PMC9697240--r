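# Summary descriptors: per-step averages, end-to-end distance, RMSD after
# optimal superposition, slide-roll A/B classification, and the assembled
# per-structure report.

STEP_COLS <- c("shift", "slide", "rise", "tilt", "roll", "twist",
               "h_rise", "h_twist")

#' Average step parameters
#'
#' Arithmetic mean per coordinate over all dinucleotide steps of a
#' sequence; angles are averaged arithmetically (all in-scope values sit
#' far from the +/-180 wrap).
#'
#' @param steps data.frame as returned by [step_series()] (or a list of
#'   `step_params`).
#' @return Named numeric of the eight mean coordinates.
#' @export
average_step_params <- function(steps) {
  if (inherits(steps, "step_params")) steps <- list(steps)
  if (is.list(steps) && !is.data.frame(steps)) {
    if (length(steps) == 0) stop("no steps to average")
    steps <- do.call(rbind, lapply(steps, function(s)
      as.data.frame(s[STEP_COLS])))
  }
  if (is.null(steps) || nrow(steps) == 0) stop("no steps to average")
  colMeans(as.matrix(steps[, STEP_COLS]))
}

#' End-to-end distance of a strand
#'
#' Euclidean distance between the 5' carbon (C5') of the first nucleotide
#' and the 3' carbon (C3') of the last nucleotide.
#'
#' @param structure a [nucleic_structure()].
#' @param chain chain identifier (default: first chain).
#' @param model model number.
#' @return Distance in Angstrom.
#' @export
end_to_end <- function(structure, chain = structure$chains[1], model = 1) {
  res <- strand_residues(structure, chain, model)
  if (length(res) == 0) stop("empty strand")
  p5 <- residue_atom(res[[1]], "C5'")
  p3 <- residue_atom(res[[length(res)]], "C3'")
  vnorm(p5 - p3)
}

#' RMSD after optimal superposition
#'
#' Least-squares proper superposition (rotation plus translation) of the
#' selected atoms of `s1` onto those of `s2`, then the root-mean-square
#' deviation over the selection.
#'
#' @param s1,s2 [nucleic_structure()]s whose selections map one-to-one.
#' @param selection optional character vector of atom names to include
#'   (e.g. `c("P", "C1'")`); `NULL` selects all atoms.
#' @param model1,model2 model numbers.
#' @return RMSD in Angstrom.
#' @export
rmsd_superposed <- function(s1, s2, selection = NULL, model1 = 1,
                            model2 = 1) {
  stopifnot(inherits(s1, "nucleic_structure"),
            inherits(s2, "nucleic_structure"))
  pick <- function(s, model) {
    keep <- if (is.null(selection)) rep(TRUE, nrow(s$atoms)) else
      s$atoms$name %in% selection
    s$models[[model]][keep, , drop = FALSE]
  }
  x <- pick(s1, model1)
  y <- pick(s2, model2)
  if (nrow(x) != nrow(y))
    stop("selection count mismatch: ", nrow(x), " vs ", nrow(y), " atoms")
  kabsch(x, y)$rmsd
}

#' Slide-roll A/B-form classification of steps
#'
#' A step is A-like when its roll lies above the configured dividing line
#' `roll = intercept + slope * slide` in the slide-roll plane; points on
#' the line classify B-like.  The default line (intercept 4 degrees, slope
#' -4 degrees per Angstrom) is calibrated so canonical fiber A and B steps
#' fall on their respective sides.
#'
#' @param steps data.frame with `slide` and `roll` columns (e.g. from
#'   [step_series()]), or a single `step_params`.
#' @param boundary named numeric with `intercept` (degrees) and `slope`
#'   (degrees per Angstrom).
#' @return data.frame with `step_label`, `slide`, `roll`, `form`
#'   (`"A"`/`"B"`).
#' @export
classify_form <- function(steps, boundary = c(intercept = 4, slope = -4)) {
  if (inherits(steps, "step_params"))
    steps <- data.frame(step_label = steps$step_label, slide = steps$slide,
                        roll = steps$roll, stringsAsFactors = FALSE)
  stopifnot(all(c("slide", "roll") %in% names(steps)))
  if (!all(is.finite(steps$slide)) || !all(is.finite(steps$roll)))
    stop("non-finite slide/roll")
  line <- boundary[["intercept"]] + boundary[["slope"]] * steps$slide
  data.frame(step_label = if ("step_label" %in% names(steps))
    steps$step_label else paste0("step", seq_len(nrow(steps))),
    slide = steps$slide, roll = steps$roll,
    form = ifelse(steps$roll > line, "A", "B"),
    stringsAsFactors = FALSE)
}

step_labels_for <- function(rt_chain) {
  n <- nrow(rt_chain)
  vapply(seq_len(n - 1), function(i)
    paste0(rt_chain$base[i], "(", rt_chain$resno[i], ")/",
           rt_chain$base[i + 1], "(", rt_chain$resno[i + 1], ")"),
    character(1))
}

#' Conformational report for a structure
#'
#' Assembles the package's summary descriptors: the per-step parameter
#' table (per strand, or between Watson-Crick pair frames for duplexes),
#' the average of each coordinate, sugar pucker distribution, end-to-end
#' distances, slide-roll form classification, optional RMSD against a
#' reference, and homo-dinucleotide (AA/TT/CC/GG) group averages.
#'
#' @param structure a [nucleic_structure()].
#' @param mode `"per-strand"` (steps within each strand independently; the
#'   single-strand and per-strand duplex analysis) or `"base-pair-steps"`
#'   (pair frames from Watson-Crick partners, then steps between pairs;
#'   duplexes only).
#' @param reference optional [nucleic_structure()] for RMSD after optimal
#'   superposition (all atoms common by name per residue position).
#' @param model model number to analyze.
#' @param boundary slide-roll dividing line, see [classify_form()].
#' @param allow_mismatch tolerate non-complementary duplexes.
#' @return Object of class `structure_report`.
#' @export
analyze_structure <- function(structure,
                              mode = c("per-strand", "base-pair-steps"),
                              reference = NULL, model = 1,
                              boundary = c(intercept = 4, slope = -4),
                              allow_mismatch = FALSE) {
  stopifnot(inherits(structure, "nucleic_structure"))
  mode <- match.arg(mode)
  rt <- residue_table(structure)
  steps <- NULL
  if (mode == "per-strand") {
    for (ch in structure$chains) {
      frames <- fit_frames(structure, ch, model)
      rtc <- rt[rt$chain == ch, , drop = FALSE]
      st <- step_series(frames, labels = step_labels_for(rtc))
      if (nrow(st) > 0) {
        st <- cbind(chain = ch, st, stringsAsFactors = FALSE)
        steps <- rbind(steps, st)
      }
    }
  } else {
    check_duplex(structure, allow_mismatch = allow_mismatch)
    ch1 <- structure$chains[1]; ch2 <- structure$chains[2]
    f1 <- fit_frames(structure, ch1, model)
    f2 <- fit_frames(structure, ch2, model)
    n <- length(f1)
    pframes <- lapply(seq_len(n), function(i)
      pair_frame(f1[[i]], f2[[n + 1 - i]]))
    rtc <- rt[rt$chain == ch1, , drop = FALSE]
    steps <- step_series(pframes, labels = step_labels_for(rtc))
    steps <- cbind(chain = "pair", steps, stringsAsFactors = FALSE)
  }
  averages <- if (!is.null(steps) && nrow(steps) > 0)
    average_step_params(steps) else NULL
  pucker <- do.call(rbind, lapply(seq_len(nrow(rt)), function(r) {
    res <- get_residue(structure, rt$chain[r], rt$resno[r], model)
    p <- tryCatch(sugar_pucker(res), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    data.frame(chain = rt$chain[r], resno = rt$resno[r], base = rt$base[r],
               P = p$P, tau_m = p$tau_m, label = p$label,
               stringsAsFactors = FALSE)
  }))
  e2e <- vapply(structure$chains, function(ch)
    tryCatch(end_to_end(structure, ch, model), error = function(e)
      NA_real_), numeric(1))
  classification <- if (!is.null(steps) && nrow(steps) > 0)
    classify_form(steps, boundary = boundary) else NULL
  rmsd <- if (!is.null(reference))
    rmsd_superposed(structure, reference, model1 = model) else NULL
  homo <- homo_step_averages(steps)
  structure(list(mode = mode, steps = steps, averages = averages,
                 pucker = pucker, end_to_end = e2e,
                 classification = classification, rmsd = rmsd,
                 homo_groups = homo, boundary = boundary),
            class = "structure_report")
}

# Average coordinates per homo-dinucleotide step type (AA, TT, CC, GG),
# pooling steps from all strands of the table.
homo_step_averages <- function(steps) {
  if (is.null(steps) || nrow(steps) == 0) return(NULL)
  type <- gsub("\\([0-9]+\\)", "", steps$step_label)
  homo <- type %in% c("A/A", "T/T", "C/C", "G/G")
  if (!any(homo)) return(NULL)
  out <- stats::aggregate(steps[homo, STEP_COLS],
                          by = list(step_type = type[homo]), FUN = mean)
  out$n_steps <- as.integer(table(type[homo])[out$step_type])
  out
}

#' @export
print.structure_report <- function(x, digits = 2, ...) {
  cat("<structure_report> mode:", x$mode, "\n")
  if (!is.null(x$steps)) {
    cat("\nper-step parameters:\n")
    st <- x$steps
    st[STEP_COLS] <- lapply(st[STEP_COLS], round, digits)
    print(st, row.names = FALSE)
  }
  if (!is.null(x$averages)) {
    cat("\naverages:\n")
    print(round(x$averages, digits))
  }
  if (!is.null(x$homo_groups)) {
    cat("\nhomo-step group averages:\n")
    hg <- x$homo_groups
    hg[STEP_COLS] <- lapply(hg[STEP_COLS], round, digits)
    print(hg, row.names = FALSE)
  }
  if (!is.null(x$pucker)) {
    cat("\nsugar puckers:\n")
    print(table(x$pucker$label))
  }
  cat("\nend-to-end (A):",
      paste(names(x$end_to_end),
            sprintf("%.2f", x$end_to_end), collapse = ", "), "\n")
  if (!is.null(x$rmsd))
    cat("RMSD vs reference (A):", sprintf("%.3f", x$rmsd), "\n")
  if (!is.null(x$classification))
    cat("step forms:", paste(x$classification$form, collapse = " "), "\n")
  invisible(x)
}

#' Write a structure report to TSV files
#'
#' Emits `<prefix>_steps.tsv` (step table in the documented column order),
#' `<prefix>_pucker.tsv`, `<prefix>_slide_roll.tsv` (scatter data with
#' form labels) and `<prefix>_summary.txt` (key-value block with averages,
#' end-to-end distances, optional RMSD and the configuration used).
#'
#' @param report a `structure_report`.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, prefix) {
  stopifnot(inherits(report, "structure_report"))
  files <- character(0)
  if (!is.null(report$steps)) {
    f <- paste0(prefix, "_steps.tsv")
    utils::write.table(report$steps, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(report$pucker)) {
    f <- paste0(prefix, "_pucker.tsv")
    utils::write.table(report$pucker, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(report$classification)) {
    f <- paste0(prefix, "_slide_roll.tsv")
    utils::write.table(report$classification, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- paste0(prefix, "_summary.txt")
  con <- file(f, "w")
  on.exit(close(con))
  kv <- function(k, v) writeLines(paste0(k, "\t", v), con)
  kv("mode", report$mode)
  if (!is.null(report$averages))
    for (nm in names(report$averages))
      kv(paste0("mean_", nm), format(report$averages[[nm]]))
  for (ch in names(report$end_to_end))
    kv(paste0("end_to_end_", ch), format(report$end_to_end[[ch]]))
  if (!is.null(report$rmsd)) kv("rmsd", format(report$rmsd))
  kv("boundary_intercept", report$boundary[["intercept"]])
  kv("boundary_slope", report$boundary[["slope"]])
  files <- c(files, f)
  invisible(files)
}
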