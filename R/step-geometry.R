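# The six base-step rigid-body coordinates and the two helical coordinates
# between consecutive base (or base-pair) frames, plus the exact inverse
# used by the fiber generator.
#
# Mid-frame construction: the bending angle gamma between the two z-axes is
# removed symmetrically by rotating each frame by -/+ gamma/2 about the
# hinge axis z_i x z_j; twist is then the angle between the rotated y-axes
# about the common z, translations are read in the mid-frame whose y-axis
# bisects the rotated y-axes, and gamma is decomposed into roll/tilt by the
# hinge's phase angle from the mid-frame y-axis.

#' Base-step rigid-body parameters between two frames
#'
#' Computes shift, slide, rise (Angstrom) and tilt, roll, twist (degrees)
#' with the mid-frame (CEHS-style) construction, plus the helical rise and
#' twist via [helical_parameters()].  The helical coordinates coincide with
#' rise and twist exactly when shift, slide, tilt and roll all vanish.
#'
#' @param frame_i,frame_j [base_frame()]s of the 5' and 3' members of the
#'   step, in that order.
#' @param step_label optional label such as `"C(5)/C(6)"`.
#' @return Object of class `step_params`: named list with `shift`, `slide`,
#'   `rise`, `tilt`, `roll`, `twist`, `h_rise`, `h_twist`, `step_label`.
#' @export
step_parameters <- function(frame_i, frame_j, step_label = NA_character_) {
  stopifnot(inherits(frame_i, "base_frame"), inherits(frame_j, "base_frame"))
  R1 <- frame_i$axes; R2 <- frame_j$axes
  z1 <- R1[, 3]; z2 <- R2[, 3]
  hinge <- pracma_cross(z1, z2)
  sg <- vnorm(hinge)
  cg <- min(1, max(-1, sum(z1 * z2)))
  gamma <- atan2(sg, cg) / DEG
  if (gamma >= 90)
    stop("z-axes of the two frames subtend ", sprintf("%.1f", gamma),
         " degrees; step parameters are undefined for flipped bases")
  if (sg > 1e-9) {
    A1 <- rot_about(hinge, +gamma / 2)
    A2 <- rot_about(hinge, -gamma / 2)
  } else {
    hinge <- NULL
    A1 <- A2 <- diag(3)
  }
  R1p <- A1 %*% R1
  R2p <- A2 %*% R2
  zm <- R1p[, 3]
  twist <- signed_angle(R1p[, 2], R2p[, 2], zm)
  ym <- unitv(R1p[, 2] + R2p[, 2])
  xm <- unitv(pracma_cross(ym, zm))
  Rm <- cbind(xm, ym, zm)
  disp <- as.vector(t(Rm) %*% (frame_j$origin - frame_i$origin))
  if (!is.null(hinge)) {
    h <- unitv(hinge)
    phi <- atan2(sum(h * xm), sum(h * ym)) / DEG
    roll <- gamma * cos(phi * DEG)
    tilt <- gamma * sin(phi * DEG)
  } else {
    roll <- tilt <- 0
  }
  hel <- helical_parameters(frame_i, frame_j)
  structure(list(shift = disp[1], slide = disp[2], rise = disp[3],
                 tilt = tilt, roll = roll, twist = wrap180(twist),
                 h_rise = hel[["h_rise"]], h_twist = hel[["h_twist"]],
                 step_label = step_label),
            class = "step_params")
}

#' @export
print.step_params <- function(x, ...) {
  cat("<step_params>", if (!is.na(x$step_label)) x$step_label else "", "\n")
  v <- unlist(x[c("shift", "slide", "rise", "tilt", "roll", "twist",
                  "h_rise", "h_twist")])
  print(round(v, 3))
  invisible(x)
}

#' Helical rise and twist between two frames
#'
#' The relative rotation of the two frames is decomposed into a single
#' axis-angle pair: the helical twist is the rotation angle about that
#' helical axis (the rotation bringing consecutive bases or pairs into
#' coincidence), and the helical rise is the inter-origin vector projected
#' onto the axis, signed along the 5'->3' advance.  When the relative
#' rotation is below 0.01 degrees the mid-frame z-axis serves as the
#' helical axis (pure-translation convention).
#'
#' @inheritParams step_parameters
#' @param centers optional list of two length-3 positions (e.g. base
#'   geometric centers) whose difference is projected instead of the
#'   frame-origin difference.
#' @return Named numeric: `h_rise` (Angstrom), `h_twist` (degrees).
#' @export
helical_parameters <- function(frame_i, frame_j, centers = NULL) {
  stopifnot(inherits(frame_i, "base_frame"), inherits(frame_j, "base_frame"))
  rel <- frame_j$axes %*% t(frame_i$axes)
  aa <- axis_angle(rel)
  zm <- unitv(frame_i$axes[, 3] + frame_j$axes[, 3])
  d <- if (is.null(centers)) frame_j$origin - frame_i$origin else
    centers[[2]] - centers[[1]]
  if (aa$angle < 0.01) {
    return(c(h_rise = sum(d * zm), h_twist = 0))
  }
  axis <- aa$axis
  ang <- aa$angle
  if (sum(axis * zm) < 0) {
    axis <- -axis
    ang <- -ang
  }
  c(h_rise = sum(d * axis), h_twist = wrap180(ang))
}

#' Build the 3' frame of a step from parameters
#'
#' Exact inverse of [step_parameters()]: chaining `build_step` then
#' measuring recovers the input parameters to numerical precision.
#'
#' @param frame_i the 5' [base_frame()].
#' @param params a `step_params` object or named list/vector providing
#'   `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`.
#' @return The 3' [base_frame()].
#' @export
build_step <- function(frame_i, params) {
  stopifnot(inherits(frame_i, "base_frame"))
  p <- unlist(params[c("shift", "slide", "rise", "tilt", "roll", "twist")])
  if (anyNA(p) || any(!is.finite(p)))
    stop("step parameters must supply finite shift, slide, rise, tilt, ",
         "roll, twist")
  gamma <- sqrt(p[["roll"]]^2 + p[["tilt"]]^2)
  if (gamma >= 90)
    stop("combined roll/tilt bending angle ", sprintf("%.1f", gamma),
         " degrees is out of range (< 90 required)")
  phi <- atan2(p[["tilt"]], p[["roll"]]) / DEG
  omega <- p[["twist"]]
  # hinge axis in mid-frame coordinates
  h_local <- c(sin(phi * DEG), cos(phi * DEG), 0)
  Rz_half <- rot_about(c(0, 0, 1), omega / 2)
  Rh_half <- rot_about(h_local, gamma / 2)
  Rm <- frame_i$axes %*% Rz_half %*% Rh_half
  R2 <- Rm %*% Rh_half %*% Rz_half
  o2 <- frame_i$origin +
    as.vector(Rm %*% c(p[["shift"]], p[["slide"]], p[["rise"]]))
  base_frame(origin = o2, axes = R2, fit_rmsd = 0,
             residue_ref = frame_i$residue_ref)
}

#' Step parameters along a strand or pair-frame series
#'
#' @param frames list of [base_frame()]s in 5'->3' order.
#' @param labels optional character labels, length `length(frames) - 1`.
#' @return data.frame with one row per step and columns `step_label`,
#'   `shift`, `slide`, `rise`, `tilt`, `roll`, `twist`, `h_rise`,
#'   `h_twist` (the documented TSV column order).
#' @export
step_series <- function(frames, labels = NULL) {
  n <- length(frames)
  if (n < 2)
    return(data.frame(step_label = character(0), shift = numeric(0),
                      slide = numeric(0), rise = numeric(0),
                      tilt = numeric(0), roll = numeric(0),
                      twist = numeric(0), h_rise = numeric(0),
                      h_twist = numeric(0), stringsAsFactors = FALSE))
  if (is.null(labels)) labels <- paste0("step", seq_len(n - 1))
  rows <- lapply(seq_len(n - 1), function(i) {
    sp <- step_parameters(frames[[i]], frames[[i + 1]], labels[i])
    data.frame(step_label = labels[i], shift = sp$shift, slide = sp$slide,
               rise = sp$rise, tilt = sp$tilt, roll = sp$roll,
               twist = sp$twist, h_rise = sp$h_rise, h_twist = sp$h_twist,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
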