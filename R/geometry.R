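# Geometry-level synthesis: build a 20-point landmark set whose facial
# metrics match a target metric vector, by deforming a template face.
#
# The template fixes the dimensionless facial proportions that the seven
# metrics do not constrain (vertical placement of cheeks/jaw relative to
# the lower face, inner-eye span relative to cheek width, ...). Widths,
# heights and the overall mm scale are then solved from the targets: the
# lower-face polygon is shape-similar under the ratio constraints, so its
# perimeter-to-area ratio scales exactly as 1/size and pins the scale.

#' Synthetic template face
#'
#' An anatomically plausible 20-point landmark set in mm (image convention,
#' y downward), used as the deformation template for geometry-level
#' synthesis. This is a synthetic construction, not a measured face.
#'
#' @return A `landmark_set` in mm.
#' @export
face_template <- function() {
  pts <- rbind(
    P1 = c(0, 0), P2 = c(0, 180),
    P3 = c(-70, 90), P4 = c(70, 90),
    P5 = c(-60, 130), P6 = c(60, 130),
    P7 = c(0, 55), P8 = c(0, 120),
    P9 = c(-47, 72), P10 = c(47, 72),
    P11 = c(-16, 72), P12 = c(16, 72),
    P13 = c(-30, 70), P14 = c(30, 70),
    P9p = c(-47, 55), P10p = c(47, 55),
    P11p = c(-16, 55), P12p = c(16, 55),
    P13p = c(-30, 53), P14p = c(30, 53)
  )
  colnames(pts) <- c("x", "y")
  landmark_set("template", pts, unit = "mm")
}

# Dimensionless proportions of a template that the metrics leave free.
template_proportions <- function(template) {
  p <- template$points
  yp <- mean(p[c("P13", "P14"), "y"])
  a <- abs(p["P2", "y"] - yp)
  W <- abs(p["P4", "x"] - p["P3", "x"])
  list(
    yp = yp,
    cheek_f = (mean(p[c("P3", "P4"), "y"]) - yp) / a,
    jaw_f = (mean(p[c("P5", "P6"), "y"]) - yp) / a,
    eye_f = (mean(p[c("P9", "P10", "P11", "P12"), "y"]) - yp) / a,
    p7_f = (p["P7", "y"] - yp) / a,
    ein_f = abs(p["P12", "x"] - p["P11", "x"]) / W,
    pup_f = abs(p["P14", "x"] - p["P13", "x"]) / W
  )
}

# Build a landmark set from explicit dimensions + template proportions.
build_face <- function(W, a, J, H78, FH, eout, ein, ehh, prop, subject_id) {
  yp <- prop$yp
  ycheek <- yp + prop$cheek_f * a
  yjaw <- yp + prop$jaw_f * a
  yeye <- yp + prop$eye_f * a
  y7 <- yp + prop$p7_f * a
  pts <- rbind(
    P1 = c(0, yp + a - FH), P2 = c(0, yp + a),
    P3 = c(-W / 2, ycheek), P4 = c(W / 2, ycheek),
    P5 = c(-J / 2, yjaw), P6 = c(J / 2, yjaw),
    P7 = c(0, y7), P8 = c(0, y7 + H78),
    P9 = c(-eout / 2, yeye), P10 = c(eout / 2, yeye),
    P11 = c(-ein / 2, yeye), P12 = c(ein / 2, yeye),
    P13 = c(-prop$pup_f * W / 2, yp), P14 = c(prop$pup_f * W / 2, yp),
    P9p = c(-eout / 2, yeye - ehh), P10p = c(eout / 2, yeye - ehh),
    P11p = c(-ein / 2, yeye - ehh), P12p = c(ein / 2, yeye - ehh),
    P13p = c(-prop$pup_f * W / 2, yp - ehh),
    P14p = c(prop$pup_f * W / 2, yp - ehh)
  )
  colnames(pts) <- c("x", "y")
  landmark_set(subject_id, pts, unit = "mm")
}

#' Synthesize a landmark set matching a target metric vector
#'
#' Deforms the template (independent cheek/jaw width scalings, lower-face
#' and fWHR-height scalings, eye-corner and eyebrow offsets, global mm
#' scale) and iterates until all seven metrics of the output match the
#' targets within relative tolerance.
#'
#' @param targets Named numeric vector with elements `PAR`, `WHR`, `CJWR`,
#'   `eye_size`, `LF_FH`, `FW_LFH`, `EH_mean`.
#' @param template A `landmark_set`; defaults to [face_template()].
#' @param subject_id Identifier for the output.
#' @param tol Relative tolerance on each metric (default 1e-6).
#' @param max_iter Maximum deformation iterations.
#' @return A `landmark_set` whose [metric_vector()] matches `targets`.
#' @export
landmarks_from_metrics <- function(targets, template = face_template(),
                                   subject_id = "synthetic", tol = 1e-6,
                                   max_iter = 50L) {
  mets <- metric_names()
  if (!all(mets %in% names(targets)))
    stop("targets must name all of: ", paste(mets, collapse = ", "))
  targets <- targets[mets]
  if (any(!is.finite(targets)) ||
      any(targets[c("PAR", "WHR", "CJWR", "LF_FH", "FW_LFH", "EH_mean")] <= 0))
    stop("metric targets must be finite and positive")
  prop <- template_proportions(template)
  W0 <- abs(template$points["P4", "x"] - template$points["P3", "x"])
  adj <- targets  # working targets, multiplicatively corrected if needed
  for (iter in seq_len(max_iter)) {
    # dimensions implied by the ratio targets at a provisional width W0,
    # then global rescale so the lower-face polygon PAR is exact
    a <- W0 / adj[["FW_LFH"]]
    J <- W0 / adj[["CJWR"]]
    H78 <- W0 / adj[["WHR"]]
    FH <- a / adj[["LF_FH"]]
    lm0 <- build_face(W0, a, J, H78, FH, eout = W0 * 0.67,
                      ein = prop$ein_f * W0, ehh = adj[["EH_mean"]],
                      prop = prop, subject_id = subject_id)
    s <- face_par(lm0) / adj[["PAR"]]
    W <- W0 * s
    ein <- prop$ein_f * W
    lm <- build_face(W, a * s, J * s, H78 * s, FH * s,
                     eout = ein + 2 * adj[["eye_size"]], ein = ein,
                     ehh = adj[["EH_mean"]], prop = prop,
                     subject_id = subject_id)
    got <- metric_vector(lm)[mets]
    rel <- abs(got - targets) / pmax(abs(targets), .Machine$double.eps)
    if (all(rel < tol)) return(lm)
    adj <- adj * targets / got
  }
  worst <- mets[which.max(rel)]
  stop(sprintf("geometry synthesis did not converge for metric %s (rel err %.2e)",
               worst, max(rel)))
}

#' Generate geometry-level synthetic subjects
#'
#' For each metric-level synthetic subject, synthesizes a full 20-point
#' landmark set whose computed metrics equal the subject's sampled metric
#' values (relative tolerance 1e-6), so that geometry-level and
#' metric-level generators agree in distribution by construction.
#'
#' @param records data.frame from [generate_metric_level()].
#' @param template A `landmark_set` template.
#' @param tol Relative tolerance passed to [landmarks_from_metrics()].
#' @return Named list of `landmark_set` objects, one per record.
#' @export
generate_geometry_level <- function(records, template = face_template(),
                                    tol = 1e-6) {
  mets <- metric_names()
  out <- lapply(seq_len(nrow(records)), function(i) {
    targets <- unlist(records[i, mets])
    landmarks_from_metrics(targets, template = template,
                           subject_id = records$subject_id[i], tol = tol)
  })
  names(out) <- records$subject_id
  out
}
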