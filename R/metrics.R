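# Facial metric computations on a 20-point landmark set.
#
# All distances are Euclidean in mm except the lower-face height `a`, which
# is a vertical (|dy|) distance between the chin line and the pupil line,
# matching the image convention under which heads are aligned so that the
# pupil line is horizontal.

dist2 <- function(p, q) sqrt(sum((p - q)^2))

lpoint <- function(lm, name) lm$points[name, ]

require_mm <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (lm$unit != "mm")
    stop("landmarks must be in mm; call as_mm() or pass scale= when reading")
  lm
}

#' Polygon perimeter and shoelace area
#'
#' Closed-cycle perimeter and absolute shoelace (surveyor's) area of a
#' simple polygon given as an n x 2 vertex matrix in order. The closing
#' edge from the last vertex back to the first is included.
#'
#' @param verts n x 2 numeric matrix of vertices in cyclic order.
#' @return List with `perimeter` and `area`.
#' @export
polygon_measure <- function(verts) {
  verts <- as.matrix(verts)
  n <- nrow(verts)
  if (n < 3) stop("polygon needs at least 3 vertices")
  nxt <- c(2:n, 1)
  per <- sum(sqrt(rowSums((verts[nxt, , drop = FALSE] - verts)^2)))
  area <- abs(sum(verts[, 1] * verts[nxt, 2] - verts[nxt, 1] * verts[, 2])) / 2
  list(perimeter = per, area = area)
}

# Segment intersection test used for the polygon-simplicity diagnostic.
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 != o2) && (o3 != o4) && all(c(o1, o2, o3, o4) != 0)
}

polygon_is_simple <- function(verts) {
  n <- nrow(verts)
  nxt <- c(2:n, 1)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (shared endpoint)
      if (j == i || j == i %% n + 1 || i == j %% n + 1) next
      if (segments_cross(verts[i, ], verts[nxt[i], ],
                         verts[j, ], verts[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

lower_face_polygon <- function(lm) {
  rbind(lpoint(lm, "P3"), lpoint(lm, "P5"), lpoint(lm, "P2"), lpoint(lm, "P6"), lpoint(lm, "P4"))
}

#' Perimeter-to-area ratio (PAR)
#'
#' Ratio of the closed perimeter of the lower-face polygon
#' P3-P5-P2-P6-P4-P3 to its enclosed (shoelace) area, in 1/mm. Lower PAR
#' means a rounder lower face.
#'
#' @param lm A `landmark_set` in mm.
#' @return PAR in 1/mm.
#' @export
face_par <- function(lm) {
  lm <- require_mm(lm)
  verts <- lower_face_polygon(lm)
  if (!polygon_is_simple(verts))
    stop(sprintf("subject %s: lower-face polygon P3-P5-P2-P6-P4 is self-intersecting",
                 lm$subject_id))
  m <- polygon_measure(verts)
  if (m$area <= .Machine$double.eps)
    stop(sprintf("subject %s: lower-face polygon has zero area", lm$subject_id))
  m$perimeter / m$area
}

#' Facial width-to-height ratio (WHR)
#'
#' Cheekbone width d(P3,P4) divided by the brow-to-upper-lip height
#' d(P7,P8). Larger WHR indicates a wider face.
#'
#' @param lm A `landmark_set` in mm.
#' @return WHR, dimensionless.
#' @export
face_whr <- function(lm) {
  lm <- require_mm(lm)
  h <- dist2(lpoint(lm, "P7"), lpoint(lm, "P8"))
  if (h <= 0) stop("d(P7,P8) is zero; WHR undefined")
  dist2(lpoint(lm, "P3"), lpoint(lm, "P4")) / h
}

#' Cheek-to-jaw-width ratio (CJWR)
#'
#' Cheekbone width d(P3,P4) divided by jaw width d(P5,P6). Smaller CJWR
#' indicates a squarer face.
#'
#' @param lm A `landmark_set` in mm.
#' @return CJWR, dimensionless.
#' @export
face_cjwr <- function(lm) {
  lm <- require_mm(lm)
  j <- dist2(lpoint(lm, "P5"), lpoint(lm, "P6"))
  if (j <= 0) stop("d(P5,P6) is zero; CJWR undefined")
  dist2(lpoint(lm, "P3"), lpoint(lm, "P4")) / j
}

#' Eye size (mm)
#'
#' Half the difference between the outer-corner span d(P9,P10) and the
#' inner-corner span d(P11,P12), i.e. the mean single-eye width. A negative
#' value (inner span wider than outer span) is anatomically impossible and
#' triggers a warning, but the value is still returned.
#'
#' @param lm A `landmark_set` in mm.
#' @return Eye size in mm.
#' @export
eye_size <- function(lm) {
  lm <- require_mm(lm)
  v <- (dist2(lpoint(lm, "P9"), lpoint(lm, "P10")) -
          dist2(lpoint(lm, "P11"), lpoint(lm, "P12"))) / 2
  if (v < 0)
    warning(sprintf("subject %s: negative eye size (check landmark order)",
                    lm$subject_id))
  v
}

# Lower-face height a: vertical distance between the horizontal line
# through the chin (P2) and the horizontal line through the two pupils.
lower_face_height <- function(lm) {
  abs(lpoint(lm, "P2")["y"] - mean(c(lpoint(lm, "P13")["y"], lpoint(lm, "P14")["y"])))
}

#' Lower-face to face-height ratio (LF/FH)
#'
#' The vertical distance `a` between the chin line and the pupil line,
#' divided by the full face height d(P1,P2).
#'
#' @param lm A `landmark_set` in mm.
#' @return LF/FH, dimensionless.
#' @export
lf_fh <- function(lm) {
  lm <- require_mm(lm)
  fh <- dist2(lpoint(lm, "P1"), lpoint(lm, "P2"))
  if (fh <= 0) stop("d(P1,P2) is zero; LF/FH undefined")
  unname(lower_face_height(lm) / fh)
}

#' Face-width to lower-face-height ratio (FW/LFH)
#'
#' Cheekbone width d(P3,P4) divided by the lower-face height `a`.
#'
#' @param lm A `landmark_set` in mm.
#' @return FW/LFH, dimensionless.
#' @export
fw_lfh <- function(lm) {
  lm <- require_mm(lm)
  a <- lower_face_height(lm)
  if (a <= 0) stop("lower-face height a is zero; FW/LFH undefined")
  unname(dist2(lpoint(lm, "P3"), lpoint(lm, "P4")) / a)
}

#' Mean eyebrow height (mm)
#'
#' Arithmetic mean of the six Euclidean distances from P9..P14 to their
#' primed eyebrow points P9p..P14p.
#'
#' @param lm A `landmark_set` in mm.
#' @return Mean eyebrow height in mm.
#' @export
eh_mean <- function(lm) {
  lm <- require_mm(lm)
  mean(vapply(9:14, function(k)
    dist2(lpoint(lm, paste0("P", k)), lpoint(lm, paste0("P", k, "p"))), numeric(1)))
}

#' All seven facial metrics for one subject
#'
#' @param lm A `landmark_set` in mm.
#' @return Named numeric vector with elements `PAR` (1/mm), `WHR`, `CJWR`,
#'   `eye_size` (mm), `LF_FH`, `FW_LFH`, `EH_mean` (mm) and the
#'   intermediate lower-face height `a` (mm).
#' @export
metric_vector <- function(lm) {
  lm <- require_mm(lm)
  c(PAR = face_par(lm), WHR = face_whr(lm), CJWR = face_cjwr(lm),
    eye_size = eye_size(lm), LF_FH = lf_fh(lm), FW_LFH = fw_lfh(lm),
    EH_mean = eh_mean(lm), a = unname(lower_face_height(lm)))
}

#' Metric names
#'
#' The seven facial metrics in canonical order.
#' @return Character vector.
#' @export
metric_names <- function() {
  c("PAR", "WHR", "CJWR", "eye_size", "LF_FH", "FW_LFH", "EH_mean")
}

#' Per-subject metrics table
#'
#' @param lms List of `landmark_set` objects (mm).
#' @return data.frame with subject_id and metric columns.
#' @export
metrics_table <- function(lms) {
  if (inherits(lms, "landmark_set")) lms <- list(lms)
  out <- do.call(rbind, lapply(lms, function(lm)
    data.frame(subject_id = lm$subject_id, t(metric_vector(lm)),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Test-retest reliability as coefficient of variation
#'
#' For each subject measured at least twice, the per-metric coefficient of
#' variation 100 * SD / mean across the repeats; summarised as the min-max
#' range over subjects per metric.
#'
#' @param repeated A data.frame with columns `subject_id` plus metric
#'   columns, at least two rows per subject (e.g. from [metrics_table()]
#'   applied to repeated landmarkings).
#' @return List with `per_subject` (data.frame of CV% per subject x metric)
#'   and `range` (data.frame metric, min_cv, max_cv).
#' @export
reliability_cv <- function(repeated) {
  mets <- intersect(metric_names(), names(repeated))
  if (!length(mets)) stop("no metric columns found")
  counts <- table(repeated$subject_id)
  if (any(counts < 2))
    stop("each subject needs at least 2 repeated measurements")
  per <- do.call(rbind, lapply(split(repeated, repeated$subject_id), function(d) {
    cvs <- vapply(mets, function(m) 100 * sd(d[[m]]) / mean(d[[m]]), numeric(1))
    data.frame(subject_id = d$subject_id[1], t(cvs), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  rng <- data.frame(
    metric = mets,
    min_cv = vapply(mets, function(m) min(per[[m]]), numeric(1)),
    max_cv = vapply(mets, function(m) max(per[[m]]), numeric(1)),
    row.names = NULL
  )
  list(per_subject = per, range = rng)
}
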