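#' @importFrom stats aov anova as.formula atanh coef complete.cases cor
#'   glm.fit lm model.matrix na.omit pchisq pf pnorm pt ptukey qnorm qtukey
#'   quantile rbinom rnorm runif sd setNames var vcov binomial plogis
#' @importFrom utils read.csv write.csv
NULL

# 20-point facial landmark scheme: P1..P14 plus primed eyebrow points
# P9p..P14p directly above P9..P14 (ASCII encoding of the prime glyph).
LANDMARK_POINTS <- c(paste0("P", 1:14), paste0("P", 9:14, "p"))

#' Landmark point semantics
#'
#' Returns the package's documented convention for what each of the 20
#' facial landmark points denotes. The published point scheme is a figure,
#' not a machine-readable table, so the mapping is shipped as data and can
#' be inspected (and, for the eye/pupil points, reinterpreted) by the user.
#'
#' @return A data.frame with columns `point` and `meaning`.
#' @export
landmark_scheme <- function() {
  data.frame(
    point = LANDMARK_POINTS,
    meaning = c(
      "top of forehead, midline",
      "chin (menton), midline",
      "left cheekbone extreme (zygion)",
      "right cheekbone extreme (zygion)",
      "left jaw point (gonion)",
      "right jaw point (gonion)",
      "midline brow point (upper endpoint of fWHR height)",
      "midline upper-lip point (lower endpoint of fWHR height)",
      "left outer eye corner (exocanthion)",
      "right outer eye corner (exocanthion)",
      "left inner eye corner (endocanthion)",
      "right inner eye corner (endocanthion)",
      "left pupil center",
      "right pupil center",
      "eyebrow point above P9",
      "eyebrow point above P10",
      "eyebrow point above P11",
      "eyebrow point above P12",
      "eyebrow point above P13",
      "eyebrow point above P14"
    ),
    stringsAsFactors = FALSE
  )
}

#' Construct a landmark set for one subject
#'
#' A `landmark_set` holds the 20 named 2-D facial points of one subject in
#' image convention: x increases rightward, y increases downward, so a
#' "vertical" distance is `abs(diff(y))`. Coordinates may be in pixels (with
#' a positive mm-per-pixel scale) or directly in millimetres.
#'
#' @param subject_id Opaque subject identifier.
#' @param points A 20 x 2 numeric matrix with rownames exactly the point
#'   names `P1..P14, P9p..P14p` and columns `x`, `y`.
#' @param unit `"mm"` or `"pixel"`.
#' @param mm_per_pixel Positive scale factor; required when `unit = "pixel"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, points, unit = c("mm", "pixel"),
                         mm_per_pixel = NULL) {
  unit <- match.arg(unit)
  points <- as.matrix(points)
  if (is.null(colnames(points))) colnames(points) <- c("x", "y")
  if (ncol(points) != 2L)
    stop("points must have two columns (x, y)")
  missing <- setdiff(LANDMARK_POINTS, rownames(points))
  if (length(missing))
    stop(sprintf("subject %s: missing point %s", subject_id,
                 paste(missing, collapse = ", ")))
  dup <- rownames(points)[duplicated(rownames(points))]
  if (length(dup))
    stop(sprintf("subject %s: duplicate point %s", subject_id,
                 paste(unique(dup), collapse = ", ")))
  points <- points[LANDMARK_POINTS, , drop = FALSE]
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop(sprintf("subject %s: non-finite coordinate", subject_id))
  if (unit == "pixel") {
    if (is.null(mm_per_pixel) || !is.finite(mm_per_pixel) || mm_per_pixel <= 0)
      stop("mm_per_pixel must be a positive number when unit = 'pixel'")
  } else {
    mm_per_pixel <- NULL
  }
  structure(
    list(subject_id = as.character(subject_id), points = points,
         unit = unit, mm_per_pixel = mm_per_pixel),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject %s, 20 points, unit = %s\n",
              x$subject_id, x$unit))
  invisible(x)
}

#' Convert a landmark set to millimetres
#'
#' @param lm A `landmark_set`.
#' @return A `landmark_set` with `unit = "mm"`.
#' @export
as_mm <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  if (lm$unit == "mm") return(lm)
  landmark_set(lm$subject_id, lm$points * lm$mm_per_pixel, unit = "mm")
}

#' Read landmark tables
#'
#' Reads a delimited text file with columns `subject_id`, `point`, `x`, `y`
#' (header required) into one `landmark_set` per subject. When `scale` is
#' given, coordinates are interpreted as pixels and converted to mm.
#'
#' @param path Path to a CSV/TSV landmark table.
#' @param scale mm-per-pixel factor, or `NULL` if coordinates are already mm.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A named list of `landmark_set` objects (mm units).
#' @export
read_landmarks <- function(path, scale = NULL, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "point", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns subject_id, point, x, y")
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("non-numeric coordinate in landmark file")
  out <- lapply(split(df, df$subject_id), function(d) {
    pts <- as.matrix(d[, c("x", "y")])
    rownames(pts) <- d$point
    if (is.null(scale)) {
      landmark_set(d$subject_id[1], pts, unit = "mm")
    } else {
      as_mm(landmark_set(d$subject_id[1], pts, unit = "pixel",
                         mm_per_pixel = scale))
    }
  })
  out[unique(df$subject_id)]
}

#' Write landmark tables
#'
#' Inverse of [read_landmarks()]: writes one row per (subject, point).
#'
#' @param lms A list of `landmark_set` objects.
#' @param path Output CSV path.
#' @export
write_landmarks <- function(lms, path) {
  if (inherits(lms, "landmark_set")) lms <- list(lms)
  rows <- do.call(rbind, lapply(lms, function(lm) {
    data.frame(subject_id = lm$subject_id, point = rownames(lm$points),
               x = lm$points[, "x"], y = lm$points[, "y"],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject demographics
#'
#' @param path CSV with columns `subject_id`, `sex` (M/F), `age_group`
#'   (20s/60s), `type` (TE/SE/SY), `height_m`, `weight_kg`.
#' @return A data.frame with an added `bmi` column (kg/m^2).
#' @export
read_demographics <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age_group", "type", "height_m", "weight_kg")
  if (!all(need %in% names(df)))
    stop("demographics file must have columns ", paste(need, collapse = ", "))
  df$bmi <- mapply(compute_bmi, df$weight_kg, df$height_m)
  df
}

#' Body mass index
#'
#' BMI in kg/m^2: weight in kilograms divided by the square of height in
#' metres.
#'
#' @param weight_kg Body weight, kg (> 0).
#' @param height_m Standing height, m (> 0).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(76.1, 1.754)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (!is.finite(weight_kg) || weight_kg <= 0)
    stop("weight_kg must be positive")
  if (!is.finite(height_m) || height_m <= 0)
    stop("height_m must be positive")
  weight_kg / height_m^2
}
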