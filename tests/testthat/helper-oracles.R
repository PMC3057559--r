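# Shared fixtures and independent oracles used across the test files.

# Random star-shaped (hence simple) polygon: vertices at sorted angles
# around the origin with random radii. Angular gaps are kept below pi so
# the origin is strictly interior and the origin-fan triangulation is an
# exact decomposition.
random_simple_polygon <- function(n_min = 3, n_max = 10) {
  n <- sample(n_min:n_max, 1)
  repeat {
    th <- sort(runif(n, 0, 2 * pi))
    gaps <- diff(c(th, th[1] + 2 * pi))
    if (max(gaps) < 0.95 * pi) break
  }
  r <- runif(n, 0.5, 10)
  cbind(x = r * cos(th), y = r * sin(th))
}

# Triangulation oracle: fan from the origin (the star center of the
# polygons built above), each triangle's area via Heron's formula from its
# side lengths -- a computation path independent of the shoelace algebra.
triangulation_area <- function(verts) {
  n <- nrow(verts)
  nxt <- c(2:n, 1)
  sum(vapply(1:n, function(i) {
    side <- sort(c(sqrt(sum(verts[i, ]^2)),
                   sqrt(sum(verts[nxt[i], ]^2)),
                   sqrt(sum((verts[i, ] - verts[nxt[i], ])^2))),
                 decreasing = TRUE)
    a <- side[1]; b <- side[2]; cc <- side[3]
    # Kahan's numerically stable Heron form
    0.25 * sqrt(max((a + (b + cc)) * (cc - (a - b)) *
                      (cc + (a - b)) * (a + (b - cc)), 0))
  }, numeric(1)))
}

# Brute-force pairwise AUC oracle: fraction of (positive, negative) pairs
# where the positive outranks the negative, ties counting one half.
brute_force_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Perturb a template landmark set by iid Gaussian jitter on every
# coordinate (used for the reliability study).
jitter_landmarks <- function(lm, sd_mm) {
  pts <- lm$points + matrix(rnorm(length(lm$points), 0, sd_mm),
                            nrow(lm$points), 2)
  landmark_set(lm$subject_id, pts, unit = "mm")
}

# Write a landmark table CSV for the given landmark sets, return the path.
landmark_csv <- function(lms, dir = tempdir()) {
  path <- tempfile("landmarks", tmpdir = dir, fileext = ".csv")
  write_landmarks(lms, path)
  path
}

# M20s stratum generator at printed group sizes, used by several files.
m20s_records <- function(config = synthetic_config()) {
  generate_metric_level(config, strata = list(sex = "M", age_group = "20s"))
}
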