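# Facial metric formulas checked against direct arithmetic and geometric
# oracles on constructed landmark sets.

# helper: template with selected points overridden
with_points <- function(...) {
  pts <- face_template()$points
  repl <- list(...)
  for (nm in names(repl)) pts[nm, ] <- repl[[nm]]
  landmark_set("test", pts, unit = "mm")
}

test_that("PAR equals closed-cycle perimeter over shoelace area", {
  # degenerate square cycle: P5 and P2 coincide, so the polygon
  # P3-P5-P2-P6-P4 reduces to a square of side 89
  sq <- with_points(P3 = c(0, 0), P5 = c(0, 89), P2 = c(0, 89),
                    P6 = c(89, 89), P4 = c(89, 0))
  expect_equal(face_par(sq), 4 / 89, tolerance = 1e-12)

  # regular pentagon with circumradius R: closed form perimeter/area
  R <- 75
  th <- pi / 2 + 2 * pi * (0:4) / 5
  pent <- cbind(R * cos(th), R * sin(th))
  lmp <- with_points(P3 = pent[1, ], P5 = pent[2, ], P2 = pent[3, ],
                     P6 = pent[4, ], P4 = pent[5, ])
  expected <- (10 * sin(pi / 5)) / ((5 / 2) * sin(2 * pi / 5) * R)
  expect_equal(face_par(lmp), expected, tolerance = 1e-12)

  # scaling law: doubling all landmarks halves PAR
  tmpl <- face_template()
  doubled <- landmark_set("d", tmpl$points * 2, unit = "mm")
  expect_equal(face_par(doubled), face_par(tmpl) / 2, tolerance = 1e-12)

  # bowtie ordering is flagged as self-intersecting
  bow <- with_points(P3 = c(0, 0), P5 = c(100, 100), P2 = c(100, 0),
                     P6 = c(0, 100), P4 = c(50, 150))
  expect_error(face_par(bow), "self-intersecting")
})

test_that("width and height ratios follow their defining quotients", {
  lm <- with_points(P3 = c(-70, 90), P4 = c(70, 90),
                    P7 = c(0, 55), P8 = c(0, 125),
                    P5 = c(-60, 130), P6 = c(60, 130))
  expect_equal(face_whr(lm), 140 / 70, tolerance = 1e-12)
  expect_equal(face_cjwr(lm), 140 / 120, tolerance = 1e-12)

  lm2 <- with_points(P8 = c(0, 122))  # d(P7,P8) = 67
  expect_equal(face_whr(lm2), 140 / 67, tolerance = 1e-12)
  expect_equal(round(face_whr(lm2), 4), 2.0896)

  lm3 <- with_points(P5 = c(-62, 130), P6 = c(62, 130))
  expect_equal(round(face_cjwr(lm3), 3), 1.129)
  lm4 <- with_points(P5 = c(-70, 130), P6 = c(70, 130))
  expect_equal(face_cjwr(lm4), 1, tolerance = 1e-12)

  degenerate <- with_points(P3 = c(0, 90), P4 = c(0, 90))
  expect_equal(face_whr(degenerate), 0)
  expect_error(face_whr(with_points(P7 = c(0, 55), P8 = c(0, 55))), "WHR")
  expect_error(face_cjwr(with_points(P5 = c(0, 130), P6 = c(0, 130))), "CJWR")
})

test_that("eye size is half the outer-minus-inner corner span difference", {
  lm <- with_points(P9 = c(-47.5, 72), P10 = c(47.5, 72),
                    P11 = c(-15, 72), P12 = c(15, 72))
  expect_equal(eye_size(lm), (95 - 30) / 2, tolerance = 1e-12)
  lm2 <- with_points(P9 = c(-45, 72), P10 = c(45, 72),
                     P11 = c(-15, 72), P12 = c(15, 72))
  expect_equal(eye_size(lm2), 30)
  eq <- with_points(P9 = c(-15, 72), P10 = c(15, 72),
                    P11 = c(-15, 72), P12 = c(15, 72))
  expect_equal(eye_size(eq), 0)
  swapped <- with_points(P9 = c(-10, 72), P10 = c(10, 72),
                         P11 = c(-40, 72), P12 = c(40, 72))
  expect_warning(v <- eye_size(swapped), "negative eye size")
  expect_equal(v, -30)
})

test_that("face proportions use vertical chin-to-pupil distance a", {
  # a = |y(P2) - mean pupil y| = 110, face height 180
  lm <- with_points(P2 = c(0, 180), P1 = c(0, 0),
                    P13 = c(-30, 70), P14 = c(30, 70))
  expect_equal(lf_fh(lm), 110 / 180, tolerance = 1e-12)
  expect_equal(fw_lfh(lm), 140 / 110, tolerance = 1e-12)

  # pupils on the chin line: a = 0
  flat <- with_points(P13 = c(-30, 180), P14 = c(30, 180))
  expect_equal(lf_fh(flat), 0)
  expect_error(fw_lfh(flat), "FW/LFH")

  # a equal to full height when pupils sit at P1 level and P1P2 vertical
  tall <- with_points(P13 = c(-30, 0), P14 = c(30, 0))
  expect_equal(lf_fh(tall), 1, tolerance = 1e-12)

  # identity FW_LFH * LF_FH = width / d(P1,P2) when P1P2 vertical
  tmpl <- face_template()
  expect_equal(fw_lfh(tmpl) * lf_fh(tmpl),
               140 / 180, tolerance = 1e-12)
})

test_that("mean eyebrow height averages the six point-to-prime distances", {
  pts <- face_template()$points
  for (k in 9:14) pts[paste0("P", k, "p"), ] <-
    pts[paste0("P", k), ] - c(0, 16.6)
  lm <- landmark_set("t", pts, unit = "mm")
  expect_equal(eh_mean(lm), 16.6, tolerance = 1e-12)

  d <- c(10, 20, 10, 20, 10, 20)
  for (i in seq_along(9:14)) {
    k <- (9:14)[i]
    pts[paste0("P", k, "p"), ] <- pts[paste0("P", k), ] - c(0, d[i])
  }
  expect_equal(eh_mean(landmark_set("t", pts, unit = "mm")), 15)

  # random offsets (not axis-aligned) match a brute-force recomputation
  set.seed(7)
  for (k in 9:14) pts[paste0("P", k, "p"), ] <-
    pts[paste0("P", k), ] + rnorm(2, 0, 5)
  lm3 <- landmark_set("t", pts, unit = "mm")
  brute <- mean(sapply(9:14, function(k)
    sqrt(sum((pts[paste0("P", k), ] - pts[paste0("P", k, "p"), ])^2))))
  expect_equal(eh_mean(lm3), brute, tolerance = 1e-12)
})

test_that("metrics obey scaling and translation invariances", {
  set.seed(11)
  tmpl <- face_template()
  for (rep in 1:20) {
    s <- runif(1, 0.3, 3)
    shift <- rnorm(2, 0, 50)
    pts <- tmpl$points * s
    pts[, 1] <- pts[, 1] + shift[1]
    pts[, 2] <- pts[, 2] + shift[2]
    lm <- landmark_set("t", pts, unit = "mm")
    v0 <- metric_vector(tmpl)
    v1 <- metric_vector(lm)
    for (m in c("WHR", "CJWR", "LF_FH", "FW_LFH"))
      expect_equal(v1[[m]], v0[[m]], tolerance = 1e-9)
    expect_equal(v1[["PAR"]], v0[["PAR"]] / s, tolerance = 1e-9)
    expect_equal(v1[["eye_size"]], v0[["eye_size"]] * s, tolerance = 1e-9)
    expect_equal(v1[["EH_mean"]], v0[["EH_mean"]] * s, tolerance = 1e-9)
  }
})

test_that("shoelace area matches the triangulation oracle", {
  set.seed(3)
  for (i in 1:250) {
    poly <- random_simple_polygon()
    m <- polygon_measure(poly)
    expect_equal(m$area, triangulation_area(poly),
                 tolerance = 1e-9)
  }
})

test_that("test-retest coefficient of variation behaves as defined", {
  tmpl <- face_template()
  ident <- metrics_table(list(tmpl, tmpl, tmpl))
  ident$subject_id <- "s1"
  cv0 <- reliability_cv(ident)
  expect_true(all(cv0$range$min_cv == 0 & cv0$range$max_cv == 0))

  # direct two-repeat formula: values 10 and 10.1
  rep2 <- data.frame(subject_id = "s", PAR = c(10, 10.1))
  cv <- reliability_cv(rep2)
  expect_equal(cv$range$min_cv, 100 * sd(c(10, 10.1)) / 10.05,
               tolerance = 1e-12)
  expect_equal(round(cv$range$min_cv, 2), 0.70)

  expect_error(reliability_cv(data.frame(subject_id = c("a", "b"),
                                         PAR = c(1, 2))),
               "at least 2 repeated")

  # jittered landmarking of 15 subjects: small jitter keeps CVs in the
  # low single-digit percent range reported for manual relandmarking
  set.seed(21)
  reps <- do.call(rbind, lapply(1:15, function(i) {
    base <- jitter_landmarks(tmpl, 2)
    base$subject_id <- paste0("s", i)
    out <- metrics_table(list(jitter_landmarks(base, 0.8),
                              jitter_landmarks(base, 0.8)))
    out$subject_id <- paste0("s", i)
    out
  }))
  rng <- reliability_cv(reps)$range
  expect_true(all(rng$max_cv < 10))
  expect_true(all(rng$min_cv >= 0))
})
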