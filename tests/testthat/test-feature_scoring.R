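make_entry <- function(seq_str = "LVEAGVNKR", intensities = NULL) {
  p <- parse_proforma(seq_str)
  ft <- pinboost:::fragment_table(p, 1L)
  if (is.null(intensities)) {
    intensities <- seq(0.1, 1, length.out = nrow(ft))
  }
  ft$intensity <- intensities / max(intensities)
  predicted_entry(p, 2L, ft)
}

make_spectrum <- function(mz, intensity) {
  ord <- order(mz)
  structure(list(scan_number = 1L, precursor_mz = 500, precursor_charge = 2L,
                 retention_time = 10, mz = mz[ord], intensity = intensity[ord],
                 annotation = rep(NA_character_, length(mz)),
                 nce = NA_real_, instrument = NA_character_, title = "t"),
            class = "spectrum")
}

test_that("peak matching honors tolerance and one-use-per-peak", {
  e <- make_entry()
  # exact coincidence: experimental vector equals the peak intensities
  s <- make_spectrum(e$fragments$mz, e$fragments$intensity * 100)
  a <- match_peaks(s, e, tol = 20)
  expect_equal(a$experimental, e$fragments$intensity * 100)

  # a peak 30 ppm away is not matched at 20 ppm
  mz1 <- e$fragments$mz[1]
  s2 <- make_spectrum(mz1 * (1 + 30e-6), 50)
  a2 <- match_peaks(s2, e, tol = 20)
  expect_equal(sum(a2$experimental), 0)
  a3 <- match_peaks(s2, e, tol = 40)
  expect_equal(a3$experimental[1], 50)

  # two predicted fragments near one experimental peak: closer one wins
  p <- parse_proforma("GGGGGGK")
  ft <- pinboost:::fragment_table(p, 1L)[1:2, ]
  ft$mz <- c(400.000, 400.004)
  ft$intensity <- c(1, 0.5)
  e3 <- predicted_entry(p, 2L, ft)
  s3 <- make_spectrum(400.003, 10)
  a4 <- match_peaks(s3, e3, tol = 20)
  expect_equal(a4$experimental, c(0, 10))
})

test_that("greedy matching equals brute-force optimal-order assignment on tiny cases", {
  # enumerate all pairings on <= 5 peaks: assign pairs in ascending
  # distance order, each side used once (straight transcription of the rule)
  oracle_match <- function(pred_mz, peak_mz, peak_int, tol_ppm) {
    pairs <- expand.grid(f = seq_along(pred_mz), p = seq_along(peak_mz))
    pairs$d <- abs(peak_mz[pairs$p] - pred_mz[pairs$f]) / pred_mz[pairs$f]
    pairs <- pairs[pairs$d <= tol_ppm * 1e-6, ]
    pairs <- pairs[order(pairs$d), ]
    out <- numeric(length(pred_mz))
    fu <- logical(length(pred_mz)); pu <- logical(length(peak_mz))
    for (r in seq_len(nrow(pairs))) {
      f <- pairs$f[r]; p <- pairs$p[r]
      if (!fu[f] && !pu[p]) { fu[f] <- TRUE; pu[p] <- TRUE
        out[f] <- peak_int[p] }
    }
    out
  }
  withr::with_seed(99, {
    for (i in 1:100) {
      n_pred <- sample(2:5, 1)
      n_peak <- sample(1:5, 1)
      pred_mz <- sort(runif(n_pred, 200, 210))
      peak_mz <- sort(pred_mz[sample(n_pred, n_peak, replace = TRUE)] *
                        (1 + runif(n_peak, -40e-6, 40e-6)))
      peak_int <- runif(n_peak, 1, 100)
      got <- pinboost:::match_intensities(pred_mz, peak_mz, peak_int, 20,
                                          "ppm")
      expect_equal(got, oracle_match(pred_mz, peak_mz, peak_int, 20))
    }
  })
})

test_that("entropy similarity matches the direct formula and its bounds", {
  ident <- list(predicted = c(0.2, 0.8), experimental = c(2, 8))
  expect_equal(entropy_similarity(ident), 1.0)

  disjoint <- list(predicted = c(1, 0), experimental = c(0, 1))
  expect_equal(entropy_similarity(disjoint), 0, tolerance = 1e-12)

  a <- list(predicted = c(0.8, 0.2), experimental = c(0.5, 0.5))
  expect_equal(entropy_similarity(a),
               oracle_entropy_similarity(c(0.8, 0.2), c(0.5, 0.5)),
               tolerance = 1e-12)

  expect_equal(entropy_similarity(
    list(predicted = c(1, 1), experimental = c(0, 0))), 0)
  expect_error(entropy_similarity(
    list(predicted = c(0, 0), experimental = c(1, 1))), "all-zero")
})

test_that("entropy similarity is bounded, symmetric and scale invariant", {
  withr::with_seed(400, {
    for (i in 1:500) {
      n <- sample(2:30, 1)
      p <- runif(n) * rbinom(n, 1, 0.8)
      q <- runif(n) * rbinom(n, 1, 0.8)
      if (sum(p) == 0) p[1] <- 0.5
      s <- entropy_similarity(list(predicted = p, experimental = q))
      expect_gte(s, 0); expect_lte(s, 1 + 1e-12)
      expect_equal(s, oracle_entropy_similarity(p, q), tolerance = 1e-10)
      if (sum(q) > 0) {
        expect_equal(s, entropy_similarity(list(predicted = q,
                                                experimental = p)),
                     tolerance = 1e-12)
        expect_equal(s, entropy_similarity(list(predicted = 3.7 * p,
                                                experimental = 0.01 * q)),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("grouped entropy equals per-pair evaluation", {
  withr::with_seed(41, {
    sizes <- sample(2:12, 20, replace = TRUE)
    group <- rep(seq_along(sizes), sizes)
    pred <- runif(sum(sizes)) + 0.01
    expv <- runif(sum(sizes)) * rbinom(sum(sizes), 1, 0.7)
    got <- pinboost:::entropy_similarity_grouped(pred, expv, group,
                                                 length(sizes))
    for (g in seq_along(sizes)) {
      expect_equal(got[g], oracle_entropy_similarity(pred[group == g],
                                                     expv[group == g]),
                   tolerance = 1e-12)
    }
  })
})

test_that("loess calibration reproduces a line and tracks smooth curves", {
  x <- seq(1, 100, length.out = 60)
  cal <- fit_rt_calibration(x, 2 * x + 3, span = 0.5)
  expect_equal(predict(cal, x[10:50]), 2 * x[10:50] + 3, tolerance = 1e-6)
  # clamped beyond the fitted range
  expect_equal(predict(cal, 1e6), predict(cal, max(x)))

  # noiseless monotone cubic, compared with an independent smoother
  xx <- seq(0, 1, length.out = 200)
  yy <- 10 + 30 * xx + 5 * xx^3
  cal2 <- fit_rt_calibration(xx, yy, span = 0.3)
  ref <- stats::lowess(xx, yy, f = 0.3)
  interior <- xx > 0.1 & xx < 0.9
  expect_lt(max(abs(predict(cal2, xx[interior]) -
                      approx(ref$x, ref$y, xx[interior])$y)), 0.05)

  expect_error(fit_rt_calibration(1:10, 1:10), "linear")
})

test_that("delta RT loess recovers injected deviations", {
  x <- seq(5, 50, length.out = 80)
  cal <- fit_rt_calibration(x, x * 1.5 + 2, span = 0.4)
  expect_equal(delta_rt_loess(1.5 * 20 + 2, 20, cal), 0, tolerance = 1e-6)
  expect_equal(delta_rt_loess(1.5 * 20 + 2 + 1.5, 20, cal), 1.5,
               tolerance = 1e-6)
  withr::with_seed(8, {
    dev <- runif(30, -4, 4)
    at <- runif(30, 6, 49)
    got <- delta_rt_loess(1.5 * at + 2 + dev, at, cal)
    expect_equal(got, abs(dev), tolerance = 1e-5)
  })
})

test_that("delta RT is invariant to affine predicted-scale changes after refit", {
  withr::with_seed(12, {
    pred <- sort(runif(60, 0, 100))
    expr <- 5 + 0.3 * pred + rnorm(60, 0, 0.3)
    cal_a <- fit_rt_calibration(pred, expr, span = 0.4)
    cal_b <- fit_rt_calibration(7 + 2.5 * pred, expr, span = 0.4)
    probe <- runif(20, 10, 90)
    expect_equal(delta_rt_loess(20, probe, cal_a),
                 delta_rt_loess(20, 7 + 2.5 * probe, cal_b),
                 tolerance = 1e-6)
  })
})

test_that("fragment m/z adjustment equals direct computation on the modified peptide", {
  # phospho at residue 7 of a 9-mer: y3 covers it, b3 does not
  plain <- parse_proforma("QHSQGGSVV")
  modded <- parse_proforma("QHSQGGS[U:Phospho]VV")
  ft <- pinboost:::fragment_table(plain, 1L)
  ft$intensity <- seq_len(nrow(ft)) / nrow(ft)
  e <- predicted_entry(plain, 2L, ft)
  adj <- adjust_fragment_mzs(e, data.frame(position = 7, delta = 79.966331))
  y3 <- adj$fragments$mz[adj$fragments$series == "y" &
                           adj$fragments$ordinal == 3]
  b3 <- adj$fragments$mz[adj$fragments$series == "b" &
                           adj$fragments$ordinal == 3]
  expect_equal(y3, fragment_mz(modded, "y", 3, 1), tolerance = 1e-6)
  expect_equal(b3, fragment_mz(plain, "b", 3, 1), tolerance = 1e-6)

  # empty removal list leaves the entry unchanged
  expect_equal(adjust_fragment_mzs(e, data.frame(position = integer(),
                                                 delta = numeric())),
               e)

  # doubly charged fragments shift by delta / 2
  ft2 <- pinboost:::fragment_table(plain, 2L)
  ft2$intensity <- rep(1, nrow(ft2))
  e2 <- predicted_entry(plain, 2L, ft2)
  adj2 <- adjust_fragment_mzs(e2, data.frame(position = 7, delta = 80))
  y3_2 <- which(ft2$series == "y" & ft2$ordinal == 3)
  expect_equal(adj2$fragments$mz[y3_2] - ft2$mz[y3_2], 40)
})

test_that("adjustment matches fragment_mz on random stripped peptides", {
  tab <- modification_table()
  withr::with_seed(77, {
    for (i in 1:200) {
      p <- random_peptidoform(p_charge = 0)
      n <- length(p$residues)
      free <- setdiff(0:(n + 1), p$mods$position)
      if (length(free) == 0) next
      pos <- sample(free, 1)
      k <- sample(which(!grepl("pyro", tab$name)), 1)
      modded <- peptidoform(
        paste(p$residues, collapse = ""),
        rbind(p$mods, data.frame(position = pos, name = tab$name[k],
                                 accession = tab$accession[k],
                                 delta = tab$mono_mass[k],
                                 nterm_style = FALSE)))
      ft <- pinboost:::fragment_table(p, 1L)
      ft$intensity <- rep(1, nrow(ft))
      adj <- adjust_fragment_mzs(
        predicted_entry(p, 2L, ft),
        data.frame(position = pos, delta = tab$mono_mass[k]))
      direct <- pinboost:::fragment_table(modded, 1L)
      expect_equal(adj$fragments$mz, direct$mz, tolerance = 1e-4)
    }
  })
})
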