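test_that("row normalization returns per-sample proportions", {
  m <- rbind(c(2, 3, 5), c(0, 0, 0), c(1, 1, 1))
  out <- normalizeSignatureExposures(m)
  expect_equal(out[1, ], c(0.2, 0.3, 0.5))
  expect_equal(out[2, ], c(0, 0, 0))
  expect_equal(out[3, ], rep(1 / 3, 3))
  expect_equal(normalizeSignatureExposures(rbind(rep(1, 4)))[1, ],
               rep(0.25, 4))
  expect_error(normalizeSignatureExposures(rbind(c(-1, 2))),
               "non-negative")
})

test_that("scarHRD normalization divides by the cohort maximum", {
  expect_equal(normalizeScarHRD(c(10, 25, 50)), c(0.2, 0.5, 1.0))
  expect_equal(normalizeScarHRD(c(0, 0)), c(0, 0))
  expect_equal(normalizeScarHRD(7), 1.0)
  expect_error(normalizeScarHRD(c(-1, 2)), "non-negative")
})

test_that("CN channel combination averages the CN1 complement with CN17", {
  expect_equal(combineCN(1, 0), 0)
  expect_equal(combineCN(0, 1), 1)
  expect_equal(combineCN(0.4, 0.6), 0.6)
  expect_error(combineCN(1.2, 0), "normalized")
})

test_that("tumor weights count supra-epsilon fractions inclusively", {
  ch <- cbind(A = c(0.05, 0.2, 0.3, 0.0), B = c(0.1, 0.1, 0, 0))
  w <- computeWeights(ch, factor(rep("T1", 4)), 0.1)
  expect_equal(unname(w["T1", "A"]), 0.5)
  expect_equal(unname(w["T1", "B"]), 0.5)
  w2 <- computeWeights(cbind(A = c(0.1, 0.1)), factor(c("T1", "T1")), 0.1)
  expect_equal(unname(w2["T1", "A"]), 1.0)
  w3 <- computeWeights(cbind(A = c(0, 0)), factor(c("T1", "T1")), 0.1)
  expect_equal(unname(w3["T1", "A"]), 0)
  expect_error(computeWeights(ch, factor(rep("T1", 4),
                                         levels = c("T1", "T2")), 0.1),
               "zero samples")
})

test_that("weight rescaling normalizes rows with a uniform fallback", {
  expect_equal(unname(rescaleWeights(rbind(c(0.2, 0.2, 0.4, 0.2)))[1, ]),
               c(0.2, 0.2, 0.4, 0.2))
  expect_equal(unname(rescaleWeights(rbind(c(1, 1, 1, 1)))[1, ]),
               rep(0.25, 4))
  expect_warning(out <- rescaleWeights(rbind(T9 = c(0, 0, 0, 0))),
                 "uniform")
  expect_equal(unname(out[1, ]), rep(0.25, 4))
})

test_that("full scoring chain equals the loop transcription oracle", {
  es <- randomExposureSet(n = 200, nTypes = 3, seed = 123)
  got <- hrdScores(panhrdScores(es))
  expect_lt(max(abs(got - oracleScores(es))), 1e-12)
})

test_that("scores are weighted means of the selected channels", {
  # with uniform weights and all channels at 1 the score is exactly 1
  es <- randomExposureSet(n = 50, seed = 4)
  res <- panhrdScores(es)
  ch <- res@normalizedExposures
  w <- scoreWeights(res)[as.character(tumorLabels(es)), ]
  expect_equal(unname(hrdScores(res)), unname(rowSums(ch * w)))
  expect_true(all(abs(rowSums(scoreWeights(res)) - 1) < 1e-9))
  expect_true(all(hrdScores(res) >= 0 & hrdScores(res) <= 1))
})

test_that("class-wise positive rescaling leaves scores unchanged", {
  es <- randomExposureSet(n = 150, seed = 8)
  base <- hrdScores(panhrdScores(es))
  for (k in c("SBS", "ID", "CN", "scarHRD")) {
    es2 <- es
    es2@exposures[[k]] <- es2@exposures[[k]] * 7.3
    expect_equal(hrdScores(panhrdScores(es2)), base, tolerance = 1e-12)
  }
})

test_that("raising CN17 never lowers the score; raising CN1 never raises it", {
  es <- randomExposureSet(n = 100, seed = 15)
  res <- panhrdScores(es)
  ch <- res@normalizedExposures
  w <- scoreWeights(res)[as.character(tumorLabels(es)), ]
  s0 <- rowSums(ch * w)
  up <- ch; up[, "CN"] <- pmin(up[, "CN"] + 0.1, 1)
  dn <- ch; dn[, "CN"] <- pmax(dn[, "CN"] - 0.1, 0)
  expect_true(all(rowSums(up * w) >= s0 - 1e-12))
  expect_true(all(rowSums(dn * w) <= s0 + 1e-12))
})

test_that("median discretization labels the strict upper half positive", {
  d <- discretizeByMedian(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(d$labels, c(0L, 0L, 1L, 1L))
  expect_equal(d$cutoff, 0.25)
  expect_equal(discretizeByMedian(c(0.3, 0.3, 0.3))$labels, c(0L, 0L, 0L))
  expect_equal(discretizeByMedian(0.9)$labels, 0L)
  expect_error(discretizeByMedian(numeric()), "empty")
  ext <- discretizeByMedian(c(0.1, 0.9), cutoff = 0.305)
  expect_equal(ext$labels, c(0L, 1L))
})

test_that("a missing selected biomarker is a configuration error", {
  es <- randomExposureSet(n = 20, seed = 2)
  cfg <- scoreConfig(selected = list(SBS = "SBS99", ID = "ID6",
                                     CN = c("CN1", "CN17"),
                                     scarHRD = "scarHRD"))
  expect_error(panhrdScores(es, cfg), "absent")
  expect_error(scoreConfig(epsilon = 1.5), "epsilon")
})
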