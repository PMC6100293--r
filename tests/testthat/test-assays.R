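test_that("DPPH scavenging follows (Ac - As)/Ac and flags pro-oxidants", {
  expect_equal(as.numeric(dpph_scavenging(0.5, 0.5)), 0)
  expect_equal(as.numeric(dpph_scavenging(0, 0.8)), 100)
  # absorbance pair on the scale of strong tripeptide scavengers
  expect_equal(as.numeric(dpph_scavenging(0.295, 0.800)), 63.125)
  neg <- dpph_scavenging(0.9, 0.8)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "pro_oxidant"))
  expect_error(dpph_scavenging(0.5, 0), "positive")
})

test_that("standard curves recover exact lines and reject bad inputs", {
  conc <- seq(150, 1500, length.out = 6)
  resp <- 0.001 * conc + 0.05
  cv <- fit_standard_curve(conc, resp, analyte = "trolox")
  expect_equal(cv$slope, 0.001, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1)
  expect_identical(cv$range, c(150, 1500))
  expect_error(fit_standard_curve(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_standard_curve(c(1, 2, 2), c(1, 2, 3)), "duplicate")
  # a scrambled, non-linear response fails the r-squared floor
  expect_error(fit_standard_curve(1:5, c(1, 5, 2, 4, 3)), "below floor")
})

test_that("noisy standard-curve slopes fall within 3 standard errors of truth", {
  set.seed(12)
  conc <- seq(200, 1200, length.out = 8)
  resp <- 0.05 + 0.001 * conc + rnorm(8, 0, 0.01)
  cv <- fit_standard_curve(conc, resp, analyte = "FeSO4", r2_floor = 0.9)
  # independent OLS standard error of the slope
  fit <- lm(resp ~ conc)
  se <- summary(fit)$coefficients["conc", "Std. Error"]
  expect_lt(abs(cv$slope - 0.001), 3 * se)
})

test_that("peptide molar masses come from the bundled residue-mass table", {
  # 3 glycyl residues (57.0519 each) plus one water (18.01528)
  expect_equal(peptide_molar_mass("GGG"), 3 * 57.0519 + 18.01528)
  expect_equal(peptide_molar_mass("GGG"), 189.17, tolerance = 1e-4 * 189.17)
  expect_equal(peptide_molar_mass("AG"), peptide_molar_mass("GA"))
  expect_error(peptide_molar_mass(""), "empty")
  expect_error(peptide_molar_mass("AXB"), "nonstandard")
  # 0.1 mg/mL of GGG in micromolar
  expect_equal(peptide_micromolar(0.1, "GGG"),
               0.1 / (3 * 57.0519 + 18.01528) * 1e6)
})

test_that("TEAC and FRAP read-offs invert the standard curve", {
  trolox <- synthetic_standard_curve("trolox")
  feso4 <- synthetic_standard_curve("FeSO4")
  # response at the zero-concentration point of the line maps to value 0
  expect_equal(as.numeric(teac_value(trolox$intercept, trolox, 0.1, "GKW")), 0)
  expect_equal(as.numeric(frap_value(feso4$intercept, feso4, 0.1, "GKW")), 0)
  # doubling the peptide molar concentration halves the value
  r <- trolox$intercept + trolox$slope * 500
  v1 <- as.numeric(teac_value(r, trolox, 0.1, "GKW"))
  v2 <- as.numeric(teac_value(r, trolox, 0.2, "GKW"))
  expect_equal(v2, v1 / 2, tolerance = 1e-12)
  # FRAP monotone in absorbance for a positive slope
  lo <- as.numeric(frap_value(0.3, feso4, 0.1, "GKW"))
  hi <- as.numeric(frap_value(0.6, feso4, 0.1, "GKW"))
  expect_gt(hi, lo)
  # analyte mismatch and degenerate slope are errors
  expect_error(teac_value(0.5, feso4, 0.1, "GKW"), "trolox")
  expect_error(frap_value(0.5, trolox, 0.1, "GKW"), "FeSO4")
  flat <- trolox; flat$slope <- 0
  expect_error(teac_value(0.5, flat, 0.1, "GKW"), "slope")
})

test_that("values scale inversely with the assumed molar mass", {
  trolox <- synthetic_standard_curve("trolox")
  r <- trolox$intercept + trolox$slope * 400
  v_small <- as.numeric(teac_value(r, trolox, 0.1, "GGG"))
  v_large <- as.numeric(teac_value(r, trolox, 0.1, "WWW"))
  expect_equal(v_large / v_small,
               peptide_molar_mass("WWW") / peptide_molar_mass("GGG"),
               tolerance = 1e-12)
})

test_that("replicate aggregation reports mean, SD and n per peptide", {
  vals <- c(1, 1.1, 0.9, 2, 2.2, 1.8)
  grp <- rep(c("AAA", "CCC"), each = 3)
  agg <- aggregate_replicates(vals, grp)
  expect_identical(agg$n, c(3L, 3L))
  expect_equal(agg$mean, c(1, 2))
  expect_equal(agg$sd, c(0.1, 0.2), tolerance = 1e-12)
  expect_true(all(agg$sd >= 0))
})

test_that("zero-noise synthetic plates round-trip through plate analysis exactly", {
  seqs <- c("GKW", "YHW", "GHG", "PYW")
  truth <- c(1.2, 2.0, 0.3, 1.7)
  for (type in c("teac", "frap")) {
    curve <- synthetic_standard_curve(if (type == "teac") "trolox" else "FeSO4")
    plate <- generate_assay_plate(seqs, truth, curve,
                                  noise_sd_absorbance = 0, seed = 1)
    out <- analyze_plate(plate, type = type)
    expect_identical(out$n, rep(3L, 4))
    got <- out$value[match(seqs, out$sequence)]
    expect_equal(got, truth, tolerance = 1e-10)
    expect_equal(out$sd, rep(0, 4), tolerance = 1e-10)
  }
})

test_that("noisy plates recover true values within a few percent", {
  # samples at 0.2 mg/mL read mid-curve, where 0.005 AU noise on a
  # 4e-4 AU/uM slope permits 5% relative precision
  set.seed(77)
  seqs <- sample(enumerate_candidates(), 20)
  truth <- runif(20, 1.0, 2.0)
  curve <- synthetic_standard_curve("trolox")
  rel_err <- c()
  for (s in 1:20) {
    plate <- generate_assay_plate(seqs, truth, curve,
                                  noise_sd_absorbance = 0.005,
                                  conc_mass = 0.2, seed = s)
    out <- analyze_plate(plate, type = "teac", r2_floor = 0.95)
    got <- out$value[match(seqs, out$sequence)]
    rel_err <- c(rel_err, abs(got - truth) / truth)
  }
  expect_gte(mean(rel_err <= 0.05), 0.95)
})
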