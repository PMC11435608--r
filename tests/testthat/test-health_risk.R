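adult <- list(group = "adult", IR = 2, EF = 365, ED = 30, BW = 70,
              LE = 70)

test_that("chronic daily intake follows the ingestion equation at both
          horizons", {
  # EF = 365 and the non-carcinogenic AT = ED*365 cancel ED entirely
  expect_equal(cdi(10, adult, "noncarcinogenic"), 0.01 * 2 / 70,
               tolerance = 1e-12)
  # carcinogenic horizon averages over the life expectancy instead
  expect_equal(cdi(10, adult, "carcinogenic"),
               (0.01 * 2 * 365 * 30) / (70 * 70 * 365),
               tolerance = 1e-12)
  expect_equal(cdi(0, adult), 0)
  expect_equal(cdi(20, adult), 2 * cdi(10, adult))       # linearity
  # partial-year exposure scales CDI by EF/365
  half <- adult; half$EF <- 182.5
  expect_equal(cdi(10, half), cdi(10, adult) / 2)
  bad <- adult; bad$BW <- 0
  expect_error(cdi(10, bad), "positive")
})

test_that("HQ, HI, CR, CCR satisfy their defining identities on random
          inputs", {
  expect_equal(hazard_quotient(0.0003, 0.0003), 1)
  expect_equal(hazard_index(c(0.2, 0.3, 0.5)), 1.0)
  expect_warning(hi0 <- hazard_index(numeric(0)), "empty")
  expect_equal(hi0, 0)
  expect_equal(cancer_risk(1e-5, 1.5), 1.5e-5)
  expect_equal(cancer_risk(0, 1.5), 0)
  expect_equal(cumulative_cancer_risk(2e-6), 2e-6)

  set.seed(14)
  for (rep in 1:25) {
    k <- sample(2:12, 1)
    cdi_v <- rexp(k, 1e3)
    rfd <- rexp(k, 10)
    sf <- rexp(k, 1)
    hq <- hazard_quotient(cdi_v, rfd)
    expect_equal(hq, cdi_v / rfd)
    hi <- hazard_index(hq)
    expect_equal(hi, sum(cdi_v / rfd))
    # removing one analyte removes exactly its HQ
    drop <- sample(k, 1)
    expect_equal(hazard_index(hq[-drop]), hi - hq[drop])
    cr <- cancer_risk(cdi_v, sf)
    expect_equal(cumulative_cancer_risk(cr), sum(cdi_v * sf))
    # degree-1 homogeneity in concentration
    a <- runif(1, 0.1, 10)
    expect_equal(hazard_index(hazard_quotient(a * cdi_v, rfd)), a * hi)
  }
  expect_error(hazard_quotient(1e-4, 0), "positive")
  expect_error(cancer_risk(1e-4, -1), "positive")
})

test_that("risk levels reproduce the I/II and I-V taxonomies at every
          breakpoint", {
  expect_identical(classify_hi(c(0, 0.5, 1, 1 + 1e-12, 7)),
                   c("I", "I", "I", "II", "II"))
  expect_identical(classify_cr(5e-5), "III")
  # half-open lower edges: an exact breakpoint belongs to the band above
  expect_identical(
    classify_cr(c(0, 9.9e-7, 1e-6, 9.9e-6, 1e-5, 9.9e-5,
                  1e-4, 9.9e-4, 1e-3, 2e-3)),
    c("I", "I", "II", "II", "III", "III", "IV", "IV", "V", "V"))
  # monotone non-decreasing in CR
  lv <- classify_cr(sort(10^runif(100, -8, -2)))
  expect_true(all(diff(match(lv, c("I", "II", "III", "IV", "V"))) >= 0))
  expect_error(classify_hi(-0.1), "non-negative")
  expect_error(classify_cr(-1e-9), "non-negative")
})

test_that("the assessment table is internally consistent and children
          carry the largest non-carcinogenic risk", {
  fx <- make_worked_fixtures()
  risk <- assess_risk(fx$table)
  s <- risk$summary
  d <- risk$detail
  # HI is exactly the sum of the per-analyte HQs
  hi_re <- tapply(d$hq, list(d$sample, d$group), sum)
  for (g in unique(s$group)) {
    sg <- s[s$group == g, ]
    expect_equal(sg$hi, unname(hi_re[sg$sample, g]))
  }
  # CCR is the sum of CR over carcinogens (here As only)
  cr_re <- tapply(d$cr, list(d$sample, d$group), sum, na.rm = TRUE)
  for (g in unique(s$group)) {
    sg <- s[s$group == g, ]
    expect_equal(sg$ccr, unname(cr_re[sg$sample, g]))
  }
  expect_true(all(s$hi >= 0) && all(s$ccr >= 0))
  expect_identical(s$hi_level, classify_hi(s$hi))
  expect_identical(s$cr_level, classify_cr(s$ccr))
  # children's HQ dominates both adult groups cell-by-cell
  hq_c <- d$hq[d$group == "children"]
  expect_true(all(hq_c >= d$hq[d$group == "men"]))
  expect_true(all(hq_c >= d$hq[d$group == "women"]))
})

test_that("all-zero concentrations give zero risk at level I", {
  cfg <- analyte_config(c("As", "Cd"), mdl = c(1e-4, 1e-4),
                        error_fraction = c(0.1, 0.1))
  X <- matrix(0, 4, 2, dimnames = list(NULL, c("As", "Cd")))
  risk <- assess_risk(conc_table(X, cfg))
  expect_true(all(risk$summary$hi == 0))
  expect_true(all(risk$summary$cr_level == "I"))
  expect_true(all(risk$fractions$hi_below_1_percent == 100))
})

test_that("HI sensitivity ranks dominant analytes first and shares sum
          to one", {
  cfg <- analyte_config(c("As", "Cd", "Se"), mdl = rep(1e-4, 3),
                        error_fraction = rep(0.1, 3))
  set.seed(31)
  base <- rexp(10, 1)
  # As contributes 10x Cd's HQ everywhere; Se's HQ column is exactly
  # Cd's (identical concentrations and RfD), forcing a tie
  X <- cbind(As = base * 10 * 0.0005, Cd = base * 0.0005,
             Se = base * 0.0005)
  tox <- toxicity_table(rfd = c(As = 0.0005, Cd = 0.0005, Se = 0.0005),
                        sf = c(As = 1.5))
  risk <- assess_risk(conc_table(X, cfg), tox = tox)
  sens <- hi_sensitivity(risk, "children")
  expect_identical(sens$analyte[1], "As")
  expect_equal(sum(sens$score), 1)
  # identical HQ columns tie and break lexicographically
  expect_identical(sens$analyte[2:3], c("Cd", "Se"))
  expect_equal(sens$score[2], sens$score[3])

  spear <- hi_sensitivity(risk, "children", method = "spearman")
  expect_identical(spear$analyte[1], "As")  # perfectly rank-correlated
  expect_equal(attr(spear, "method"), "spearman")
})
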