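# Method 1 (proximity to aspirational values) and Method 2 (KPI score
# matrix) resistance-to-damage scoring.

test_that("hole-enlargement score table reproduces all 12 published cells", {
  # rows: damage type; columns: end-size band (<=5, 6-20, >=21 mm)
  expected <- rbind(
    none = c(100, 80, 40),
    laddering = c(80, 64, 32),
    unravelling = c(50, 40, 20),
    tearing_combined = c(40, 32, 16)
  )
  ends <- c(3, 10, 25)
  for (dmg in rownames(expected)) {
    expect_equal(hole_enlargement_score_m1(ends, dmg),
                 unname(expected[dmg, ]),
                 info = dmg)
  }
  # band edges: 5 mm is still the top band, 20 mm still the middle one
  expect_equal(hole_enlargement_score_m1(c(5, 5.01, 20, 20.5), "none"),
               c(100, 80, 80, 40))
})

test_that("secondary-damage labels are case-insensitive and tearing variants collapse", {
  expect_equal(hole_enlargement_score_m1(3, "Laddering"), 80)
  expect_equal(hole_enlargement_score_m1(3, "tearing+laddering"), 40)
  expect_equal(hole_enlargement_score_m1(3, "tearing+unravelling"), 40)
  expect_equal(hole_enlargement_score_m1(3, "Tearing combined with laddering"),
               40)
  expect_error(hole_enlargement_score_m1(3, "melting"), "unknown")
})

test_that("Method 1 equals the weighted proximity sum and is not clamped", {
  at_target <- lab_record(bursting_kpa = 700, snag_n = 200,
                          abrasion_rubs = 400, end_hole_mm = 3,
                          secondary_damage = "none")
  expect_equal(rd_method1(at_target)$total, 100)

  halves <- lab_record(bursting_kpa = 350, snag_n = 100, abrasion_rubs = 200,
                       end_hole_mm = 3, secondary_damage = "unravelling")
  expect_equal(rd_method1(halves)$total, 50)  # every term at half target

  over <- lab_record(bursting_kpa = 1400, snag_n = 200, abrasion_rubs = 400,
                     end_hole_mm = 3, secondary_damage = "none")
  expect_equal(rd_method1(over)$total, 125)   # bursting term doubles, no cap
})

test_that("Method 1 result components are consistent and linear in each value", {
  r <- rd_method1(lab_record(bursting_kpa = 420, snag_n = 120,
                             abrasion_rubs = 333, end_hole_mm = 12,
                             secondary_damage = "laddering"))
  expect_equal(r$total, sum(r$contributions), tolerance = 1e-12)
  expect_true(all(r$contributions >= 0))
  expect_equal(r$contributions[["hole_enlargement"]], 64 / 4)

  # doubling the snag value adds exactly its contribution again
  base <- lab_record(snag_n = 80)
  doubled <- lab_record(snag_n = 160)
  delta <- rd_method1(doubled)$total - rd_method1(base)$total
  expect_equal(delta, 80 / 200 * 25, tolerance = 1e-12)

  expect_error(rd_method1(lab_record(), aspirational = list(
    bursting_kpa = -1, snag_n = 200, abrasion_rubs = 400,
    hole_score_max = 100)), "positive")
})

test_that("bin_score returns the highest tier at or below the value", {
  cases <- list(
    list(250, "bursting", 2.5), list(249.9, "bursting", 1),
    list(299, "bursting", 2.5), list(300, "bursting", 5),
    list(699.9, "bursting", 22.5), list(700, "bursting", 25),
    list(59, "snag", 5), list(19, "snag", 1), list(200, "snag", 25),
    list(410, "abrasion", 25), list(24, "abrasion", 1),
    list(60, "abrasion", 3),   # value in a printed gap takes the tier below
    list(249, "abrasion", 13), list(250, "abrasion", 16)
  )
  for (cs in cases) {
    expect_equal(bin_score(cs[[1]], cs[[2]]), cs[[3]],
                 info = paste(cs[[1]], cs[[2]]))
  }
  expect_error(bin_score(100, "weight"))
  expect_error(bin_score(-1, "snag"), "non-negative")
})

test_that("default score matrix has the published tier structure", {
  m <- default_score_matrix()
  expect_equal(nrow(m$bursting), 11)
  expect_equal(nrow(m$snag), 11)
  expect_equal(nrow(m$abrasion), 9)
  expect_equal(m$bursting$score, c(1, seq(2.5, 25, by = 2.5)))
  expect_equal(m$abrasion$score, c(1, 3, 6, 9, 13, 16, 19, 22, 25))
  expect_true(all(diff(m$bursting$lower) > 0))
  expect_error(score_matrix(
    bursting = data.frame(lower = c(0, 300, 250), score = c(1, 2, 3)),
    snag = m$snag, abrasion = m$abrasion), "strictly increasing")
})

test_that("penalty score applies the published formula", {
  p <- penalty_score(3, "laddering")
  expect_equal(p$sigma_h, 25)
  expect_equal(p$rho_h, 2.5)        # 10 * 25 / 100
  p <- penalty_score(3, "none")
  expect_equal(p$rho_h, 0)
  p <- penalty_score(25, "tearing_combined")
  expect_equal(p$sigma_h, 10)
  expect_equal(p$rho_h, 3)          # 30 * 10 / 100
})

test_that("Method 2 totals the four tier scores net of the penalty", {
  top <- lab_record(bursting_kpa = 700, snag_n = 200, abrasion_rubs = 400,
                    end_hole_mm = 3, secondary_damage = "none")
  expect_equal(rd_method2(top)$total, 100)

  mixed <- lab_record(bursting_kpa = 250, snag_n = 59, abrasion_rubs = 410,
                      end_hole_mm = 3, secondary_damage = "laddering")
  expect_equal(rd_method2(mixed)$total, 55)  # 2.5 + 5 + 25 + (25 - 2.5)

  worst <- lab_record(bursting_kpa = 100, snag_n = 10, abrasion_rubs = 10,
                      end_hole_mm = 25, secondary_damage = "tearing_combined")
  expect_equal(rd_method2(worst)$total, 10)  # 1 + 1 + 1 + (10 - 3)
})

test_that("both methods are monotone in every parameter", {
  set.seed(401)
  for (i in 1:40) {
    rec <- lab_record(
      bursting_kpa = runif(1, 50, 900), snag_n = runif(1, 5, 250),
      abrasion_rubs = round(runif(1, 5, 450)),
      end_hole_mm = runif(1, 0.5, 40),
      secondary_damage = sample(c("none", "laddering", "unravelling",
                                  "tearing_combined"), 1)
    )
    for (fun in list(rd_method1, rd_method2)) {
      base <- fun(rec)$total
      for (f in c("bursting_kpa", "snag_n", "abrasion_rubs")) {
        up <- rec
        up[[f]] <- up[[f]] * 1.5
        expect_gte(fun(up)$total, base)
      }
      bigger_hole <- rec
      bigger_hole$end_hole_mm <- rec$end_hole_mm + 20
      expect_lte(fun(bigger_hole)$total, base)
      if (rec$secondary_damage == "none") {
        worse <- rec
        worse$secondary_damage <- "tearing_combined"
        expect_lte(fun(worse)$total, base)
      }
    }
  }
})

test_that("Method 2 totals stay within [10, 100] over random valid inputs", {
  set.seed(402)
  for (i in 1:100) {
    rec <- lab_record(
      bursting_kpa = runif(1, 1, 2000), snag_n = runif(1, 1, 500),
      abrasion_rubs = round(runif(1, 0, 1000)),
      end_hole_mm = runif(1, 0, 60),
      secondary_damage = sample(c("none", "laddering", "unravelling",
                                  "tearing_combined"), 1)
    )
    rec$abrasion_rubs <- max(rec$abrasion_rubs, 1)
    tot <- rd_method2(rec)$total
    expect_gte(tot, 10)
    expect_lte(tot, 100)
  }
})

test_that("score_panel preserves order, tags methods, and is deterministic", {
  panel <- lab_panel_df(lab_record("n1"), lab_record("n2", snag_n = 150))
  rep1 <- score_panel(panel, "method1")
  expect_equal(rep1$net_id, c("n1", "n2"))
  expect_equal(unique(rep1$method), "method1")
  expect_identical(rep1, score_panel(panel, "method1"))

  both <- score_panel(panel, "both")
  expect_equal(nrow(both), 4)
  expect_equal(both$total, both$bursting + both$snag + both$abrasion +
                 both$hole_enlargement, tolerance = 1e-12)
  expect_error(score_panel(panel[0, ], "method1"), "non-empty")

  synth <- generate_lab_panel(synthetic_config(n_nets = 16, seed = 3))
  totals <- score_panel(synth, "method2")$total
  expect_length(totals, 16)
  expect_true(all(is.finite(totals)))
})
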