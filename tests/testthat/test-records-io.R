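# Validated readers and deterministic report writers.

test_that("lab CSV reader round-trips a stated row and an empty file", {
  path <- write_lab_csv("netA,BA,350,100,200,10,laddering")
  recs <- read_lab_records(path, "csv")
  expect_equal(nrow(recs), 1)
  expect_equal(recs$bursting_kpa, 350)
  expect_equal(recs$snag_n, 100)
  expect_equal(recs$abrasion_rubs, 200)
  expect_equal(recs$end_hole_mm, 10)
  expect_equal(recs$secondary_damage, "laddering")

  empty <- write_lab_csv(character())
  expect_equal(nrow(read_lab_records(empty, "csv")), 0)
})

test_that("lab reader rejects schema violations with row and field context", {
  bad_num <- write_lab_csv("netA,BA,350,abc,200,10,none")
  expect_error(read_lab_records(bad_num, "csv"), "row 1.*snag_n")

  bad_label <- write_lab_csv(c("netA,BA,350,100,200,10,none",
                               "netB,BB,350,100,200,10,melted"))
  expect_error(read_lab_records(bad_label, "csv"), "row 2.*secondary_damage")

  nonpos <- write_lab_csv("netA,BA,0,100,200,10,none")
  expect_error(read_lab_records(nonpos, "csv"), "bursting_kpa")

  frac_rubs <- write_lab_csv("netA,BA,350,100,200.5,10,none")
  expect_error(read_lab_records(frac_rubs, "csv"), "abrasion_rubs.*integer")

  missing_col <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,bursting_kpa,snag_n,abrasion_rubs,end_hole_mm",
               "netA,BA,350,100,200,10"), missing_col)
  expect_error(read_lab_records(missing_col, "csv"), "secondary_damage")

  expect_error(read_lab_records(tempfile(), "csv"), "not found")
})

test_that("lab reader normalises damage labels and reads JSON", {
  path <- write_lab_csv(c("netA,BA,350,100,200,10,Tearing+Laddering",
                          "netB,BB,350,100,200,10,UNRAVELLING"))
  recs <- read_lab_records(path, "csv")
  expect_equal(recs$secondary_damage, c("tearing_combined", "unravelling"))

  jpath <- tempfile(fileext = ".json")
  jsonlite::write_json(
    data.frame(net_id = "netA", brand = "BA", bursting_kpa = 350,
               snag_n = 100, abrasion_rubs = 200, end_hole_mm = 10,
               secondary_damage = "laddering"),
    jpath, dataframe = "rows")
  expect_equal(read_lab_records(jpath, "json")$bursting_kpa, 350)
})

test_that("field reader accepts one hole encoding and rejects mixtures", {
  census <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,months_in_use,N1,N2,N3,N4",
               "a,X,24,2,1,0,0"), census)
  recs <- read_field_records(census, "csv")
  expect_equal(unname(unlist(recs[1, c("N1", "N2", "N3", "N4")])),
               c(2L, 1L, 0L, 0L))

  diam <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,months_in_use,hole_diameters_cm",
               "a,X,24,1.25;10"), diam)
  recs <- read_field_records(diam, "csv")
  expect_equal(recs$hole_diameters_cm[[1]], c(1.25, 10))

  both <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,months_in_use,N1,N2,N3,N4,hole_diameters_cm",
               "a,X,24,2,1,0,0,1.25"), both)
  expect_error(read_field_records(both, "csv"), "both")

  neg <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,months_in_use,N1,N2,N3,N4",
               "a,X,24,2,1,-1,0"), neg)
  expect_error(read_field_records(neg, "csv"), "N3")

  below <- tempfile(fileext = ".csv")
  writeLines(c("net_id,brand,months_in_use,hole_diameters_cm",
               "a,X,24,0.3;1.25"), below)
  expect_error(read_field_records(below, "csv"), "threshold")
})

test_that("reports are deterministic with fixed rounding", {
  # n1 sits at half of every aspirational target: Method 1 total exactly 50
  panel <- lab_panel_df(lab_record("n1", secondary_damage = "unravelling"),
                        lab_record("n2", snag_n = 157))
  report <- score_panel(panel, "both")
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_report(report, p1, "csv")
  write_report(report, p2, "csv")
  expect_identical(readLines(p1), readLines(p2))
  # RD written to one decimal place
  expect_true(any(grepl("50\\.0", readLines(p1))))

  phis <- phi_summary(data.frame(net_id = c("a", "b"), brand = c("X", "X"),
                                 months_in_use = c(12, 12),
                                 N1 = c(0, 1), N2 = c(0, 0),
                                 N3 = c(0, 0), N4 = c(0, 0)), "brand")
  pj <- tempfile(fileext = ".json")
  write_report(phis, pj, "json")
  parsed <- jsonlite::fromJSON(pj)
  expect_equal(parsed$mean_hole_index, 0)  # 0.5 rounds to nearest integer

  expect_error(write_report(report[0, ], tempfile(), "csv"), "non-empty")
  expect_error(write_report(report, file.path(tempfile(), "x", "y.csv")),
               "directory")
})

test_that("write-then-read round-trips record collections exactly", {
  panel <- generate_lab_panel(synthetic_config(n_nets = 8, seed = 9))
  p <- tempfile(fileext = ".csv")
  write_report(panel, p, "csv")
  back <- read_lab_records(p, "csv")
  for (col in names(panel)) {
    expect_equal(back[[col]], panel[[col]], info = col)
  }

  field <- generate_field_phi(panel, synthetic_config(n_nets = 8, seed = 9))
  f <- tempfile(fileext = ".csv")
  write_report(field, f, "csv")
  backf <- read_field_records(f, "csv")
  expect_equal(backf$N4, field$N4)
  expect_equal(hole_index(backf), hole_index(field))
})
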