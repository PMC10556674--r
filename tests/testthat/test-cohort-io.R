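test_that("participants reader parses rows, preserves order, enforces schema", {
  path <- participants_csv(c(
    "P01,female,28.5,163,57.8,57.6,FALSE,2-6 h/wk",
    "P02,female,31,170,62.1,62.4,TRUE,none"
  ))
  df <- read_participants(path)
  expect_equal(nrow(df), 2L)
  expect_equal(df$id, c("P01", "P02"))
  expect_equal(df$weight_start_kg[1], 57.8)
  expect_equal(df$height_cm[1], 163)
  expect_equal(df$age_y[1], 28.5)
  expect_false(df$smoker[1])

  # header-only file: empty table, not an error
  empty <- participants_csv(character(0))
  expect_equal(nrow(read_participants(empty)), 0L)

  # non-numeric weight: parse error naming row
  bad <- participants_csv("P01,female,28.5,163,abc,57.6,FALSE,none")
  expect_error(read_participants(bad), "row 1")

  # missing column named in error
  nocol <- write_fixture_csv(c("id,sex,age_y", "P01,female,28"))
  expect_error(read_participants(nocol), "height_cm")

  # non-positive anthropometrics rejected
  neg <- participants_csv("P01,female,-2,163,57.8,57.6,FALSE,none")
  expect_error(read_participants(neg), "age_y")
})

test_that("occasion reader validates labels and pairs before/after images", {
  path <- occasions_csv(c(
    occ_row(label = "before", energy = 500, ts = "2024-03-01T08:00:00"),
    occ_row(label = "after", energy = 100, ts = "2024-03-01T08:30:00"),
    occ_row(label = "ate_everything", energy = 400,
            ts = "2024-03-01T12:00:00")
  ))
  df <- read_occasions(path)
  expect_equal(df$occasion_id, c(1L, 1L, 2L))
  expect_false(any(df$unmatched))

  # unknown label rejected
  bad <- occasions_csv(occ_row(label = "brunch"))
  expect_error(read_occasions(bad), "brunch")

  # orphan 'after' kept with a warning and flagged
  orphan <- occasions_csv(occ_row(label = "after", energy = 50))
  expect_warning(df2 <- read_occasions(orphan), "unmatched")
  expect_equal(nrow(df2), 1L)
  expect_true(df2$unmatched)

  # negative energy rejected
  neg <- occasions_csv(occ_row(energy = -10))
  expect_error(read_occasions(neg), "energy_kcal")
})

test_that("csv round-trip preserves doubles bit-exactly", {
  df <- tibble::tibble(
    id = c("a", "b"),
    x = c(1 / 3, sqrt(2)),
    y = c(57.8, 0.1 + 0.2)
  )
  path <- tempfile(fileext = ".csv")
  write_table_csv(df, path)
  back <- utils::read.csv(path)
  expect_identical(back$x, df$x)
  expect_identical(back$y, df$y)
})

test_that("report serialization round-trips and is deterministic", {
  report <- list(a = list(bias = -329.6, loa = c(lower = -1503.8,
                                                 upper = 844.5)),
                 n = 30L)
  p1 <- tempfile(fileext = ".json")
  p2 <- tempfile(fileext = ".json")
  write_report(report, p1, markdown = FALSE)
  write_report(report, p2, markdown = FALSE)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_report(p1)
  expect_equal(back$a$bias, -329.6)
  expect_equal(back$a$loa$lower, -1503.8)

  # NaN serialized as null with warning
  expect_warning(write_report(list(x = NaN), p1, markdown = FALSE),
                 "non-finite")
  expect_null(read_report(p1)$x)
})

test_that("isotope and recall readers enforce their schemas", {
  iso <- write_fixture_csv(c(
    paste0("participant_id,dose_o18_g,dose_d2_g,ape_o18,ape_d2,",
           "E_pre_o18,E_post_o18,E_final_o18,E_pre_d2,E_post_d2,",
           "E_final_d2,t_post_h,t_final_h"),
    "P01,46.8,3.1,10,99.9,0,177,80,0,1154,600,3.5,171.5"
  ))
  df <- read_isotopes(iso)
  expect_equal(df$dose_o18_g, 46.8)

  bad_t <- write_fixture_csv(c(
    paste0("participant_id,dose_o18_g,dose_d2_g,ape_o18,ape_d2,",
           "E_pre_o18,E_post_o18,E_final_o18,E_pre_d2,E_post_d2,",
           "E_final_d2,t_post_h,t_final_h"),
    "P01,46.8,3.1,10,99.9,0,177,80,0,1154,600,171.5,3.5"
  ))
  expect_error(read_isotopes(bad_t), "t_final_h")

  rec <- write_fixture_csv(c(
    "participant_id,tdei_kcal,carb_g,sugar_g,fat_g,satfat_g,protein_g,fiber_g,occasions_n",
    "P01,1692.1,179.3,63.7,73.3,27.5,70.0,20.9,5"
  ))
  df2 <- read_recall24(rec)
  expect_equal(df2$tdei_kcal, 1692.1)
  dup <- write_fixture_csv(c(
    "participant_id,tdei_kcal,carb_g,sugar_g,fat_g,satfat_g,protein_g,fiber_g,occasions_n",
    "P01,1692.1,0,0,0,0,0,0,5",
    "P01,1500,0,0,0,0,0,0,4"
  ))
  expect_error(read_recall24(dup), "one record")
})

test_that("yaml study config loads with nested blocks and defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "rq: 0.9",
    "bonferroni_factor: 3",
    "goldberg:",
    "  d_days: 6",
    "  cv_wtdei: 42.55",
    "dlw:",
    "  dsr_high: 1.7"
  ), path)
  cfg <- read_study_config(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$dlw$rq, 0.9)
  expect_equal(cfg$dlw$dsr_high, 1.7)
  expect_equal(cfg$goldberg$cv_wtdei, 42.55)
  expect_equal(cfg$kcal_to_kj, 4.184)
})
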