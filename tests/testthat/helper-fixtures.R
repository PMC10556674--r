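# Builders for small in-memory fixtures used across the suite.

write_fixture_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

participants_csv <- function(rows = c("P01,female,28.5,163,57.8,57.6,FALSE,2-6 h/wk")) {
  write_fixture_csv(c(
    "id,sex,age_y,height_cm,weight_start_kg,weight_end_kg,smoker,activity_band",
    rows
  ))
}

occasions_header <- paste0(
  "participant_id,day,timestamp,label,item_name,energy_kcal,",
  "carb_g,sugar_g,fat_g,satfat_g,protein_g,fiber_g"
)

occasions_csv <- function(rows) {
  write_fixture_csv(c(occasions_header, rows))
}

occ_row <- function(pid = "P01", day = 1, ts = "2024-03-01T08:00:00",
                    label = "before", energy = 500, item = "meal") {
  sprintf("%s,%d,%s,%s,%s,%g,0,0,0,0,0,0", pid, day, ts, label, item, energy)
}

# differences with known mean/sd for agreement tests
pairs_from_diffs <- function(d, ref = 2000) {
  paired_estimates(sprintf("P%02d", seq_along(d)), ref + d, rep(ref, length(d)))
}
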