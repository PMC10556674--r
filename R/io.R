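#' @keywords internal
#' @importFrom stats coef complete.cases cor.test median pf pnorm pt qf qt
#'   rlnorm rnorm runif sd setNames shapiro.test t.test var wilcox.test
#' @importFrom utils read.csv
#' @importFrom rlang .data
"_PACKAGE"

# Column schemas for the interchange tables. Types: c character, d double,
# i integer, l logical.
.schema_participants <- c(
  id = "c", sex = "c", age_y = "d", height_cm = "d", weight_start_kg = "d",
  weight_end_kg = "d", smoker = "l", activity_band = "c"
)
.schema_occasions <- c(
  participant_id = "c", day = "i", timestamp = "c", label = "c",
  item_name = "c", energy_kcal = "d", carb_g = "d", sugar_g = "d",
  fat_g = "d", satfat_g = "d", protein_g = "d", fiber_g = "d"
)
.schema_recall24 <- c(
  participant_id = "c", tdei_kcal = "d", carb_g = "d", sugar_g = "d",
  fat_g = "d", satfat_g = "d", protein_g = "d", fiber_g = "d",
  occasions_n = "i"
)
.schema_isotopes <- c(
  participant_id = "c", dose_o18_g = "d", dose_d2_g = "d", ape_o18 = "d",
  ape_d2 = "d", E_pre_o18 = "d", E_post_o18 = "d", E_final_o18 = "d",
  E_pre_d2 = "d", E_post_d2 = "d", E_final_d2 = "d", t_post_h = "d",
  t_final_h = "d"
)

.activity_bands <- c("none", "1-2 h/wk", "2-6 h/wk", ">6 h/wk")
.occasion_labels <- c("before", "after", "ate_everything")

# Read a CSV as character, enforce the schema, convert column types with
# row-accurate parse errors. Never drops rows.
read_checked_csv <- function(path, schema, what) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop(what, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  raw <- raw[names(schema)]
  out <- raw
  for (col in names(schema)) {
    out[[col]] <- parse_column(raw[[col]], schema[[col]], col, what)
  }
  tibble::as_tibble(out)
}

parse_column <- function(x, type, col, what) {
  if (type == "c") return(x)
  if (type == "l") {
    v <- toupper(trimws(x))
    parsed <- ifelse(v %in% c("TRUE", "T", "1"), TRUE,
                     ifelse(v %in% c("FALSE", "F", "0"), FALSE, NA))
    bad <- which(is.na(parsed) & nzchar(x))
    if (length(bad) > 0) {
      stop(what, ": cannot parse `", col, "` as logical at row ", bad[1],
           " (value \"", x[bad[1]], "\")", call. = FALSE)
    }
    return(as.logical(parsed))
  }
  parsed <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(parsed) & nzchar(x) & toupper(x) != "NA")
  if (length(bad) > 0) {
    stop(what, ": cannot parse `", col, "` as numeric at row ", bad[1],
         " (value \"", x[bad[1]], "\")", call. = FALSE)
  }
  if (type == "i") as.integer(round(parsed)) else parsed
}

#' Read a participants table
#'
#' Expects the columns `id, sex, age_y, height_cm, weight_start_kg,
#' weight_end_kg, smoker, activity_band` (comma-separated, UTF-8, `.`
#' decimal). Age, height and both weights must be strictly positive;
#' `sex` must be `female` or `male`; `activity_band` one of
#' `none`, `1-2 h/wk`, `2-6 h/wk`, `>6 h/wk`. Row order is preserved and no
#' row is dropped.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per participant.
#' @export
read_participants <- function(path) {
  df <- read_checked_csv(path, .schema_participants, "read_participants")
  if (nrow(df) == 0) return(df)
  if (!all(df$sex %in% c("female", "male"))) {
    stop("read_participants: sex must be 'female' or 'male'", call. = FALSE)
  }
  for (col in c("age_y", "height_cm", "weight_start_kg", "weight_end_kg")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad) > 0) {
      stop("read_participants: `", col, "` must be strictly positive (row ",
           bad[1], ")", call. = FALSE)
    }
  }
  if (!all(df$activity_band %in% .activity_bands)) {
    stop("read_participants: activity_band must be one of ",
         paste(.activity_bands, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("read_participants: duplicated participant id", call. = FALSE)
  }
  df
}

#' Read an eating-occasion export
#'
#' Expects one row per recorded food item with the columns
#' `participant_id, day, timestamp, label, item_name, energy_kcal, carb_g,
#' sugar_g, fat_g, satfat_g, protein_g, fiber_g`. Labels follow the
#' image-based recording protocol: a `before` image opens an eating
#' occasion, and either an `after` image (leftovers) or an `ate_everything`
#' image closes it. Rows are grouped into occasions per participant-day in
#' timestamp order and an `occasion_id` column is added; an `after` image
#' with no preceding open `before` is kept but flagged `unmatched` with a
#' warning.
#'
#' @param path Path to a CSV file.
#' @return A tibble of item rows with `occasion_id` and `unmatched` columns
#'   added; the number of flagged rows is reported in attribute
#'   `n_unmatched`.
#' @export
read_occasions <- function(path) {
  df <- read_checked_csv(path, .schema_occasions, "read_occasions")
  bad_label <- which(!(df$label %in% .occasion_labels))
  if (length(bad_label) > 0) {
    stop("read_occasions: unknown label \"", df$label[bad_label[1]],
         "\" at row ", bad_label[1], " (expected ",
         paste(.occasion_labels, collapse = ", "), ")", call. = FALSE)
  }
  nutr <- c("energy_kcal", "carb_g", "sugar_g", "fat_g", "satfat_g",
            "protein_g", "fiber_g")
  for (col in nutr) {
    bad <- which(is.finite(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop("read_occasions: `", col, "` must be non-negative (row ", bad[1],
           ")", call. = FALSE)
    }
  }
  if (any(!is.na(df$day) & df$day < 1)) {
    stop("read_occasions: day index must be >= 1", call. = FALSE)
  }
  df <- assign_occasions(df)
  n_unmatched <- sum(df$unmatched)
  if (n_unmatched > 0) {
    warning("read_occasions: ", n_unmatched,
            " 'after' row(s) without a preceding 'before' image; ",
            "kept and flagged `unmatched`", call. = FALSE)
  }
  attr(df, "n_unmatched") <- n_unmatched
  df
}

# Group item rows into eating occasions per participant-day. A `before` row
# opens a new occasion unless one is open and still unclosed (items of the
# same image); `after`/`ate_everything` close the open occasion.
assign_occasions <- function(df) {
  df$.row <- seq_len(nrow(df))
  ord <- order(df$participant_id, df$day, df$timestamp, df$.row)
  df <- df[ord, ]
  df$occasion_id <- NA_integer_
  df$unmatched <- FALSE
  occ <- 0L
  key_prev <- NULL
  open <- FALSE          # a `before` image has opened an occasion
  open_ts <- NA_character_
  for (i in seq_len(nrow(df))) {
    key <- paste(df$participant_id[i], df$day[i], sep = "\r")
    if (!identical(key, key_prev)) {
      open <- FALSE
      key_prev <- key
    }
    lab <- df$label[i]
    ts <- df$timestamp[i]
    if (lab == "before") {
      if (open && identical(ts, open_ts)) {
        # another item of the same before image
        df$occasion_id[i] <- occ
      } else {
        occ <- occ + 1L
        open <- TRUE
        open_ts <- ts
        df$occasion_id[i] <- occ
      }
    } else if (open) {
      df$occasion_id[i] <- occ
      # items of the same closing image share a timestamp; close on last one
      nxt_same <- i < nrow(df) &&
        identical(paste(df$participant_id[i + 1], df$day[i + 1],
                        sep = "\r"), key) &&
        df$label[i + 1] != "before" &&
        identical(df$timestamp[i + 1], ts)
      if (!nxt_same) open <- FALSE
    } else if (lab == "ate_everything") {
      # standalone fully-consumed record forms its own occasion
      occ <- occ + 1L
      df$occasion_id[i] <- occ
    } else {
      occ <- occ + 1L
      df$occasion_id[i] <- occ
      df$unmatched[i] <- TRUE
    }
  }
  df <- df[order(df$.row), ]
  df$.row <- NULL
  df
}

#' Read single-day 24-hour recall totals
#'
#' One row per participant with total daily energy intake (kcal),
#' macronutrients (g) and the number of eating occasions of the recall day.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per participant.
#' @export
read_recall24 <- function(path) {
  df <- read_checked_csv(path, .schema_recall24, "read_recall24")
  if (anyDuplicated(df$participant_id)) {
    stop("read_recall24: one record per participant expected", call. = FALSE)
  }
  num <- setdiff(names(.schema_recall24), "participant_id")
  for (col in num) {
    bad <- which(is.finite(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop("read_recall24: `", col, "` must be non-negative (row ", bad[1],
           ")", call. = FALSE)
    }
  }
  df
}

#' Read an isotope enrichment table
#'
#' One row per participant with tracer doses (g), dose atom-percent-excess,
#' and background-corrected urine enrichments (ppm excess over the
#' reference standard) at pre-dose, post-dose plateau and final sampling,
#' plus the post-dose and final sample times in hours.
#'
#' @param path Path to a CSV file.
#' @return A tibble, one row per participant.
#' @export
read_isotopes <- function(path) {
  df <- read_checked_csv(path, .schema_isotopes, "read_isotopes")
  if (anyDuplicated(df$participant_id)) {
    stop("read_isotopes: one row per participant expected", call. = FALSE)
  }
  if (any(df$t_final_h <= df$t_post_h)) {
    stop("read_isotopes: t_final_h must exceed t_post_h", call. = FALSE)
  }
  df
}

#' Write an interchange table
#'
#' Writes a data frame as comma-separated UTF-8 with `.` decimals. Numeric
#' values are rendered with up to 17 significant digits so that re-reading
#' reproduces every double bit-exactly.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (!is.finite(v)) return(as.character(v))
        # shortest decimal string that round-trips the double
        for (d in 1:17) {
          s <- formatC(v, digits = d, format = "g")
          if (as.numeric(s) == v) return(s)
        }
        s
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a benchmark report
#'
#' Writes the machine-readable JSON form of a benchmark report (and, when
#' `markdown = TRUE`, a human-readable markdown rendering alongside it with
#' extension `.md`). Non-finite numbers are serialized as JSON `null` with a
#' warning. Writing the same report twice produces byte-identical JSON.
#'
#' @param report A `benchmark_report` (see [run_benchmark()]) or any list of
#'   named numeric/list fields.
#' @param path Output path for the JSON document.
#' @param markdown Also write a markdown rendering next to `path`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, markdown = inherits(report, "benchmark_report")) {
  if (has_nonfinite(report)) {
    warning("write_report: non-finite fields serialized as null",
            call. = FALSE)
  }
  json <- jsonlite::toJSON(strip_classes(report), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  if (isTRUE(markdown)) {
    md_path <- sub("\\.json$", "", path)
    writeLines(render_report(report, format = "markdown"),
               paste0(md_path, ".md"))
  }
  invisible(path)
}

#' Read back a serialized report
#'
#' @param path Path written by [write_report()].
#' @return A nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

has_nonfinite <- function(x) {
  if (is.list(x)) return(any(vapply(x, has_nonfinite, logical(1))))
  is.numeric(x) && any(is.nan(x) | is.infinite(x))
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    # keep names in JSON output (e.g. loa lower/upper)
    x <- as.list(x)
  }
  if (is.factor(x)) x <- as.character(x)
  x
}
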