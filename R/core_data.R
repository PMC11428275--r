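# Data model: specimen tables and the annual atmosphere series.
#
# A specimen table is a plain data.frame with one row per herbarium leaf and
# fixed, unit-committed columns (no unit auto-detection; silent unit errors
# dominate this domain):
#   specimen_id       text
#   species           text
#   year              calendar year
#   stomatal_density  stomata mm^-2 (leaf mean of 5 counts)
#   pore_length       um (leaf mean of 10 stomata)
#   guard_cell_width  um (used as stomatal pore depth)
#   delta13c          permil vs VPDB (optional)
#   lma               g m^-2 (optional; SLA is derived as 1/LMA)
#   n_area            g m^-2 (optional)
# Empty cells are absent values (NA); 0 is a measured (and rejected) value,
# never a sentinel.

.specimen_numeric_cols <- c("year", "stomatal_density", "pore_length",
                            "guard_cell_width", "delta13c", "lma", "n_area")
.specimen_mandatory    <- c("specimen_id", "species", "year")

#' Read a specimen trait table from CSV
#'
#' Reads a UTF-8, header-rowed, "." decimal CSV of per-specimen herbarium
#' trait records. Mandatory columns: `specimen_id`, `species`, `year`. Trait
#' columns (`stomatal_density`, `pore_length`, `guard_cell_width`,
#' `delta13c`, `lma`, `n_area`) are optional; absent columns are created as
#' all-`NA`, and empty cells become `NA`, never zero.
#'
#' @param path path to the CSV file.
#' @param sep field separator (CSV dialect option).
#' @return a specimen table (`data.frame`), one row per input row.
#' @seealso [write_specimen_table()], [validate_records()]
#' @export
read_specimen_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = TRUE, na.strings = c("", "NA"),
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.specimen_mandatory, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(specimen_id = raw$specimen_id,
                    species     = raw$species,
                    stringsAsFactors = FALSE)
  for (col in .specimen_numeric_cols) {
    if (col %in% names(raw)) {
      txt <- raw[[col]]
      val <- suppressWarnings(as.numeric(txt))
      bad <- which(!is.na(txt) & is.na(val))
      if (length(bad)) {
        stop(sprintf("malformed numeric value in column '%s', row %s: '%s'",
                     col, bad[1], txt[bad[1]]))
      }
      out[[col]] <- val
    } else {
      out[[col]] <- rep(NA_real_, nrow(raw))
    }
  }
  out[c(.specimen_mandatory[1:2], .specimen_numeric_cols)]
}

#' Write a specimen trait table to CSV
#'
#' Numeric columns are serialised with 17 significant digits so that a write
#' followed by [read_specimen_table()] reproduces every value to full double
#' precision.
#'
#' @param records specimen table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(records, path) {
  out <- records
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      txt <- sprintf("%.17g", out[[col]])
      txt[is.na(out[[col]])] <- NA_character_
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate specimen records against the trait invariants
#'
#' Removes records that violate the type invariants (non-positive stomatal
#' density, pore length, guard-cell width, LMA or N_area when present;
#' missing or non-finite year; optionally, year outside the atmosphere-series
#' coverage) and itemises the rejections. Validation is report-only: it never
#' errors on bad records, and it is idempotent.
#'
#' @param records specimen table.
#' @param atmosphere optional [atmosphere_series()]; when supplied, records
#'   whose year is outside its coverage are rejected.
#' @return list with `records` (clean table), `rejected` (rejected rows with
#'   a `reason` column) and `report` (data.frame of reason/count).
#' @export
validate_records <- function(records, atmosphere = NULL) {
  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  bad_pos <- function(x) !is.na(x) & x <= 0
  reason <- flag(is.na(records$year) | !is.finite(records$year),
                 "missing year")
  if (!is.null(atmosphere)) {
    rng <- range(atmosphere$year)
    reason <- flag(!is.na(records$year) &
                     (records$year < rng[1] | records$year > rng[2]),
                   "year outside atmosphere coverage")
  }
  reason <- flag(bad_pos(records$stomatal_density), "nonpositive density")
  reason <- flag(bad_pos(records$pore_length), "nonpositive pore length")
  reason <- flag(bad_pos(records$guard_cell_width),
                 "nonpositive guard cell width")
  reason <- flag(bad_pos(records$lma), "nonpositive LMA")
  reason <- flag(bad_pos(records$n_area), "nonpositive N_area")

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  report <- if (nrow(rejected)) {
    as.data.frame(table(reason = reason[!keep]), stringsAsFactors = FALSE,
                  responseName = "count")
  } else {
    data.frame(reason = character(0), count = integer(0))
  }
  list(records = records[keep, , drop = FALSE],
       rejected = rejected,
       report = report)
}

#' Write a rejection report as JSON lines
#'
#' One JSON object per rejected record, carrying the specimen id, the reason
#' and the original row index.
#'
#' @param validation result of [validate_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(validation, path) {
  rej <- validation$rejected
  lines <- character(0)
  if (!is.null(rej) && nrow(rej)) {
    lines <- vapply(seq_len(nrow(rej)), function(i) {
      jsonlite::toJSON(list(specimen_id = rej$specimen_id[i],
                            species = rej$species[i],
                            reason = rej$reason[i]),
                       auto_unbox = TRUE)
    }, character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct an annual atmosphere series
#'
#' An atmosphere series maps calendar years to ambient CO2 (`ca`, ppm) and
#' atmospheric delta-13C (`d13c_air`, permil). Years must be strictly
#' increasing and gapless within the declared range, and `ca` positive.
#'
#' @param year integer vector of consecutive years.
#' @param ca ambient CO2, ppm.
#' @param d13c_air atmospheric delta-13C, permil (optional; `NA` if absent).
#' @return data.frame of class `"atmosphere_series"`.
#' @export
atmosphere_series <- function(year, ca, d13c_air = NA_real_) {
  year <- as.integer(year)
  if (anyDuplicated(year)) stop("duplicate year in atmosphere series")
  if (is.unsorted(year, strictly = TRUE)) {
    stop("atmosphere series years must be strictly increasing")
  }
  if (any(diff(year) != 1L)) {
    stop("atmosphere series must have no gaps within its declared range")
  }
  if (any(!is.finite(ca)) || any(ca <= 0)) stop("ca must be positive")
  out <- data.frame(year = year, ca = ca,
                    d13c_air = rep_len(d13c_air, length(year)))
  class(out) <- c("atmosphere_series", "data.frame")
  out
}

#' Read an atmosphere series from CSV
#'
#' Reads a `year, ca[, d13c_air]` table. With `path = NULL` the bundled
#' default covering 1927-2015 is used: a smooth synthetic reconstruction of
#' the published annual CO2 and delta-13C records (see
#' `inst/extdata/atmosphere_1927_2015_synthetic.csv`), intended to be
#' replaced by a measured series where available.
#'
#' @param path CSV path, or `NULL` for the bundled default.
#' @return an [atmosphere_series()].
#' @export
read_atmosphere_series <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atmosphere_1927_2015_synthetic.csv",
                        package = "herbiwue", mustWork = TRUE)
  }
  tab <- utils::read.csv(path)
  if (!all(c("year", "ca") %in% names(tab))) {
    stop("atmosphere file must have columns 'year' and 'ca'")
  }
  atmosphere_series(tab$year, tab$ca,
                    if ("d13c_air" %in% names(tab)) tab$d13c_air else NA_real_)
}

#' Look up atmospheric composition for given years
#'
#' @param atmosphere an [atmosphere_series()].
#' @param year year(s) to look up; every year must be covered.
#' @return list with vectors `ca` and `d13c_air`.
#' @export
atmosphere_lookup <- function(atmosphere, year) {
  idx <- match(year, atmosphere$year)
  if (anyNA(idx[!is.na(year)])) {
    miss <- unique(year[is.na(idx) & !is.na(year)])
    stop("year(s) outside atmosphere series coverage: ",
         paste(miss, collapse = ", "))
  }
  list(ca = atmosphere$ca[idx], d13c_air = atmosphere$d13c_air[idx])
}
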