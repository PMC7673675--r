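#' Read and write the package's CSV interchange tables
#'
#' All stage inputs and outputs travel as plain CSV with fixed, documented
#' headers:
#' \describe{
#'   \item{SLIP tables}{`id, age_ka, age_2sigma_ka, H_m, I_m, S_m,
#'     S_2sigma_m, kind`}
#'   \item{calibration curves}{IntCal-style `cal_bp, c14_bp, sigma`}
#'   \item{tidal histories}{`time_ka, aM2_m, aS2_m`}
#'   \item{radiocarbon dates}{`lab_id, site_id, region, c14_age,
#'     c14_error`}
#'   \item{monument inventories}{`monument_id, period, start_bp, end_bp,
#'     known`}
#'   \item{candidate RSL curves}{`time_ka, rsl_m` (one file per model;
#'     the file name is the model label)}
#' }
#'
#' @param x the table to write.
#' @param path file path (for candidates, a directory).
#' @return readers return the validated object; writers return `path`
#'   invisibly.
#' @name paleoscape_io
NULL

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname paleoscape_io
#' @export
write_slips <- function(x, path) {
  check_cols(x, c("id", "age_ka", "age_2sigma_ka", "H_m", "I_m", "S_m",
                  "S_2sigma_m", "kind"), "SLIP table")
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname paleoscape_io
#' @export
read_slips <- function(path) {
  df <- check_cols(read.csv(path), c("id", "age_ka", "age_2sigma_ka",
                                     "H_m", "I_m", "S_m", "S_2sigma_m",
                                     "kind"), "SLIP table")
  bad <- !df$kind %in% c("precise", "marine_limiting",
                         "terrestrial_limiting")
  if (any(bad)) stop("unknown SLIP kind: ",
                     paste(unique(df$kind[bad]), collapse = ", "))
  structure(df, class = c("slip_table", "data.frame"))
}

#' @rdname paleoscape_io
#' @export
write_calcurve <- function(x, path) {
  check_cols(x, c("cal_bp", "c14_bp", "sigma"), "calibration curve")
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname paleoscape_io
#' @export
read_calcurve <- function(path) {
  df <- check_cols(read.csv(path), c("cal_bp", "c14_bp", "sigma"),
                   "calibration curve")
  calibration_curve(df$cal_bp, df$c14_bp, df$sigma)
}

#' @rdname paleoscape_io
#' @export
write_tides <- function(x, path) {
  check_cols(x, c("time_ka", "aM2_m", "aS2_m"), "tide history")
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname paleoscape_io
#' @export
read_tides <- function(path) {
  check_cols(read.csv(path), c("time_ka", "aM2_m", "aS2_m"),
             "tide history")
}

#' @rdname paleoscape_io
#' @export
write_dates <- function(x, path) {
  check_cols(x, c("lab_id", "site_id", "region", "c14_age", "c14_error"),
             "radiocarbon table")
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname paleoscape_io
#' @export
read_dates <- function(path) {
  check_cols(read.csv(path), c("lab_id", "site_id", "region", "c14_age",
                               "c14_error"), "radiocarbon table")
}

#' @rdname paleoscape_io
#' @export
write_monuments <- function(x, path) {
  check_cols(x, c("monument_id", "period", "start_bp", "end_bp", "known"),
             "monument inventory")
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname paleoscape_io
#' @export
read_monuments <- function(path) {
  check_cols(read.csv(path), c("monument_id", "period", "start_bp",
                               "end_bp", "known"), "monument inventory")
}

#' @rdname paleoscape_io
#' @export
read_gia_candidates <- function(path) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("no candidate CSV files in ", path)
  out <- lapply(files, function(f) {
    df <- check_cols(read.csv(f), c("time_ka", "rsl_m"),
                     paste("candidate", basename(f)))
    gia_candidate(sub("\\.csv$", "", basename(f)), df$time_ka, df$rsl_m)
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}
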