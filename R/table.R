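# The particle-table dialect shared by all pipeline stages.

# Columns every particle table must carry; further columns are preserved.
PARTICLE_TABLE_REQUIRED <- "particle_id"

#' Validate a particle table
#'
#' A particle table is a data.frame with one row per particle, a mandatory
#' unique `particle_id` column, and any number of further columns
#' (`diameter_nm`, `center_x/y/z` in 0-based voxel indices, `docked`,
#' `class_id`, `azimuth_deg`, shifts, `score`, ...). Unknown columns are
#' always preserved by I/O.
#'
#' @param tab a data.frame.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_particle_table <- function(tab) {
  if (!is.data.frame(tab)) stop("particle table must be a data.frame")
  missing_cols <- setdiff(PARTICLE_TABLE_REQUIRED, names(tab))
  if (length(missing_cols))
    stop(sprintf("particle table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(tab$particle_id))
    stop("duplicate particle_id values in particle table")
  if ("diameter_nm" %in% names(tab) &&
      any(!is.na(tab$diameter_nm) & tab$diameter_nm <= 0))
    stop("diameter_nm must be positive where set")
  invisible(tab)
}

#' Read a particle table (TSV)
#'
#' Tab-separated, UTF-8, '.' decimal separator, mandatory header row.
#'
#' @param path path to a TSV file.
#' @return a validated data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  validate_particle_table(tab)
  tab
}

#' Write a particle table (TSV)
#'
#' @param tab a particle table (validated before writing).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(tab, path) {
  validate_particle_table(tab)
  utils::write.table(tab, path, sep = "\t", dec = ".", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
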