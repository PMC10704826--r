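# Shared CSV reading with strict schema and locale checks. readr is used for
# parsing; any parse problem (e.g. "1,5" in a numeric column) is promoted to
# an error naming the offending line and column.
read_checked_csv <- function(path, required_first) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         locale = readr::locale(decimal_mark = ".",
                                                grouping_mark = ""))
  pb <- readr::problems(tbl)
  if (nrow(pb) > 0L) {
    abort(paste0("Parse error in ", path, " at line ", pb$row[1] + 1L,
                 ", column ", pb$col[1], ": expected ", pb$expected[1],
                 ", got '", pb$actual[1], "'."))
  }
  if (names(tbl)[1] != required_first) {
    abort(paste0(path, ": first column must be `", required_first, "`."))
  }
  for (col in names(tbl)[-1]) {
    if (!is.numeric(tbl[[col]]) && !all(is.na(tbl[[col]]))) {
      abort(paste0(path, ": column `", col, "` is not numeric."))
    }
  }
  tbl
}

#' Read and write trajectories, datasets, parameter sets and sweeps
#'
#' Plain-CSV serialisation for every package type; `write` followed by
#' `read` is the identity (up to numeric printing precision, 15 significant
#' digits). Trajectory files have a `time_h` column followed by the 16
#' canonical species; dataset files a `time_h` column and any measured
#' subset (blank cells are missing); parameter files one row per reaction
#' with columns `reaction, V, kA, kB, kC`; sweep files the long grid
#' columns of [run_sweep()]. Unknown species columns and non-`.`-decimal
#' numbers are rejected with a pointed error.
#'
#' @param x Object to write.
#' @param path File path.
#' @param label Provenance label for the read object.
#' @return Readers return the package type; writers return `path`
#'   invisibly.
#' @name abe_io
NULL

#' @rdname abe_io
#' @export
write_trajectory <- function(x, path) {
  readr::write_csv(as_tibble(x)[c("time_h", abe_species())], path)
  invisible(path)
}

#' @rdname abe_io
#' @export
read_trajectory <- function(path) {
  tbl <- read_checked_csv(path, "time_h")
  missing <- setdiff(abe_species(), names(tbl))
  if (length(missing)) {
    abort(paste0(path, ": missing species column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(tbl), c("time_h", abe_species()))
  if (length(extra)) {
    abort(paste0(path, ": unknown column(s): ", paste(extra, collapse = ", ")))
  }
  tbl[c("time_h", abe_species())]
}

#' @rdname abe_io
#' @export
write_dataset <- function(x, path) {
  readr::write_csv(as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname abe_io
#' @export
read_dataset <- function(path, label = basename(path)) {
  tbl <- read_checked_csv(path, "time_h")
  abe_dataset(tbl, label = label)
}

#' @rdname abe_io
#' @export
write_parameters <- function(x, path) {
  readr::write_csv(as_tibble(x)[c("reaction", "V", "kA", "kB", "kC")],
                   path, na = "")
  invisible(path)
}

#' @rdname abe_io
#' @export
read_parameters <- function(path, label = basename(path)) {
  tbl <- read_checked_csv(path, "reaction")
  abe_parameters(tbl, label = label)
}

#' @rdname abe_io
#' @export
write_sweep <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
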