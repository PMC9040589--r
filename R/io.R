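# Tabular I/O. All tables are tab-separated UTF-8 with a header row,
# decimal points, no quoting.

#' Write a table in the package's TSV dialect
#'
#' @param df data.frame.
#' @param path Output path (directories created as needed).
#' @export
write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV table
#'
#' @param path File path.
#' @return data.frame (strings kept as character).
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read an ion time-course table
#'
#' Validates the schema: metadata columns `species`, `medium`, `replicate`,
#' `time_h`, `od` followed by one numeric column per annotated ion, times
#' strictly increasing within each (species, medium, replicate), no
#' negative intensities.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ion_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("species", "medium", "replicate", "time_h", "od"),
                paste0("ion table '", path, "'"))
  ions <- setdiff(names(df), c("species", "medium", "replicate", "time_h",
                               "od"))
  for (ion in ions) {
    if (!is.numeric(df[[ion]])) {
      stop("ion column '", ion, "' is not numeric in ", path)
    }
    if (any(df[[ion]] < 0, na.rm = TRUE)) {
      stop("negative intensities in column '", ion, "' of ", path)
    }
  }
  key <- interaction(df$species, df$medium, df$replicate, drop = TRUE)
  for (grp in split(df, key)) {
    if (any(diff(grp$time_h) <= 0)) {
      stop("times not strictly increasing for ", grp$species[1], " / ",
           grp$medium[1], " replicate ", grp$replicate[1], " in ", path)
    }
  }
  df
}

#' Read a quantified concentration time-course table
#'
#' Schema: `metabolite`, `species`, `medium`, `time_h`, `conc_mM`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_concentration_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("metabolite", "species", "medium", "time_h",
                      "conc_mM"), paste0("concentration table '", path, "'"))
  df
}

#' Write a ground-truth edge list
#'
#' @param truth Result of [ground_truth()].
#' @param path Output TSV path (header `producer consumer metabolite`).
#' @export
write_ground_truth <- function(truth, path) {
  write_tsv(truth$edges, path)
}
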