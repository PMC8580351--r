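#' Packaged parameter and driver tables
#'
#' The package ships CSV transcriptions of the published per-cancer
#' parameter tables (male, female, and both-sexes-pooled fits to the
#' 2010-2013 registry data) and the driver-mutation decomposition table.
#' File integrity is verified against an md5 manifest before use.
#'
#' @param check verify md5 checksums against the packaged manifest
#' @return list of data frames: `male` (26 rows), `female` (29 rows),
#'   `pooled` (24 rows), `drivers` (27 rows)
#' @export
paper_fixture_tables <- function(check = TRUE) {
  files <- c(male = "table1a_male.csv", female = "table1b_female.csv",
             pooled = "table1c_pooled.csv", drivers = "table2_drivers.csv")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "stagesen", mustWork = TRUE), "")
  if (check) {
    manifest_path <- system.file("extdata", "manifest_md5.csv",
                                 package = "stagesen", mustWork = TRUE)
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    for (f in files) {
      want <- manifest$md5[manifest$file == f]
      got <- unname(tools::md5sum(paths[[which(files == f)]]))
      if (length(want) != 1L || !identical(got, want))
        stop("checksum mismatch for packaged fixture ", f)
    }
  }
  out <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  names(out) <- names(files)
  out
}
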