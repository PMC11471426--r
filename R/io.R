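# Plain-text I/O: occurrence CSV, layer TSV with a small header, jurisdiction
# centroids as GeoJSON points.

#' Write and read occurrence tables
#'
#' Standard occurrence CSV with columns species, x, y, year, source (plus any
#' extra columns present, e.g. the synthetic `artifact` labels).
#'
#' @param table occurrence data.frame.
#' @param path file path.
#' @return `read_occurrences` returns the data.frame.
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  need <- c("species", "x", "y", "year", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("occurrence file lacks column(s): ",
                            paste(missing, collapse = ", "))
  df
}

#' Write and read a raster layer as headered TSV
#'
#' Text raster format: three header lines (`# nrows ncols`, `# cell_size`,
#' `# origin x y`) followed by the matrix, row 1 first, tab-separated.
#'
#' @param layer numeric matrix.
#' @param path file path.
#' @param cell_size,origin grid geometry (km).
#' @return `read_layer_tsv` returns a list(layer, cell_size, origin).
#' @export
write_layer_tsv <- function(layer, path, cell_size = 1, origin = c(0, 0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %d %d", nrow(layer), ncol(layer)),
               sprintf("# %g", cell_size),
               sprintf("# %g %g", origin[1], origin[2])), con)
  utils::write.table(layer, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_layer_tsv
#' @export
read_layer_tsv <- function(path) {
  hdr <- readLines(path, n = 3)
  dims <- as.integer(strsplit(sub("^# ", "", hdr[1]), " ")[[1]])
  cell_size <- as.numeric(sub("^# ", "", hdr[2]))
  origin <- as.numeric(strsplit(sub("^# ", "", hdr[3]), " ")[[1]])
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 3))
  dimnames(m) <- NULL
  stopifnot(identical(dim(m), dims))
  list(layer = m, cell_size = cell_size, origin = origin)
}

#' Write jurisdiction centroids as GeoJSON points
#'
#' @param jurisdictions a `jurisdiction_set`.
#' @param path file path.
#' @export
write_jurisdictions_geojson <- function(jurisdictions, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("GeoJSON export needs the jsonlite package")
  }
  features <- lapply(seq_len(jurisdictions$n), function(i) {
    list(type = "Feature",
         properties = list(jurisdiction = jurisdictions$ids[i]),
         geometry = list(type = "Point",
                         coordinates = c(jurisdictions$centroids$x[i],
                                         jurisdictions$centroids$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
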