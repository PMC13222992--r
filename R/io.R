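## Plain-text interfaces: feature tables and point tables as CSV, scene
## configs as YAML, maps as CSV grids or (optionally) PNG previews.

#' Write / read a feature table as CSV
#'
#' @param table data.frame from [build_feature_table()].
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Save / load a scene configuration as YAML
#'
#' @param config a [scene_config()].
#' @param path file path.
#' @export
write_scene_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required to write YAML configs")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the yaml package is required to read YAML configs")
  do.call(scene_config, yaml::read_yaml(path))
}

#' Write an LAI map as a CSV grid
#'
#' Cell values only; cell size is recorded in a header comment line.
#'
#' @param map an `lai_map`.
#' @param path output file.
#' @export
write_lai_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(map$cell_size))
    writeLines(sprintf("# cell_size_cm: %s", map$cell_size), con)
  utils::write.table(map$grid, con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' Write an 8-bit PNG preview of a map or RGB patch
#'
#' Values are min-max scaled to [0, 1]. Requires the png package.
#'
#' @param x matrix or H x W x 3 array.
#' @param path output file.
#' @export
write_png_preview <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the png package is required for PNG output")
  v <- if (inherits(x, "lai_map")) x$grid else unclass(x)
  rng <- range(v)
  v <- if (diff(rng) == 0) v * 0 else (v - rng[1]) / diff(rng)
  png::writePNG(v, path)
  invisible(path)
}
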