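# File-format plumbing: gas-exchange CSV, labeled-volume TIFF stacks with a
# JSON sidecar, and climate CSV.

#' Read a gas-exchange table
#'
#' Long-format CSV, one row per observation. Required columns (after optional
#' renaming through `column_map`): `accession_id`, `treatment`, `replicate`,
#' `Ca`, `Ci`, `An`; optional: `PPFD`, `PhiPSII`, `T_leaf`, `gs`,
#' `Psi_leaflet`, `LMA`, `leaf_N`.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector mapping file column
#'   names to the canonical names, e.g. `c(A = "An", CO2_s = "Ca")`.
#' @return A data frame.
#' @export
read_gas_exchange <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  need <- c("accession_id", "treatment", "replicate", "Ca", "Ci", "An")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gas-exchange table is missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a gas-exchange table
#'
#' @param df Data frame as produced by the simulator/pipeline.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a labeled volume as a multi-page TIFF plus JSON sidecar
#'
#' One 8-bit page per z slice (axis 1), label values stored directly. The
#' sidecar records the voxel size, axis order and label map.
#'
#' @param v A [labeled_volume()].
#' @param tif_path,json_path Output paths; the sidecar defaults to the TIFF
#'   path with a `.json` extension.
#' @return `tif_path`, invisibly.
#' @export
write_labeled_volume <- function(v, tif_path,
                                 json_path = sub("\\.tiff?$", ".json", tif_path)) {
  d <- dim(v$voxels)
  pages <- lapply(seq_len(d[1]), function(z) v$voxels[z, , ] / 255)
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 8L, compression = "none")
  jsonlite::write_json(
    list(voxel_size_um = v$voxel_size,
         axis_order = "z,x,y",
         label_map = as.list(setNames(0:6, names(LABELS)))),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(tif_path)
}

#' Read a labeled volume from a multi-page TIFF plus JSON sidecar
#'
#' @param tif_path,json_path Input paths (sidecar defaults as in
#'   [write_labeled_volume()]).
#' @return A [labeled_volume()].
#' @export
read_labeled_volume <- function(tif_path,
                                json_path = sub("\\.tiff?$", ".json", tif_path)) {
  pages <- tiff::readTIFF(tif_path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  d1 <- length(pages)
  d23 <- dim(pages[[1]])
  arr <- array(0L, dim = c(d1, d23[1], d23[2]))
  for (z in seq_len(d1)) arr[z, , ] <- as.integer(round(pages[[z]]))
  vs <- meta$voxel_size_um
  labeled_volume(arr, if (is.null(vs)) 0.65 else as.numeric(vs))
}

#' Read a climate table
#'
#' Wide CSV, one row per site: `site_id`, `latitude`, `t01..t12`, `p01..p12`,
#' `frost_free_days`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_climate <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", sprintf("t%02d", 1:12), sprintf("p%02d", 1:12))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("climate table is missing columns: ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a climate table
#'
#' @param df Data frame in the wide per-site layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
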