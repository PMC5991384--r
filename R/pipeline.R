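#' Extract descriptor features for every image of a dataset
#'
#' Optionally tiles each whole image into sub-images first, then runs the
#' selected texture descriptors on every (sub-)image. The result feeds
#' [run_cv()] directly: one feature matrix per descriptor plus the per-row
#' bookkeeping (label, patient, parent image, manifest row) that the fold
#' protocol needs.
#'
#' @param manifest an `ms_manifest`.
#' @param cubes named list of `spectral_cube` keyed by `cube_id`; when
#'   `NULL`, cubes are read from `manifest$cube_path`.
#' @param cfg a [descriptor_config()].
#' @param descriptors descriptor subset to run (default all six).
#' @param band_subset optional band indices, e.g. a [select_bands()] result.
#' @param tile optional `c(tile_h, tile_w)`; when given every image is split
#'   into non-overlapping tiles and rows describe tiles.
#' @return list with `features` (named list of matrices), `info` (data.frame
#'   with `label`, `patient_id`, `slide_id`, `parent_image_id`,
#'   `tile_index`) and `fold_of` (manifest row index of each feature row).
#' @export
extract_dataset_features <- function(manifest, cubes = NULL,
                                     cfg = descriptor_config(),
                                     descriptors = descriptor_names(),
                                     band_subset = NULL, tile = NULL) {
  wl <- attr(manifest, "wavelengths_nm")
  tg <- attr(manifest, "spectrum_tags")
  rows <- list(); feats <- list(); fold_of <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    cube <- if (!is.null(cubes)) cubes[[manifest$cube_id[i]]]
    else read_cube(manifest$cube_path[i], wl, tg)
    ls0 <- labeled_sample(cube, manifest$label[i], manifest$patient_id[i],
                          manifest$slide_id[i])
    parts <- if (is.null(tile)) list(ls0) else tile_cube(ls0, tile[1], tile[2])
    for (s in parts) {
      fv <- extract_all(s$cube, cfg, band_subset = band_subset,
                        descriptors = descriptors)
      rows[[length(rows) + 1L]] <-
        data.frame(label = s$label, patient_id = s$patient_id,
                   slide_id = s$slide_id, parent_image_id = s$parent_image_id,
                   tile_index = s$tile_index, stringsAsFactors = FALSE)
      fold_of <- c(fold_of, i)
      for (d in descriptors)
        feats[[d]][[length(fold_of)]] <- fv[[d]]$values
    }
  }
  list(features = lapply(feats, function(v) do.call(rbind, v)),
       info = do.call(rbind, rows),
       fold_of = fold_of)
}
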