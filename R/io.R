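#' Write / read phantom voxel data as NIfTI
#'
#' HU images are stored as signed 16-bit with voxel spacing in the header;
#' labels as 8-bit.  The centerline and per-station ground truth go to CSV
#' alongside.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if missing).
#' @return `write_phantom()` invisibly returns the written paths;
#'   `read_image_volume()` returns an [image_volume()].
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, "image.nii.gz"),
             labels = file.path(dir, "labels.nii.gz"),
             component = file.path(dir, "component.nii.gz"),
             centerline = file.path(dir, "centerline.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  img <- phantom$image
  as_nii <- function(arr, datatype, spacing) {
    RNifti::asNifti(structure(arr, pixdim = spacing), datatype = datatype)
  }
  RNifti::writeNifti(
    as_nii(array(as.integer(round(img$data)), dim(img$data)), "int16",
           img$spacing), paths["image"])
  RNifti::writeNifti(as_nii(phantom$labels$label, "uint8",
                            phantom$labels$spacing), paths["labels"])
  RNifti::writeNifti(as_nii(phantom$labels$component, "uint8",
                            phantom$labels$spacing), paths["component"])
  readr::write_csv(phantom$centerline, paths["centerline"])
  readr::write_csv(phantom$truth$stations, paths["truth"])
  invisible(paths)
}

#' @rdname write_phantom
#' @param path a NIfTI file written by [write_phantom()].
#' @param origin world origin to attach (mm).
#' @export
read_image_volume <- function(path, origin = c(0, 0, 0)) {
  nii <- RNifti::readNifti(path)
  image_volume(array(as.numeric(nii), dim(nii)),
               spacing = RNifti::pixdim(nii)[1:3], origin = origin)
}

#' Write / read a pullback profile as CSV plus a JSON anchor sidecar
#'
#' @param profile a `pullback_profile`.
#' @param path CSV path; anchors go to `<path>.anchors.json`.
#' @return the read-back `pullback_profile` for `read_pullback_profile()`.
#' @export
write_pullback_profile <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  jsonlite::write_json(pullback_anchors(profile),
                       paste0(path, ".anchors.json"), digits = NA)
  invisible(path)
}

#' @rdname write_pullback_profile
#' @export
read_pullback_profile <- function(path) {
  prof <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  anchors <- as_tibble(jsonlite::read_json(paste0(path, ".anchors.json"),
                                           simplifyVector = TRUE))
  new_pullback_profile(prof, anchors)
}

#' Serialize a phantom spec to YAML (and back)
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$stenoses <- as.list(as.data.frame(x$stenoses))
  x$bulges <- as.list(as.data.frame(x$bulges))
  x$deposits <- as.list(as.data.frame(x$deposits))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  tb <- function(l) if (length(l[[1]]) || length(l) == 0) as_tibble(l) else NULL
  phantom_spec(
    length_mm = x$length_mm, centerline_kind = x$centerline_kind,
    helix_radius_mm = x$helix_radius_mm, helix_pitch_mm = x$helix_pitch_mm,
    lumen_radius_mm = x$lumen_radius_mm, outer_radius_mm = x$outer_radius_mm,
    stenoses = tb(x$stenoses), bulges = tb(x$bulges),
    deposits = tb(x$deposits),
    bifurcations_mm = unlist(x$bifurcations_mm) %||% numeric(),
    hu_params = purrr::map(x$hu_params, unlist),
    psf_sigma_mm = x$psf_sigma_mm, noise_sd_hu = x$noise_sd_hu,
    voxel_mm = x$voxel_mm, seed = x$seed)
}

#' Serialize a warp map to a JSON knot list (and back)
#'
#' @param warp a `warp_map`.
#' @param path JSON file path.
#' @export
write_warp_map <- function(warp, path) {
  jsonlite::write_json(warp$knots, path, digits = NA)
  invisible(path)
}

#' @rdname write_warp_map
#' @export
read_warp_map <- function(path) {
  new_warp_map(as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)))
}

#' Write / read a study configuration as YAML
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(study_config, x[!vapply(x, is.null, logical(1))])
}

#' Write study outputs (per-lesion table, report, manifest)
#'
#' @param result a `study_result` from [run_study()].
#' @param dir output directory.
#' @export
write_study_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$lesions, file.path(dir, "lesions.csv"))
  rep <- list(measures = result$report$measures, lap = result$report$lap,
              n_lesions = result$report$n_lesions)
  jsonlite::write_json(rep, file.path(dir, "agreement_report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (nrow(result$exclusions)) {
    readr::write_csv(result$exclusions, file.path(dir, "exclusions.csv"))
  }
  invisible(dir)
}

#' Write / read a cross-section series as CSV
#'
#' The `wall_hu` sample list (if present) is dropped: the CSV holds the
#' per-station area table.
#'
#' @param series a `cross_sections` tibble.
#' @param path CSV path.
#' @export
write_cross_sections <- function(series, path) {
  out <- as_tibble(series)
  out$wall_hu <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cross_sections
#' @export
read_cross_sections <- function(path) {
  out <- strip_readr_attrs(readr::read_csv(path, show_col_types = FALSE))
  structure(out, class = c("cross_sections", class(tibble())),
            step_mm = if (nrow(out) > 1) diff(out$s_mm[1:2]) else NA_real_)
}

#' Plaque volumes as a JSON report
#'
#' Thresholds (when known) are echoed into the report for auditability.
#'
#' @param volumes a `plaque_volumes` row from [component_volumes()].
#' @param path JSON path.
#' @param thresholds optional [component_thresholds()] to echo.
#' @export
write_plaque_volumes <- function(volumes, path, thresholds = NULL) {
  x <- as.list(volumes)
  if (!is.null(thresholds)) x$thresholds <- unclass(thresholds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}
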