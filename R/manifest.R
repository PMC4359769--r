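#' Plant manifest: per-plant acquisition metadata
#'
#' Records what the TAC file cannot: which plant was scanned, how much
#' activity was administered and for how long, the delay between scan start
#' and administration, and where each ROI sits along the stem.
#'
#' @param plant_id character scalar.
#' @param administered_activity_Bq total administered activity (Bq, > 0).
#' @param administration_duration_s duration of the drop-by-drop petiolar
#'   administration (seconds, > 0).
#' @param roi_positions_mm named numeric vector mapping ROI label to stem
#'   position in mm above the administration node; at least two distinct
#'   ROIs are required for velocity fitting, labels must be unique.
#' @param admin_offset_s seconds between scan start and administration
#'   start; default 60.
#' @param slice_thickness_mm per-length conversion factor for single-plane
#'   ROIs; default 1.21 mm.
#' @param age_days plant age at scan (optional, used in cohort summaries).
#' @return An object of class `plant_manifest`.
#' @seealso [read_manifest()], [fit_transport()]
#' @export
plant_manifest <- function(plant_id, administered_activity_Bq,
                           administration_duration_s, roi_positions_mm,
                           admin_offset_s = 60, slice_thickness_mm = 1.21,
                           age_days = NA_real_) {
  if (!is.numeric(administered_activity_Bq) ||
      administered_activity_Bq <= 0) {
    stop("'administered_activity_Bq' must be > 0", call. = FALSE)
  }
  if (!is.numeric(administration_duration_s) ||
      administration_duration_s <= 0) {
    stop("'administration_duration_s' must be > 0", call. = FALSE)
  }
  roi_positions_mm <- unlist(roi_positions_mm)
  if (length(roi_positions_mm) < 2L) {
    stop("at least 2 ROI positions are required for velocity fitting",
         call. = FALSE)
  }
  if (is.null(names(roi_positions_mm)) ||
      anyDuplicated(names(roi_positions_mm)) ||
      any(names(roi_positions_mm) == "")) {
    stop("'roi_positions_mm' must have unique non-empty names",
         call. = FALSE)
  }
  structure(
    list(
      plant_id = as.character(plant_id)[1L],
      administered_activity_Bq = as.numeric(administered_activity_Bq),
      administration_duration_s = as.numeric(administration_duration_s),
      admin_offset_s = as.numeric(admin_offset_s),
      roi_positions_mm = roi_positions_mm,
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      age_days = as.numeric(age_days)[1L]
    ),
    class = "plant_manifest"
  )
}

#' Read and write plant manifests (YAML)
#'
#' Flat key-value YAML with the [plant_manifest()] fields;
#' `roi_positions_mm` is a label-to-millimetre mapping.
#'
#' @param path file path.
#' @param manifest a [plant_manifest()].
#' @return `read_manifest()` returns a [plant_manifest()];
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("plant_id", "administered_activity_Bq",
                "administration_duration_s", "roi_positions_mm")
  missing <- setdiff(required, names(y))
  if (length(missing) > 0L) {
    stop(sprintf("manifest %s is missing field(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  plant_manifest(
    plant_id = y$plant_id,
    administered_activity_Bq = y$administered_activity_Bq,
    administration_duration_s = y$administration_duration_s,
    roi_positions_mm = unlist(y$roi_positions_mm),
    admin_offset_s = if (is.null(y$admin_offset_s)) 60 else y$admin_offset_s,
    slice_thickness_mm =
      if (is.null(y$slice_thickness_mm)) 1.21 else y$slice_thickness_mm,
    age_days = if (is.null(y$age_days)) NA_real_ else y$age_days
  )
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "plant_manifest"))
  yaml::write_yaml(
    list(
      plant_id = manifest$plant_id,
      administered_activity_Bq = manifest$administered_activity_Bq,
      administration_duration_s = manifest$administration_duration_s,
      admin_offset_s = manifest$admin_offset_s,
      roi_positions_mm = as.list(manifest$roi_positions_mm),
      slice_thickness_mm = manifest$slice_thickness_mm,
      age_days = manifest$age_days
    ),
    path
  )
  invisible(path)
}

#' @export
print.plant_manifest <- function(x, ...) {
  cat(sprintf("Plant '%s': %.3g MBq over %g s, %d ROIs at %s mm\n",
              x$plant_id, x$administered_activity_Bq / 1e6,
              x$administration_duration_s, length(x$roi_positions_mm),
              paste(x$roi_positions_mm, collapse = ", ")))
  invisible(x)
}
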