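#' Construct a time-activity curve (TAC)
#'
#' A TAC holds the observed activity concentration in one stem region of
#' interest (ROI) over a dynamic scan, expressed per vertical length of stem
#' and normalized by the total administered activity (units 1/mm, i.e.
#' (Bq/mm)/Bq). Values are assumed decay-corrected; no decay term appears in
#' the kinetic model.
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one activity value per frame (1/mm). Small
#'   negative values are tolerated (scatter-corrected PET noise), but the
#'   mean must be non-negative for the curve to be fittable.
#' @param roi_label character scalar identifying the ROI.
#' @param position_mm stem position of the ROI in millimetres above the
#'   administration node (signed; positive is up-stem).
#' @return An object of class `tac`.
#' @seealso [read_tac_file()], [rebase_to_administration()], [normalize_tac()]
#' @export
tac <- function(schedule, values, roi_label = "roi", position_mm = NA_real_) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != length(schedule$mid_time)) {
    stop(sprintf("'values' has length %d but the schedule has %d frames",
                 length(values), length(schedule$mid_time)), call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("TAC values must be finite", call. = FALSE)
  }
  structure(
    list(
      schedule = schedule,
      values = values,
      roi_label = as.character(roi_label)[1L],
      position_mm = as.numeric(position_mm)[1L]
    ),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s' at %g mm: %d frames, %g-%g s, peak %.3g\n",
              x$roi_label, x$position_mm, length(x$values),
              x$schedule$frame_start[1L],
              max(x$schedule$frame_start + x$schedule$frame_duration),
              max(x$values)))
  invisible(x)
}

tac_columns <- c("roi_label", "position_mm", "frame_start_s",
                 "frame_duration_s", "value")

#' Read and write time-activity curves as TSV
#'
#' The on-disk TAC format is UTF-8 tab-separated text with one row per
#' (ROI, frame) and header columns `roi_label`, `position_mm`,
#' `frame_start_s`, `frame_duration_s`, `value`. Lines starting with `#` are
#' ignored. Frames belonging to one ROI must form a contiguous schedule.
#' Writing then reading reproduces all numeric fields to at least 12
#' significant digits.
#'
#' @param path file path.
#' @param curves a list of [tac()] objects.
#' @return `read_tac_file()` returns a list of [tac()] objects, one per ROI,
#'   in file order; `write_tac_file()` returns `path` invisibly.
#' @export
read_tac_file <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(tac_columns, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("TAC file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  labels <- unique(df$roi_label)
  lapply(labels, function(lab) {
    rows <- df[df$roi_label == lab, , drop = FALSE]
    rows <- rows[order(rows$frame_start_s), , drop = FALSE]
    sched <- tryCatch(
      frame_schedule(rows$frame_start_s, rows$frame_duration_s),
      error = function(e) {
        stop(sprintf("ROI '%s' in %s has an invalid frame schedule: %s",
                     lab, path, conditionMessage(e)), call. = FALSE)
      }
    )
    pos <- unique(rows$position_mm)
    if (length(pos) != 1L) {
      stop(sprintf("ROI '%s' in %s has inconsistent position_mm", lab, path),
           call. = FALSE)
    }
    tac(sched, rows$value, roi_label = lab, position_mm = pos)
  })
}

#' @rdname read_tac_file
#' @export
write_tac_file <- function(curves, path) {
  if (inherits(curves, "tac")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, logical(1), "tac")))
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(
      roi_label = cv$roi_label,
      position_mm = cv$position_mm,
      frame_start_s = cv$schedule$frame_start,
      frame_duration_s = cv$schedule$frame_duration,
      value = cv$values,
      stringsAsFactors = FALSE
    )
  }))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(tac_columns, collapse = "\t"), con)
  num <- function(x) sprintf("%.15g", x)
  writeLines(paste(rows$roi_label, num(rows$position_mm),
                   num(rows$frame_start_s), num(rows$frame_duration_s),
                   num(rows$value), sep = "\t"), con)
  invisible(path)
}

#' Shift a TAC onto the administration time axis
#'
#' The scanner clock starts before tracer administration (the petiole is cut
#' and fed a fixed delay after scan start). All kinetic modeling uses t = 0
#' at administration start, where the trapped compartment's initial
#' condition B(0) = 0 holds. This shifts frame starts by `-admin_offset_s`
#' and drops frames whose mid-time becomes negative: they precede the tracer
#' and carry no signal.
#'
#' @param curve a [tac()].
#' @param admin_offset_s seconds between scan start and administration start
#'   (non-negative, less than the scan span).
#' @return A [tac()] on the administration time axis; durations and
#'   per-frame values of retained frames are unchanged.
#' @export
#' @examples
#' cv <- tac(standard_frame_schedule(), rep(1, 28))
#' rebase_to_administration(cv, 60)$schedule$mid_time[1]  # 30
rebase_to_administration <- function(curve, admin_offset_s) {
  stopifnot(inherits(curve, "tac"))
  admin_offset_s <- as.numeric(admin_offset_s)[1L]
  if (!is.finite(admin_offset_s) || admin_offset_s < 0) {
    stop("'admin_offset_s' must be a non-negative number", call. = FALSE)
  }
  start <- curve$schedule$frame_start - admin_offset_s
  mid <- start + curve$schedule$frame_duration / 2
  keep <- mid >= 0
  if (!any(keep)) {
    stop("administration offset leaves no frames with non-negative mid-time",
         call. = FALSE)
  }
  tac(frame_schedule(start[keep], curve$schedule$frame_duration[keep]),
      curve$values[keep], roi_label = curve$roi_label,
      position_mm = curve$position_mm)
}

#' Normalize raw ROI activity to concentration per stem length per
#' administered activity
#'
#' Converts raw reconstructed activity concentration (Bq/ml) in a
#' single-plane ROI into the normalized units the kinetic model uses:
#' activity per vertical millimetre of stem per becquerel administered
#' (1/mm). The chain is raw concentration times ROI volume (total Bq in the
#' ROI), divided by the ROI's vertical extent (the reconstruction slice
#' thickness for a single-plane ROI), divided by total administered
#' activity.
#'
#' @param raw_values numeric vector of raw activity concentrations (Bq/ml).
#' @param roi_volume_ml ROI volume in ml (> 0).
#' @param slice_thickness_mm vertical extent of the ROI in mm (> 0);
#'   default 1.21, a typical reconstruction slice thickness.
#' @param administered_activity_Bq total administered activity in Bq (> 0).
#' @return Numeric vector of normalized values (1/mm), linear in the input.
#' @export
normalize_tac <- function(raw_values, roi_volume_ml,
                          slice_thickness_mm = 1.21,
                          administered_activity_Bq) {
  for (arg in c("roi_volume_ml", "slice_thickness_mm",
                "administered_activity_Bq")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive number", arg),
           call. = FALSE)
    }
  }
  as.numeric(raw_values) * roi_volume_ml / slice_thickness_mm /
    administered_activity_Bq
}
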