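#' Describe a repeated-acquisition OCTA study
#'
#' A study manifest records the design of a repeated-acquisition study: how
#' many participants and eyes were imaged, how many sequential acquisitions
#' were taken per eye and scan area, and which scan areas and slabs are
#' analysed. All enumeration helpers are pure functions of these fields.
#'
#' @param n_participants,eyes_per_participant,n_acquisitions Positive counts.
#' @param scan_areas Character vector, subset of `c("A3x3", "A6x6")`.
#' @param slabs Character vector, subset of `c("SVP", "DVC", "FULL")`.
#' @param groups Character vector of length `n_participants` assigning each
#'   participant to `"healthy"` or `"oedema"` (recycled if length 1).
#' @return A `study_manifest` object.
#' @examples
#' m <- study_manifest(10, 2, 5, c("A3x3", "A6x6"), c("SVP", "DVC"))
#' enumerate_counts(m)
#' @export
study_manifest <- function(n_participants, eyes_per_participant = 2L,
                           n_acquisitions = 5L,
                           scan_areas = c("A3x3", "A6x6"),
                           slabs = c("SVP", "DVC"),
                           groups = "healthy") {
  stopifnot(
    n_participants >= 1, eyes_per_participant >= 1, n_acquisitions >= 1,
    length(scan_areas) >= 1, length(slabs) >= 1
  )
  scan_areas <- match.arg(scan_areas, c("A3x3", "A6x6"), several.ok = TRUE)
  slabs <- match.arg(slabs, c("SVP", "DVC", "FULL"), several.ok = TRUE)
  groups <- rep_len(match.arg(groups, c("healthy", "oedema"),
    several.ok = TRUE
  ), n_participants)
  structure(
    list(
      n_participants = as.integer(n_participants),
      eyes_per_participant = as.integer(eyes_per_participant),
      n_acquisitions = as.integer(n_acquisitions),
      scan_areas = scan_areas, slabs = slabs, groups = groups
    ),
    class = "study_manifest"
  )
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf(
    "<study_manifest> %d participants x %d eyes x %d acquisitions; areas: %s; slabs: %s\n",
    x$n_participants, x$eyes_per_participant, x$n_acquisitions,
    paste(x$scan_areas, collapse = ","), paste(x$slabs, collapse = ",")
  ))
  invisible(x)
}

#' Enumerate the image and analysis counts implied by a study design
#'
#' Computes, from the design alone, how many acquisitions are performed, how
#' many repeatability (ICC) cells the design yields, how many single and
#' averaged images result, and how many 3x3-grid boxes enter semi-quantitative
#' grading (grading uses the 3x3-mm area only).
#'
#' @param manifest A [study_manifest].
#' @return A one-row tibble with columns `acquisitions`, `icc_cells`,
#'   `single_images`, `averaged_images`, `grading_boxes`.
#' @export
enumerate_counts <- function(manifest) {
  stopifnot(inherits(manifest, "study_manifest"))
  m <- manifest
  eyes <- m$n_participants * m$eyes_per_participant
  tibble::tibble(
    acquisitions = eyes * m$n_acquisitions * length(m$scan_areas),
    icc_cells = eyes * length(m$scan_areas) * length(m$slabs),
    single_images = eyes * m$n_acquisitions * length(m$scan_areas) *
      length(m$slabs),
    averaged_images = eyes * length(m$scan_areas) * length(m$slabs),
    grading_boxes = if ("A3x3" %in% m$scan_areas) {
      eyes * length(m$slabs) * 9L
    } else {
      0L
    }
  )
}

#' Expand a study design into one row per image
#'
#' @param manifest A [study_manifest].
#' @param file_path Optional function `(participant, eye, area, slab, acq)`
#'   returning a file path for each image; default leaves `NA`.
#' @return A tibble with one row per (participant, eye, area, slab,
#'   acquisition) and columns `participant`, `eye`, `eye_id`, `scan_area`,
#'   `slab`, `acquisition`, `group`, `file_path`.
#' @export
build_manifest <- function(manifest, file_path = NULL) {
  stopifnot(inherits(manifest, "study_manifest"))
  m <- manifest
  tbl <- tidyr::expand_grid(
    participant = seq_len(m$n_participants),
    eye = seq_len(m$eyes_per_participant),
    scan_area = m$scan_areas,
    slab = m$slabs,
    acquisition = seq_len(m$n_acquisitions)
  )
  tbl <- dplyr::mutate(tbl,
    eye_id = sprintf("P%02dE%d", .data$participant, .data$eye),
    group = m$groups[.data$participant],
    file_path = if (is.null(file_path)) {
      NA_character_
    } else {
      purrr::pmap_chr(
        list(
          .data$participant, .data$eye, .data$scan_area, .data$slab,
          .data$acquisition
        ),
        file_path
      )
    }
  )
  dplyr::relocate(
    tbl, "participant", "eye", "eye_id", "scan_area", "slab",
    "acquisition", "group", "file_path"
  )
}

#' Retinal-thickness threshold defining macular oedema
#'
#' Oedema is defined as a central-subfield retinal thickness exceeding the
#' normal mean plus two standard deviations.
#'
#' @param normal_mean_um,normal_sd_um Normal central-subfield thickness mean
#'   and SD, in micrometres; the SD may be zero.
#' @return The threshold in micrometres.
#' @examples
#' oedema_thickness_threshold(260, 19) # 298
#' @export
oedema_thickness_threshold <- function(normal_mean_um, normal_sd_um) {
  if (normal_mean_um <= 0 || normal_sd_um < 0) {
    stop("thickness parameters must be positive", call. = FALSE)
  }
  normal_mean_um + 2 * normal_sd_um
}
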