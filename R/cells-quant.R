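#' Segment cell ROIs from the activity-insensitive reference channel
#'
#' Two-pass intensity segmentation standing in for manually drawn ROIs:
#' a first Otsu split separates cells from background; connected
#' components below `min_cell_area_px` are dropped; within each cell a
#' second Otsu split separates the brighter nucleus from the cytoplasm
#' (largest nuclear component kept). An ROI whose nucleus fills the whole
#' cell is flagged invalid (`valid = FALSE`) since it has no cytoplasm to
#' compare against.
#'
#' @param reference `H x W` matrix of the reference channel (or a
#'   `cell_image`, whose `$reference` is used).
#' @param min_cell_area_px Minimum cell area, px.
#' @return A list of ROIs, each a list with logical matrices `cell_mask`,
#'   `nuclear_mask`, `cytoplasm_mask` and a `valid` flag. Empty list if no
#'   cell is found.
#' @export
segment_cell_rois <- function(reference, min_cell_area_px = 30) {
  if (inherits(reference, "cell_image")) reference <- reference$reference
  th1 <- tryCatch(otsu_threshold(as.numeric(reference)),
                  larvasleep_degenerate_input = function(e) NULL)
  if (is.null(th1)) return(list())
  fg <- reference > th1
  if (!any(fg)) return(list())
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(reference))
  rois <- list()
  for (lab in setdiff(sort(unique(as.vector(labels))), 0L)) {
    cell <- labels == lab
    if (sum(cell) < min_cell_area_px) next
    inner <- reference[cell]
    th2 <- tryCatch(otsu_threshold(inner),
                    larvasleep_degenerate_input = function(e) NULL)
    nuc <- matrix(FALSE, nrow(reference), ncol(reference))
    if (!is.null(th2)) {
      nuc[cell] <- inner > th2
      if (any(nuc)) {
        nl <- EBImage::bwlabel(EBImage::Image(nuc * 1))
        nl <- matrix(as.integer(EBImage::imageData(nl)), nrow(reference))
        sizes <- tabulate(nl[nl > 0])
        nuc <- nl == which.max(sizes)
      }
    }
    cyto <- cell & !nuc
    rois[[length(rois) + 1L]] <- list(cell_mask = cell, nuclear_mask = nuc,
                                      cytoplasm_mask = cyto,
                                      valid = any(cyto) && any(nuc))
  }
  rois
}

#' Nuclear localization index of a translocation reporter
#'
#' `F_nuc` and `F_cyto` are the background-subtracted mean reporter
#' intensities over the nuclear and cytoplasmic masks (floored at zero);
#' the index is `NLI = (F_nuc - F_cyto) / (F_nuc + F_cyto)`, bounded in
#' `[-1, 1]`, `NA` when both means are zero. With `background = NULL` the
#' background is estimated as the median reporter intensity outside the
#' cell mask.
#'
#' @param reporter `H x W` reporter-channel matrix (or a `cell_image`).
#' @param roi One ROI from [segment_cell_rois()].
#' @param background Scalar background level, or `NULL` to estimate.
#' @param integrated Use integrated (summed) rather than mean region
#'   intensities; provided for comparison, the mean convention is the
#'   default and keeps the index bounded.
#' @return A one-row tibble: `f_nuc`, `f_cyto`, `nli`,
#'   `n_nuclear_px`, `n_cytoplasm_px`.
#' @export
compute_nli <- function(reporter, roi, background = NULL,
                        integrated = FALSE) {
  if (inherits(reporter, "cell_image")) reporter <- reporter$reporter
  if (!any(roi$cytoplasm_mask)) {
    abort("ROI has an empty cytoplasm mask.", class = "larvasleep_invalid_roi")
  }
  if (is.null(background)) {
    background <- median(reporter[!roi$cell_mask])
  }
  assert_scalar_num(background, "background", min = 0)
  agg <- if (integrated) sum else mean
  f_nuc <- max(0, agg(reporter[roi$nuclear_mask] - background))
  f_cyto <- max(0, agg(reporter[roi$cytoplasm_mask] - background))
  nli <- if (f_nuc + f_cyto == 0) NA_real_ else {
    (f_nuc - f_cyto) / (f_nuc + f_cyto)
  }
  tibble(f_nuc = f_nuc, f_cyto = f_cyto, nli = nli,
         n_nuclear_px = sum(roi$nuclear_mask),
         n_cytoplasm_px = sum(roi$cytoplasm_mask))
}

#' Cytosolic marker intensity within an ROI
#'
#' Background-subtracted mean marker intensity over the cytoplasm
#' (cell minus nucleus), as used for cytosolic peptide accumulation.
#'
#' @inheritParams compute_nli
#' @param marker `H x W` marker-channel matrix.
#' @return A single numeric intensity (floored at 0).
#' @export
cytosolic_intensity <- function(marker, roi, background = NULL) {
  if (!any(roi$cytoplasm_mask)) {
    abort("ROI has an empty cytoplasm mask.", class = "larvasleep_invalid_roi")
  }
  if (is.null(background)) background <- median(marker[!roi$cell_mask])
  max(0, mean(marker[roi$cytoplasm_mask] - background))
}

#' Dye-based food-intake ratio
#'
#' Quantifies food intake as the ratio of dye-stained area to total body
#' area in a photograph of a dye-fed larva. The body is segmented as the
#' largest connected component darker than the background on the
#' luminance channel; stained pixels within it are identified by a
#' red-excess color rule.
#'
#' @param image `H x W x 3` RGB array (0–255), e.g. from
#'   [render_dyed_larva()].
#' @param stain_color_model List with `red_excess`: minimum value of
#'   `R - (G + B) / 2` for a pixel to count as stained.
#' @param body_intensity_model List with `max_luminance`: luminance below
#'   which a pixel belongs to the body.
#' @return A one-row tibble: `stain_px`, `body_px`, `dye_ratio` in
#'   `[0, 1]`.
#' @export
dye_intake_ratio <- function(image,
                             stain_color_model = list(red_excess = 60),
                             body_intensity_model = list(max_luminance = 240)) {
  img <- unclass(image)
  lum <- rgb_to_gray(img)
  body <- lum < body_intensity_model$max_luminance
  if (!any(body)) {
    abort("No larva body detected in the image.",
          class = "larvasleep_not_found")
  }
  labels <- EBImage::bwlabel(EBImage::Image(body * 1))
  labels <- matrix(as.integer(EBImage::imageData(labels)), nrow(lum))
  sizes <- tabulate(labels[labels > 0])
  if (length(sizes) > 1L) {
    warn("Multiple body components detected; using the largest.")
  }
  body <- labels == which.max(sizes)
  red_excess <- img[, , 1] - (img[, , 2] + img[, , 3]) / 2
  stain <- body & red_excess > stain_color_model$red_excess
  tibble(stain_px = sum(stain), body_px = sum(body),
         dye_ratio = sum(stain) / sum(body))
}

#' Pool per-cell quantification results across brains
#'
#' Cells — not brains — are the statistical unit in the translocation
#' analyses, so pooling is concatenation with provenance retained, never
#' per-brain averaging.
#'
#' @param results A list of one-row tibbles (e.g. from [compute_nli()]),
#'   or a tibble.
#' @param brain_ids Vector of brain identifiers, one per result row.
#' @return A flat per-cell tibble with `brain_id` and `cell_id` columns.
#' @export
pool_cells <- function(results, brain_ids) {
  tb <- if (is.data.frame(results)) as_tibble(results) else {
    list_rbind(map(results, as_tibble))
  }
  if (nrow(tb) == 0) {
    return(mutate(tb, brain_id = character(), cell_id = integer()))
  }
  if (length(brain_ids) != nrow(tb)) {
    abort("`brain_ids` must have one entry per result.",
          class = "larvasleep_invalid_parameter")
  }
  tb |>
    mutate(brain_id = as.character(brain_ids)) |>
    group_by(.data$brain_id) |>
    mutate(cell_id = row_number()) |>
    ungroup()
}
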