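#' Render a synthetic two-channel translocation-reporter cell image
#'
#' Stand-in for images of a translocation-based calcium reporter
#' (nucleus-accumulating GFP fusion) alongside an activity-insensitive
#' membrane reference. The reference channel labels the whole cell with a
#' brighter nucleus, enabling ROI segmentation; the reporter channel
#' distributes a fixed total signal between nucleus and cytoplasm so that
#' `mean_nuc / (mean_nuc + mean_cyto)` equals the requested nuclear
#' fraction `f`. The resulting true nuclear-localization index is
#' `2 f - 1`.
#'
#' Intensities are arbitrary fluorescence units (not 8-bit clipped), as in
#' typical 16-bit microscope output.
#'
#' @param nuclear_fraction `f` in `[0, 1]`.
#' @param geometry List: `image_size` (`c(H, W)` px), `centers` (n x 2
#'   matrix of 0-based `(row, col)` cell centres), `cell_radius`,
#'   `nucleus_radius` (px).
#' @param noise_sd Additive Gaussian noise SD on both channels.
#' @param total_signal Total reporter signal per cell (conserved across
#'   `f` when noise is off).
#' @param seed Integer seed.
#' @return A list of class `cell_image`: `reference`, `reporter` (H x W
#'   matrices) with `ground_truth()` holding `cell_masks`,
#'   `nuclear_masks` (lists of logical matrices), `nuclear_fraction`,
#'   `true_nli`, `seed`.
#' @export
render_translocation_image <- function(nuclear_fraction,
                                       geometry = cell_geometry(),
                                       noise_sd = 2, total_signal = 1.5e5,
                                       seed = 0L) {
  assert_scalar_num(nuclear_fraction, "nuclear_fraction", min = 0, max = 1)
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  H <- geometry$image_size[1]; W <- geometry$image_size[2]
  centers <- geometry$centers
  col_idx <- matrix(rep(0:(W - 1), each = H), H, W)
  row_idx <- matrix(rep(0:(H - 1), W), H, W)
  reference <- matrix(20, H, W)
  reporter <- matrix(0, H, W)
  cell_masks <- list(); nuclear_masks <- list()
  f <- nuclear_fraction
  for (i in seq_len(nrow(centers))) {
    d2 <- (row_idx - centers[i, 1])^2 + (col_idx - centers[i, 2])^2
    cell <- d2 <= geometry$cell_radius^2
    nuc <- d2 <= geometry$nucleus_radius^2
    reference[cell] <- 100
    reference[nuc] <- 180
    a_nuc <- sum(nuc); a_cyto <- sum(cell) - a_nuc
    scale <- total_signal / (f * a_nuc + (1 - f) * a_cyto)
    reporter[cell & !nuc] <- (1 - f) * scale
    reporter[nuc] <- f * scale
    cell_masks[[i]] <- cell; nuclear_masks[[i]] <- nuc
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, list(ref = rnorm(H * W, 0, noise_sd),
                                  rep = rnorm(H * W, 0, noise_sd)))
    reference <- pmax(reference + noise$ref, 0)
    reporter <- pmax(reporter + noise$rep, 0)
  }
  structure(list(reference = reference, reporter = reporter),
            ground_truth = list(cell_masks = cell_masks,
                                nuclear_masks = nuclear_masks,
                                nuclear_fraction = f,
                                true_nli = 2 * f - 1,
                                seed = as.integer(seed)),
            class = "cell_image")
}

#' Default cell geometry for the translocation renderer
#'
#' @param image_size `c(H, W)` in px.
#' @param centers n x 2 matrix of 0-based `(row, col)` centres.
#' @param cell_radius,nucleus_radius Radii in px.
#' @return A geometry list.
#' @export
cell_geometry <- function(image_size = c(96, 96),
                          centers = matrix(c(47, 47), ncol = 2),
                          cell_radius = 18, nucleus_radius = 8) {
  stopifnot(nucleus_radius < cell_radius)
  list(image_size = image_size, centers = centers,
       cell_radius = cell_radius, nucleus_radius = nucleus_radius)
}

#' Render a synthetic dye-fed larva photograph
#'
#' Stand-in for photographs from the dye-based food-intake assay: a pale
#' larva body on a white background with a contiguous red-stained gut
#' region occupying the requested fraction of the body area (stained
#' pixels are the most anterior ones along the body axis, mimicking
#' gut filling from the mouth).
#'
#' @param stain_fraction `s` in `[0, 1]`: stained area / body area.
#' @param body_geometry List: `image_size` (`c(H, W)`), `semi_axes`
#'   (`c(a, b)` px of the body ellipse).
#' @param seed Integer seed (per-pixel color jitter).
#' @return An `H x W x 3` array of class `larva_photo` (0–255 RGB) whose
#'   `ground_truth()` holds `body_mask`, `stain_mask` and
#'   `stain_fraction`.
#' @export
render_dyed_larva <- function(stain_fraction,
                              body_geometry = list(image_size = c(120, 160),
                                                   semi_axes = c(55, 18)),
                              seed = 0L) {
  assert_scalar_num(stain_fraction, "stain_fraction", min = 0, max = 1)
  H <- body_geometry$image_size[1]; W <- body_geometry$image_size[2]
  a <- body_geometry$semi_axes[1]; b <- body_geometry$semi_axes[2]
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  col_idx <- matrix(rep(0:(W - 1), each = H), H, W)
  row_idx <- matrix(rep(0:(H - 1), W), H, W)
  body <- ((col_idx - cx) / a)^2 + ((row_idx - cy) / b)^2 <= 1
  n_body <- sum(body)
  n_stain <- round(stain_fraction * n_body)
  stain <- matrix(FALSE, H, W)
  if (n_stain > 0) {
    ord <- order(col_idx[body])          # anterior = left end of the ellipse
    idx_body <- which(body)
    stain[idx_body[ord[seq_len(n_stain)]]] <- TRUE
  }
  img <- array(0, dim = c(H, W, 3))
  base <- list(bg = c(250, 250, 250), body = c(225, 205, 170),
               stain = c(190, 40, 45))
  for (ch in 1:3) {
    m <- matrix(base$bg[ch], H, W)
    m[body] <- base$body[ch]
    m[stain] <- base$stain[ch]
    img[, , ch] <- m
  }
  img <- with_seed(seed, clip8(img + rnorm(length(img), 0, 2)))
  structure(img,
            ground_truth = list(body_mask = body, stain_mask = stain,
                                stain_fraction = stain_fraction,
                                seed = as.integer(seed)),
            class = "larva_photo")
}
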