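## Inclusion-body ("spot") quantification in two-channel images:
## sliding-parabola background removal, nuclei detection with an area
## floor, texture-based spot segmentation with size / intensity /
## ring-contrast filters, nuclear vs extranuclear assignment, and
## densities per mm^2.  Images are numeric matrices normalised to [0, 1].

## 1-D morphological erosion/dilation with a parabolic structuring
## function h(d) = coef * d^2, computed along matrix columns.
.parab_pass <- function(m, coef, radius, op) {
  n <- nrow(m)
  out <- m
  for (d in seq_len(radius)) {
    pen <- coef * d^2
    up <- m[pmax(seq_len(n) - d, 1L), , drop = FALSE]
    dn <- m[pmin(seq_len(n) + d, n), , drop = FALSE]
    out <- if (op == "min") pmin(out, up + pen, dn + pen)
           else pmax(out, up - pen, dn - pen)
  }
  out
}

#' Sliding-parabola background removal
#'
#' The slowly varying background is estimated by a grayscale opening with
#' a parabolic structuring function (a "sliding parabola" rolling under
#' the image) and subtracted; output is clipped at zero.  The parabola is
#' separable, so the opening is two 1-D erosions (rows, columns) followed
#' by two 1-D dilations.
#'
#' The `curvature` setting is defined on raw camera counts; since this
#' package normalises images to `[0, 1]`, the parabola height is scaled
#' by `intensity_scale` so that the default `curvature = 6` behaves like
#' 6 counts-per-px^2 on a 16-bit camera regardless of normalisation
#' (effective half-width about 148 px).
#'
#' @param image 2-D numeric matrix (normalised intensities).
#' @param curvature parabola second derivative, counts per px^2 on the
#'   `intensity_scale`; default 6.
#' @param intensity_scale full-scale count the curvature refers to
#'   (default 65535).
#' @return background-subtracted image, nonnegative, same shape.
#' @export
remove_background <- function(image, curvature = 6, intensity_scale = 65535) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  stopifnot(curvature > 0)
  coef <- 0.5 * curvature / intensity_scale
  rng <- diff(range(image))
  if (rng == 0) return(image * 0)
  radius <- ceiling(sqrt(rng / coef))
  er <- t(.parab_pass(t(.parab_pass(image, coef, radius, "min")),
                      coef, radius, "min"))
  bg <- t(.parab_pass(t(.parab_pass(er, coef, radius, "max")),
                      coef, radius, "max"))
  pmax(image - bg, 0)
}

#' Detect nuclei in a background-removed DAPI image
#'
#' Otsu threshold, 8-connected components, hole filling, and an area
#' floor: components smaller than `min_area` pixels are discarded.
#'
#' @param dapi background-removed DAPI channel.
#' @param min_area minimum nucleus area in pixels (default 200).
#' @return integer label matrix (0 = background) with attribute `"n"`.
#' @export
detect_nuclei <- function(dapi, min_area = 200) {
  stopifnot(is.matrix(dapi))
  if (diff(range(dapi)) == 0) {
    out <- matrix(0L, nrow(dapi), ncol(dapi)); attr(out, "n") <- 0L
    return(out)
  }
  mask <- dapi > otsu_threshold(dapi)
  mask <- fill_holes(mask)
  lab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L], attr(lab, "n"))
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab %in% keep] <- match(lab[lab %in% keep], keep)
  attr(out, "n") <- length(keep)
  out
}

#' Spot-enhancing texture filter
#'
#' A normalised centre-surround (difference-of-Gaussians) operator tuned
#' to blobs of roughly `scale_px` width, standing in for a proprietary
#' spot-texture filter: the response is the blur at `scale_px` minus the
#' blur at `2 * scale_px`, negatives clipped, and divided by 0.3 — the
#' closed-form peak response of this operator to a unit-amplitude
#' Gaussian spot of sigma `scale_px` — so a spot of amplitude `a` on a
#' `[0, 1]`-normalised image scores about `a` and the 0.2 segmentation
#' threshold is meaningful.
#'
#' @param spot_channel 2-D numeric matrix.
#' @param scale_px texture scale in pixels (>= 1; default 3).
#' @return texture response image, nonnegative.
#' @export
spot_texture <- function(spot_channel, scale_px = 3) {
  if (!is.matrix(spot_channel)) stop("image must be a 2-D matrix")
  if (scale_px < 1) stop("scale_px must be >= 1")
  resp <- gaussian_blur(spot_channel, scale_px) -
          gaussian_blur(spot_channel, 2 * scale_px)
  ## peak response to a unit Gaussian spot of sigma s:
  ## s^2/(s^2+s^2) - s^2/(s^2+(2s)^2) = 1/2 - 1/5 = 0.3, for any s
  pmax(resp, 0) / 0.3
}

## mean intensity of a 4-connected ring of width `w` around a component,
## excluding every candidate spot pixel
.ring_mean <- function(intensity, spot_px, all_spots_mask, w) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  rows <- ((spot_px - 1L) %% nr) + 1L
  cols <- ((spot_px - 1L) %/% nr) + 1L
  r0 <- max(1L, min(rows) - w); r1 <- min(nr, max(rows) + w)
  c0 <- max(1L, min(cols) - w); c1 <- min(nc, max(cols) + w)
  sub_rows <- r0:r1; sub_cols <- c0:c1
  ## distance from every pixel in the bounding box to the spot pixel set
  grid <- expand.grid(r = sub_rows, c = sub_cols)
  d2 <- outer(grid$r, rows, "-")^2 + outer(grid$c, cols, "-")^2
  mind <- sqrt(apply(d2, 1L, min))
  ring <- mind > 0 & mind <= w
  lin <- (grid$c - 1L) * nr + grid$r
  ring <- ring & !all_spots_mask[lin]
  if (!any(ring)) return(NA_real_)
  mean(intensity[lin[ring]])
}

#' Segment aggregate spots with the scripted filter cascade
#'
#' Candidate spots are 8-connected components of the texture response
#' above `texture_cut`.  Survivors must have (i) area of at least
#' `min_area` px, (ii) mean intensity of at least `intensity_factor`
#' times the global mean of the unfiltered spot channel, and (iii) mean
#' intensity at least `ring_factor`-fold that of the surrounding
#' `ring_width`-px-wide ring (other candidate spots excluded from the
#' ring).  Each survivor is flagged nuclear iff its centroid lies inside
#' the nuclei mask.
#'
#' @param spot_channel unfiltered spot channel, `[0, 1]` matrix.
#' @param nuclei label (or logical) matrix from [detect_nuclei()]; may be
#'   `NULL`, in which case every spot is extranuclear.
#' @param texture_cut threshold on the [spot_texture()] response
#'   (default 0.2).
#' @param min_area minimum spot area in px (default 5).
#' @param intensity_factor multiple of the global mean intensity
#'   (default 2).
#' @param ring_factor minimum spot/ring intensity ratio (default 1.3).
#' @param ring_width ring width in px (default 4).
#' @param scale_px texture scale (default 3).
#' @return data frame of spot records: `spot_id`, `row`, `col`
#'   (centroid), `area_px`, `mean_intensity`, `ring_contrast`,
#'   `is_nuclear`.  Zero rows when nothing passes.
#' @export
segment_spots <- function(spot_channel, nuclei = NULL,
                          texture_cut = 0.2, min_area = 5,
                          intensity_factor = 2, ring_factor = 1.3,
                          ring_width = 4, scale_px = 3) {
  stopifnot(is.matrix(spot_channel))
  tex <- spot_texture(spot_channel, scale_px)
  cand <- label_components(tex > texture_cut, connectivity = 8)
  n_cand <- attr(cand, "n")
  empty <- data.frame(spot_id = integer(), row = numeric(), col = numeric(),
                      area_px = integer(), mean_intensity = numeric(),
                      ring_contrast = numeric(), is_nuclear = logical())
  if (n_cand == 0L) return(empty)
  global_mean <- mean(spot_channel)
  all_mask <- cand > 0L
  nr <- nrow(spot_channel)
  recs <- lapply(seq_len(n_cand), function(lb) {
    px <- which(cand == lb)
    if (length(px) < min_area) return(NULL)
    mi <- mean(spot_channel[px])
    if (mi < intensity_factor * global_mean) return(NULL)
    ring <- .ring_mean(spot_channel, px, all_mask, ring_width)
    contrast <- if (is.na(ring) || ring <= 0) Inf else mi / ring
    if (contrast < ring_factor) return(NULL)
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    data.frame(row = mean(rows), col = mean(cols),
               area_px = length(px), mean_intensity = mi,
               ring_contrast = contrast)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs) || nrow(recs) == 0L) return(empty)
  if (is.null(nuclei)) {
    recs$is_nuclear <- FALSE
  } else {
    nm <- if (is.logical(nuclei)) nuclei else nuclei > 0L
    recs$is_nuclear <- nm[cbind(round(recs$row), round(recs$col))]
  }
  cbind(spot_id = seq_len(nrow(recs)), recs)
}

#' Spot densities per square millimetre
#'
#' @param spots data frame from [segment_spots()].
#' @param region_mask logical matrix of the analysed region (e.g. the
#'   imaged tissue field); its area must be positive.
#' @param pixel_size_um physical pixel size in micrometres (default
#'   0.32).
#' @return list: `n_nuclear`, `n_extranuclear`, `region_area_mm2`,
#'   `nuclear_per_mm2`, `extranuclear_per_mm2`.
#' @export
spot_density <- function(spots, region_mask, pixel_size_um = 0.32) {
  stopifnot(is.matrix(region_mask), pixel_size_um > 0)
  area_px <- sum(region_mask != 0)
  if (area_px == 0) stop("region has zero area")
  area_mm2 <- area_px * (pixel_size_um * 1e-3)^2
  n_nuc <- sum(spots$is_nuclear)
  n_ext <- sum(!spots$is_nuclear)
  list(n_nuclear = n_nuc, n_extranuclear = n_ext,
       region_area_mm2 = area_mm2,
       nuclear_per_mm2 = n_nuc / area_mm2,
       extranuclear_per_mm2 = n_ext / area_mm2)
}
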