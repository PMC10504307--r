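#' ETDRS grid definition
#'
#' The standard circular grid used for local vessel density: a central disc
#' of 1 mm diameter (fovea region) and an annulus out to 3 mm diameter split
#' into superior, inferior, temporal and nasal quadrants along the +-45
#' degree diagonals. Laterality decides which horizontal side is nasal: for
#' a right eye (OD) the nasal side is toward larger column indices, mirrored
#' for OS.
#'
#' @param center `(row, col)` 0-based grid centre in pixels.
#' @param px_per_mm positive scale.
#' @param inner_diameter_mm,outer_diameter_mm grid diameters (inner < outer).
#' @param laterality `"OD"` or `"OS"`.
#' @return An object of class `etdrs_grid`.
#' @export
etdrs_grid <- function(center, px_per_mm, inner_diameter_mm = 1,
                       outer_diameter_mm = 3, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (px_per_mm <= 0) stop("px_per_mm must be positive")
  if (inner_diameter_mm <= 0 || outer_diameter_mm <= inner_diameter_mm)
    stop("need 0 < inner_diameter_mm < outer_diameter_mm")
  structure(list(center = as.numeric(center), px_per_mm = px_per_mm,
                 inner_diameter_mm = inner_diameter_mm,
                 outer_diameter_mm = outer_diameter_mm,
                 laterality = laterality),
            class = "etdrs_grid")
}

etdrs_region_names <- c("fovea", "superior", "temporal", "nasal", "inferior")

#' Binary region masks of the ETDRS grid
#'
#' Pixel membership: the fovea region is `d <= inner radius`; annulus pixels
#' (`inner < d <= outer`, the outer circle included) belong to the quadrant
#' of their angle, with "superior" toward smaller row indices (image up) and
#' pixels exactly on a diagonal assigned to the quadrant that comes earlier
#' counter-clockwise. Quadrants crossing the image border are clipped and
#' flagged.
#'
#' @param grid an [etdrs_grid()].
#' @param shape image size `(H, W)`.
#' @return Named list of five binary matrices (`fovea`, `superior`,
#'   `temporal`, `nasal`, `inferior`) of class `etdrs_region_masks`, with a
#'   `"clipped"` attribute.
#' @export
etdrs_region_masks <- function(grid, shape) {
  stopifnot(inherits(grid, "etdrs_grid"), length(shape) >= 2)
  H <- shape[1]; W <- shape[2]
  rin <- grid$inner_diameter_mm / 2 * grid$px_per_mm
  rout <- grid$outer_diameter_mm / 2 * grid$px_per_mm
  rr <- matrix(0:(H - 1), H, W) - grid$center[1]
  cc <- matrix(0:(W - 1), H, W, byrow = TRUE) - grid$center[2]
  d <- sqrt(rr^2 + cc^2)
  # angle measured counter-clockwise in the displayed image, 0 = image right
  th <- atan2(-rr, cc) * 180 / pi
  fovea <- d <= rin
  ann <- d > rin & d <= rout
  # half-open (a, a+90]: a pixel exactly on a diagonal falls in the quadrant
  # counter-clockwise-earlier than the boundary
  right <- ann & th > -45 & th <= 45
  superior <- ann & th > 45 & th <= 135
  left <- ann & (th > 135 | th <= -135)
  inferior <- ann & th > -135 & th <= -45
  if (grid$laterality == "OD") { nasal <- right; temporal <- left }
  else { nasal <- left; temporal <- right }
  out <- lapply(list(fovea = fovea, superior = superior, temporal = temporal,
                     nasal = nasal, inferior = inferior),
                function(m) matrix(as.numeric(m), H, W))
  clipped <- grid$center[1] - rout < 0 || grid$center[2] - rout < 0 ||
    grid$center[1] + rout > H - 1 || grid$center[2] + rout > W - 1
  structure(out, class = "etdrs_region_masks", clipped = clipped)
}

#' Vessel density over the ETDRS regions
#'
#' Per region, the percentage of pixels classified as vessel:
#' `100 * sum(mask & region) / sum(region)`. Empty regions are reported as
#' `NA` with a warning.
#'
#' @param mask binary vessel mask (matrix or `vessel_mask`).
#' @param regions an [etdrs_region_masks()] result of the same shape.
#' @param image_id optional identifier recorded in the report.
#' @return Data frame of class `density_report` with columns `image_id`,
#'   `region`, `density` (percent) and `n_pixels`.
#' @export
vessel_density <- function(mask, regions, image_id = NA_character_) {
  stopifnot(inherits(regions, "etdrs_region_masks"))
  m <- unclass(mask)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  if (!identical(dim(m), dim(regions[[1]])))
    stop("mask and region masks must share shape")
  rows <- lapply(names(regions), function(nm) {
    reg <- regions[[nm]]
    npx <- sum(reg)
    if (npx == 0) {
      warning("region '", nm, "' is empty; density undefined")
      dens <- NA_real_
    } else dens <- 100 * sum(m * reg) / npx
    data.frame(image_id = image_id, region = nm, density = dens,
               n_pixels = npx, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("density_report", class(out))
  out
}
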