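#' Retinal phantom specification
#'
#' Parameters of the procedural retinal phantom: a stochastic branching vessel
#' tree rooted at the optic disc, rendered twice — dark-on-bright in a warm
#' fundus-like raster and bright-on-dark with speckle in an OCT-A-like raster
#' — together with a noiseless binary vessel mask. The OCT-A rendering can be
#' rigidly misaligned relative to the fundus frame to exercise the alignment
#' machinery.
#'
#' @param image_size square image side in pixels.
#' @param px_per_mm pixels per millimetre.
#' @param disc_center,fovea_center `(row, col)` 0-based pixel coordinates;
#'   defaults place the disc temporally and the fovea at the image centre.
#' @param disc_radius_mm,faz_radius_mm optic-disc and foveal-avascular-zone
#'   radii in mm.
#' @param n_root_vessels number of vessel trunks leaving the disc.
#' @param root_radius_px trunk radius in pixels (vessels are drawn with width
#'   `2 * radius`).
#' @param branch_prob probability that a segment bifurcates.
#' @param branch_angle_deg mean half-angle between daughter branches.
#' @param angle_jitter_deg SD of the direction jitter per segment.
#' @param seg_len_mm segment step length in mm.
#' @param radius_decay multiplicative radius factor per branching generation,
#'   in (0, 1).
#' @param min_radius_px radius below which growth terminates (at least 1).
#' @param max_segments hard cap on total segments.
#' @param fundus_noise_sd additive Gaussian noise SD (8-bit scale) for the
#'   fundus rendering.
#' @param octa_speckle_sd SD of the multiplicative log-intensity speckle for
#'   the OCT-A rendering.
#' @param misalignment [similarity_transform()] applied to the OCT-A/mask
#'   renderings relative to the fundus frame.
#' @param laterality `"OD"` or `"OS"`.
#' @param seed RNG seed controlling tree growth and noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512, px_per_mm = 100,
                         disc_center = NULL, fovea_center = NULL,
                         disc_radius_mm = 0.55, faz_radius_mm = 0.25,
                         n_root_vessels = 6, root_radius_px = NULL,
                         branch_prob = 0.25, branch_angle_deg = 35,
                         angle_jitter_deg = 10, seg_len_mm = 0.3,
                         radius_decay = 0.8, min_radius_px = 1,
                         max_segments = 4000,
                         fundus_noise_sd = 6, octa_speckle_sd = 0.25,
                         misalignment = similarity_transform(),
                         laterality = "OD", seed = 1L) {
  if (is.null(fovea_center))
    fovea_center <- c((image_size - 1) / 2, (image_size - 1) / 2)
  if (is.null(disc_center))
    disc_center <- c((image_size - 1) / 2, round(image_size * 0.82))
  if (is.null(root_radius_px)) root_radius_px <- max(2, image_size / 130)
  if (n_root_vessels < 1) stop("n_root_vessels must be at least 1")
  if (radius_decay <= 0 || radius_decay >= 1)
    stop("radius_decay must lie strictly inside (0, 1)")
  if (min_radius_px < 1) stop("min_radius_px must be at least 1")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0, 1]")
  inside <- function(p) all(p >= 0) && all(p <= image_size - 1)
  if (!inside(disc_center) || !inside(fovea_center))
    stop("disc and fovea centers must lie inside the image")
  if (!laterality %in% c("OD", "OS")) stop("laterality must be OD or OS")
  structure(list(image_size = as.integer(image_size), px_per_mm = px_per_mm,
                 disc_center = disc_center, fovea_center = fovea_center,
                 disc_radius_mm = disc_radius_mm, faz_radius_mm = faz_radius_mm,
                 n_root_vessels = as.integer(n_root_vessels),
                 root_radius_px = root_radius_px, branch_prob = branch_prob,
                 branch_angle_deg = branch_angle_deg,
                 angle_jitter_deg = angle_jitter_deg, seg_len_mm = seg_len_mm,
                 radius_decay = radius_decay, min_radius_px = min_radius_px,
                 max_segments = as.integer(max_segments),
                 fundus_noise_sd = fundus_noise_sd,
                 octa_speckle_sd = octa_speckle_sd,
                 misalignment = misalignment, laterality = laterality,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Grow a stochastic branching vessel tree
#'
#' Trunks leave the optic disc rim at roughly evenly spaced angles and grow
#' outward in fixed-length segments with jittered headings. Each segment
#' bifurcates with probability `branch_prob`, daughters inheriting the radius
#' scaled by `radius_decay` and one higher generation. Growth stops when a
#' segment would leave the image, enter the foveal avascular zone, or when the
#' radius drops below `min_radius_px`. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return An object of class `vessel_tree`: a data frame of segments with
#'   columns `r0, c0, r1, c1, radius, generation, root`.
#' @export
grow_vessel_tree <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, grow_vessel_tree_impl(spec))
}

grow_vessel_tree_impl <- function(spec) {
  S <- spec$image_size
  len <- spec$seg_len_mm * spec$px_per_mm
  disc_r <- spec$disc_radius_mm * spec$px_per_mm
  faz_r <- spec$faz_radius_mm * spec$px_per_mm
  fov <- spec$fovea_center
  in_faz <- function(p) sum((p - fov)^2) < faz_r^2
  in_img <- function(p) all(p >= 0) && all(p <= S - 1)

  base <- seq(0, 360, length.out = spec$n_root_vessels + 1)[-1]
  segs <- vector("list", spec$max_segments)
  nseg <- 0L
  # active front: list of (point, heading_deg, radius, generation, root)
  front <- lapply(seq_len(spec$n_root_vessels), function(i) {
    a <- base[i] + runif(1, -15, 15)
    u <- c(sin(a * pi / 180), cos(a * pi / 180))    # (row, col) unit
    list(p = spec$disc_center + disc_r * u, a = a,
         r = spec$root_radius_px, g = 0L, root = i)
  })
  front <- Filter(function(b) in_img(b$p) && !in_faz(b$p), front)

  while (length(front) > 0 && nseg < spec$max_segments) {
    b <- front[[1]]; front <- front[-1]
    a <- b$a + rnorm(1, 0, spec$angle_jitter_deg)
    q <- b$p + len * c(sin(a * pi / 180), cos(a * pi / 180))
    if (!in_img(q) || in_faz(q)) next
    nseg <- nseg + 1L
    segs[[nseg]] <- c(b$p, q, b$r, b$g, b$root)
    if (runif(1) < spec$branch_prob) {
      rc <- b$r * spec$radius_decay
      if (rc >= spec$min_radius_px) {
        half <- spec$branch_angle_deg
        for (s in c(-1, 1)) {
          front[[length(front) + 1L]] <-
            list(p = q, a = a + s * (half + rnorm(1, 0, spec$angle_jitter_deg)),
                 r = rc, g = b$g + 1L, root = b$root)
        }
      }
    } else {
      front[[length(front) + 1L]] <- list(p = q, a = a, r = b$r, g = b$g,
                                          root = b$root)
    }
  }
  m <- if (nseg > 0) do.call(rbind, segs[seq_len(nseg)]) else
    matrix(numeric(0), 0, 7)
  tree <- as.data.frame(m)
  names(tree) <- c("r0", "c0", "r1", "c1", "radius", "generation", "root")
  class(tree) <- c("vessel_tree", class(tree))
  attr(tree, "spec") <- spec
  tree
}

# Anti-aliased coverage of the tree: per pixel, clamp(radius + .5 - d, 0, 1)
# maximized over segments, where d is the distance to the segment axis.
# Vessels therefore have drawn width 2 * radius.
rasterize_tree <- function(tree, size) {
  cov <- matrix(0, size, size)
  if (nrow(tree) == 0) return(cov)
  for (i in seq_len(nrow(tree))) {
    r0 <- tree$r0[i]; c0 <- tree$c0[i]; r1 <- tree$r1[i]; c1 <- tree$c1[i]
    rad <- tree$radius[i]
    pad <- ceiling(rad + 1)
    rlo <- max(0, floor(min(r0, r1)) - pad); rhi <- min(size - 1, ceiling(max(r0, r1)) + pad)
    clo <- max(0, floor(min(c0, c1)) - pad); chi <- min(size - 1, ceiling(max(c0, c1)) + pad)
    if (rhi < rlo || chi < clo) next
    rr <- rlo:rhi; cc <- clo:chi
    dr <- r1 - r0; dc <- c1 - c0
    L2 <- dr * dr + dc * dc
    PR <- matrix(rr, length(rr), length(cc))
    PC <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    if (L2 == 0) {
      d <- sqrt((PR - r0)^2 + (PC - c0)^2)
    } else {
      t <- pmin(1, pmax(0, ((PR - r0) * dr + (PC - c0) * dc) / L2))
      d <- sqrt((PR - (r0 + t * dr))^2 + (PC - (c0 + t * dc))^2)
    }
    a <- pmin(1, pmax(0, rad + 0.5 - d))
    blk <- cov[rr + 1, cc + 1]
    cov[rr + 1, cc + 1] <- pmax(blk, a)
  }
  cov
}

# squared distance grid from a centre (0-based coords)
dist2_grid <- function(size, center) {
  rr <- matrix(0:(size - 1), size, size)
  cc <- matrix(0:(size - 1), size, size, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2
}

#' Render a phantom fundus / OCT-A / mask triplet
#'
#' The fundus rendering is a bright warm background with a darker macula, a
#' disc with dark rim and bright core, and the vessel tree drawn dark with
#' additive Gaussian noise. The OCT-A rendering is dark background with
#' bright vessels, an empty foveal avascular zone and multiplicative speckle.
#' The vessel mask is the noiseless anti-aliased rasterization thresholded at
#' 0.5. OCT-A and mask are warped by `spec$misalignment` out of the fundus
#' frame; `true_transform` is the inverse transform, i.e. the one that brings
#' them back into register with the fundus.
#'
#' @param tree a [grow_vessel_tree()] result.
#' @param spec the matching [phantom_spec()].
#' @return An object of class `phantom_pair` with elements `fundus`, `octa`,
#'   `vessel_mask` (all [retinal_image()]s, 8-bit for fundus/octa, 0/1 for the
#'   mask), `spec` and `true_transform`.
#' @export
render_phantom_pair <- function(tree, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  S <- spec$image_size
  cov <- rasterize_tree(tree, S)
  faz_r <- spec$faz_radius_mm * spec$px_per_mm
  d2_fov <- dist2_grid(S, spec$fovea_center)
  d2_disc <- dist2_grid(S, spec$disc_center)
  cov[d2_fov < faz_r^2] <- 0

  # ---- fundus (fundus frame) -------------------------------------------
  disc_r <- spec$disc_radius_mm * spec$px_per_mm
  mac_r <- 3 * faz_r
  base <- c(205, 125, 60)                     # warm background
  shade <- matrix(1, S, S)
  shade <- shade - 0.30 * pmax(0, 1 - d2_fov / mac_r^2)      # darker macula
  rim <- d2_disc >= (0.7 * disc_r)^2 & d2_disc < disc_r^2
  core <- d2_disc < (0.7 * disc_r)^2
  fundus <- array(0, c(S, S, 3))
  vessel_col <- c(70, 25, 20)
  for (ch in 1:3) {
    plane <- base[ch] * shade
    plane[rim] <- plane[rim] * 0.72
    plane[core] <- pmin(255, plane[core] * 1.25 + 25)
    plane <- plane * (1 - 0.85 * cov) + vessel_col[ch] * 0.85 * cov
    fundus[, , ch] <- plane
  }

  # ---- OCT-A + mask (rendered in fundus frame, then misaligned) --------
  if (is_identity_transform(spec$misalignment)) {
    cov_n <- cov
  } else {
    ci <- retinal_image(cov, modality = "synthetic_octa",
                        px_per_mm = spec$px_per_mm, frame = "octa_native")
    cov_n <- apply_similarity_transform(ci, spec$misalignment)$pixels[, , 1]
  }
  mask <- (cov_n > 0.5) * 1
  octa <- 25 + 195 * cov_n

  # ---- noise, after integer rasterization of the clean signal ----------
  with_seed(spec$seed + 1L, {
    fundus <- round(fundus) + array(rnorm(S * S * 3, 0, spec$fundus_noise_sd),
                                    c(S, S, 3))
    octa <- round(octa) * exp(matrix(rnorm(S * S, 0, spec$octa_speckle_sd),
                                     S, S))
  })
  fundus <- round(pmin(pmax(fundus, 0), 255))
  octa <- round(pmin(pmax(octa, 0), 255))

  structure(list(
    fundus = retinal_image(fundus, "fundus", spec$px_per_mm, "fundus_frame"),
    octa = retinal_image(octa, "octa", spec$px_per_mm, "octa_native"),
    vessel_mask = retinal_image(mask, "mask", spec$px_per_mm, "octa_native"),
    spec = spec,
    true_transform = invert_transform(spec$misalignment)),
    class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %dx%d px, %g px/mm, %d vessel px\n",
              x$spec$image_size, x$spec$image_size, x$spec$px_per_mm,
              sum(x$vessel_mask$pixels)))
  invisible(x)
}

#' Generate a phantom cohort on disk
#'
#' Draws per-subject variations of a template spec (distinct seeds, jittered
#' vessel counts, branching probabilities and centres), renders each subject's
#' triplet, writes PNGs and a JSON manifest. Subject identifiers allow
#' patient-level splitting downstream.
#'
#' @param out_dir output directory (created if needed).
#' @param n_subjects number of subjects (at least 1).
#' @param seed cohort seed; per-subject seeds are drawn without replacement
#'   from this stream, so they are all distinct.
#' @param template template [phantom_spec()] to jitter.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
generate_phantom_dataset <- function(out_dir, n_subjects, seed = 1L,
                                     template = phantom_spec()) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  subj_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                           n_subjects))
  jit <- with_seed(seed + 1L, list(
    n_root = sample(-1:1, n_subjects, replace = TRUE),
    bp = runif(n_subjects, -0.05, 0.05),
    dc = matrix(runif(2 * n_subjects, -0.02, 0.02), n_subjects, 2)))
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sp <- template
    sp$seed <- subj_seeds[i]
    sp$n_root_vessels <- max(1L, template$n_root_vessels + jit$n_root[i])
    sp$branch_prob <- min(1, max(0, template$branch_prob + jit$bp[i]))
    sp$disc_center <- pmin(template$image_size - 1,
                           pmax(0, template$disc_center +
                                  jit$dc[i, ] * template$image_size))
    pair <- render_phantom_pair(grow_vessel_tree(sp), sp)
    id <- sprintf("subj%03d", i)
    paths <- c(fundus = file.path(id, "fundus.png"),
               octa = file.path(id, "octa.png"),
               mask = file.path(id, "mask.png"))
    dir.create(file.path(out_dir, id), showWarnings = FALSE)
    png::writePNG(aperm(pair$fundus$pixels / 255, c(1, 2, 3)),
                  file.path(out_dir, paths["fundus"]))
    png::writePNG(pair$octa$pixels[, , 1] / 255,
                  file.path(out_dir, paths["octa"]))
    png::writePNG(pair$vessel_mask$pixels[, , 1],
                  file.path(out_dir, paths["mask"]))
    tt <- pair$true_transform
    subjects[[i]] <- list(
      id = id, seed = subj_seeds[i], laterality = sp$laterality,
      px_per_mm = sp$px_per_mm, image_size = sp$image_size,
      disc_center = sp$disc_center, fovea_center = sp$fovea_center,
      files = as.list(paths),
      true_transform = list(scale = tt$scale, rotation_deg = tt$rotation_deg,
                            tx = tt$tx, ty = tt$ty))
  }
  manifest <- list(kind = "octasyn_phantom_manifest", seed = seed,
                   n_subjects = n_subjects, subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a phantom cohort from disk
#'
#' @param dir directory holding `manifest.json` as written by
#'   [generate_phantom_dataset()].
#' @return List with `manifest` and per-subject loaded images (`fundus`,
#'   `octa`, `mask` as [retinal_image()]s, plus `true_transform`).
#' @export
load_phantom_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  subjects <- lapply(manifest$subjects, function(s) {
    fundus <- png::readPNG(file.path(dir, s$files$fundus)) * 255
    octa <- png::readPNG(file.path(dir, s$files$octa)) * 255
    mask <- png::readPNG(file.path(dir, s$files$mask))
    tt <- s$true_transform
    list(id = s$id, laterality = s$laterality, px_per_mm = s$px_per_mm,
         disc_center = unlist(s$disc_center),
         fovea_center = unlist(s$fovea_center),
         fundus = retinal_image(round(fundus), "fundus", s$px_per_mm,
                                "fundus_frame"),
         octa = retinal_image(round(octa), "octa", s$px_per_mm, "octa_native"),
         mask = retinal_image(round(mask), "mask", s$px_per_mm, "octa_native"),
         true_transform = similarity_transform(tt$scale, tt$rotation_deg,
                                               tt$tx, tt$ty))
  })
  names(subjects) <- vapply(subjects, `[[`, "", "id")
  list(manifest = manifest, subjects = subjects)
}
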