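#' Read a pipeline configuration
#'
#' Nested YAML with sections `phantom`, `train`, `stitch`, `binarize`,
#' `etdrs` and a global `seed`; unknown sections are rejected. Missing
#' sections fall back to the packaged defaults
#' (`inst/extdata/defaults.yaml`), which carry the full-scale recipe
#' (reconstruction weight 100, Adam 2e-4/1e-3, stride 8, 512-px patches,
#' 3 mm / 1 mm ETDRS grid).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "defaults.yaml",
                                          package = "octasyn"))
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), c(names(defaults), "out_dir"))
    if (length(unknown) > 0)
      stop("unknown config sections: ", paste(unknown, collapse = ", "))
    for (nm in names(user)) {
      cfg[[nm]] <- if (is.list(defaults[[nm]]))
        modifyList(defaults[[nm]], user[[nm]]) else user[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage seed fan-out (Knuth multiplicative hash, kept
# inside the 32-bit signed range)
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("phantom", "train", "synthesize", "binarize",
                        "density", "evaluate"))
  as.integer((as.numeric(seed) * 2654435761 + idx * 97) %% 2147483647)
}

#' Run the full phantom pipeline
#'
#' Executes the stages in order — phantom generation, patient-level split,
#' model training, full-field synthesis for the test subjects, vessel
#' binarization, ETDRS densities and evaluation — each stage consuming the
#' previous stage's outputs, and writes a run summary JSON with seeds and
#' per-stage wall times.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @param out_dir output root.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a list with the fitted model, the evaluation tables
#'   and the summary.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  if (is.character(config)) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  times <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    times[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
    res
  }
  ph <- config$phantom
  seed <- config$seed

  say("[1/6] phantom cohort (%d subjects)", ph$n_subjects)
  phantom_dir <- file.path(out_dir, "phantoms")
  template <- phantom_spec(image_size = ph$image_size,
                           px_per_mm = ph$px_per_mm,
                           n_root_vessels = ph$n_root_vessels,
                           branch_prob = ph$branch_prob)
  clock("phantom",
        generate_phantom_dataset(phantom_dir, ph$n_subjects,
                                 seed = stage_seed(seed, "phantom"),
                                 template = template))
  ds <- load_phantom_dataset(phantom_dir)
  ids <- names(ds$subjects)
  n_tr <- config$split$n_train; n_va <- config$split$n_val
  split <- subject_split(ids[seq_len(n_tr)],
                         ids[n_tr + seq_len(n_va)],
                         ids[-seq_len(n_tr + n_va)])

  say("[2/6] training (%s, %d epochs)", config$train$mode,
      config$train$epochs)
  tc <- phantom_train_config(mode = config$train$mode,
                             epochs = config$train$epochs,
                             seed = stage_seed(seed, "train"),
                             lambda = config$train$lambda)
  tc$patch_px <- config$train$patch_px
  fit <- clock("train", fit_octa_cgan(ds$subjects, split, tc,
                                      verbose = verbose))
  write.csv(fit$history, file.path(out_dir, "training_history.csv"),
            row.names = FALSE)

  say("[3/6] full-field synthesis on %d test subjects",
      length(split$test_ids))
  scfg <- stitch_config(patch_px = tc$patch_px,
                        stride_px = config$stitch$stride_px)
  syn_dir <- file.path(out_dir, "synthetic")
  dir.create(syn_dir, showWarnings = FALSE)
  test_subjects <- ds$subjects[split$test_ids]
  syn <- clock("synthesize", lapply(test_subjects, function(s) {
    bg <- compute_background_mask(s$fundus)
    img <- synthesize_full(s$fundus, bg, fit, scfg)
    png::writePNG(denormalize_intensity(img)$pixels[, , 1] / 255,
                  file.path(syn_dir, paste0(s$id, ".png")))
    img
  }))

  say("[4/6] vessel binarization")
  bcfg <- binarizer_config(scales = config$binarize$scales,
                           threshold = config$binarize$threshold,
                           min_object_px = config$binarize$min_object_px)
  masks <- clock("binarize", lapply(syn, function(img)
    binarize_vessels(vessel_probability(img, bcfg), bcfg)))

  say("[5/6] ETDRS vessel densities")
  densities <- clock("density", {
    rows <- mapply(function(s, m) {
      grid <- etdrs_grid(s$fovea_center, s$px_per_mm,
                         inner_diameter_mm = config$etdrs$inner_diameter_mm,
                         outer_diameter_mm = config$etdrs$outer_diameter_mm,
                         laterality = s$laterality)
      regions <- etdrs_region_masks(grid, dim(m))
      truth <- aligned_pairs(list(s), "mask")[[1]]$y
      rbind(cbind(vessel_density(m, regions, s$id), source = "synthetic"),
            cbind(vessel_density(truth[, , 1], regions, s$id),
                  source = "truth"))
    }, test_subjects, masks, SIMPLIFY = FALSE)
    do.call(rbind, rows)
  })
  write.csv(densities, file.path(out_dir, "densities.csv"),
            row.names = FALSE)

  say("[6/6] evaluation")
  evalres <- clock("evaluate", {
    ref <- densities[densities$source == "truth", ]
    cand <- densities[densities$source == "synthetic", ]
    corr <- density_correlations(ref, cand)
    scores <- lapply(syn, function(im) (im$pixels[, , 1] + 1) / 2)
    labels <- lapply(test_subjects, function(s)
      aligned_pairs(list(s), "mask")[[1]]$y[, , 1])
    pr <- pr_curve(scores, labels)
    sm <- synthesis_metrics(
      lapply(syn, function(im) denormalize_intensity(im)$pixels[, , 1]),
      lapply(test_subjects, function(s)
        aligned_pairs(list(s), "octa")[[1]]$y[, , 1]),
      ids = names(syn))
    list(correlations = corr, pr = pr, synthesis = sm)
  })
  write.csv(evalres$correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(evalres$pr$curve, file.path(out_dir, "pr_curve.csv"),
            row.names = FALSE)

  summary <- list(seed = seed, stages = names(times),
                  wall_time_s = times,
                  best_epoch = fit$best_epoch,
                  pr_auc = evalres$pr$auc,
                  pr_prevalence = evalres$pr$prevalence)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, synthetic = syn, masks = masks,
                 densities = densities, evaluation = evalres,
                 summary = summary))
}

#' Validate a dataset manifest
#'
#' Structural and referential checks: unique subject ids, all referenced
#' image files present, transforms well-formed.
#'
#' @param path path to a `manifest.json`.
#' @return List with `valid` (logical) and `problems` (character vector).
#' @export
validate_manifest <- function(path) {
  problems <- character(0)
  if (!file.exists(path)) return(list(valid = FALSE,
                                      problems = paste("missing file:", path)))
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  root <- dirname(path)
  if (is.null(m$subjects)) problems <- c(problems, "no subjects entry")
  ids <- vapply(m$subjects, function(s) s$id %||% NA_character_, "")
  if (anyDuplicated(ids))
    problems <- c(problems, paste("duplicate subject id:",
                                  paste(unique(ids[duplicated(ids)]),
                                        collapse = ", ")))
  for (s in m$subjects) {
    for (f in unlist(s$files)) {
      if (!file.exists(file.path(root, f)))
        problems <- c(problems, paste0(s$id, ": missing image file ", f))
    }
    tt <- s$true_transform
    if (is.null(tt$scale) || tt$scale <= 0)
      problems <- c(problems, paste0(s$id, ": invalid transform scale"))
  }
  list(valid = length(problems) == 0, problems = problems)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
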