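#!/usr/bin/env Rscript
# Command-line driver for the epifat pipeline.
#
#   efseg segment  --input vol.nii.gz --seed-slice S --seed-row R --seed-col C
#                  [--controls controls.csv] [--weight kg] --out outdir
#   efseg evaluate --pred pred.nii.gz --truth truth.nii.gz [--weight kg]
#   efseg phantom  --out outdir [--n-slices K] [--noise SD] [--rng-seed S]

suppressMessages({
  library(epifat)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(argv) >= 1) argv[1] else ""
rest <- argv[-1]

die <- function(...) { message(...); quit(status = 1) }

if (cmd == "segment") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--input", type = "character"),
    make_option("--seed-slice", type = "integer", dest = "seed_slice", default = 1L),
    make_option("--seed-row", type = "integer", dest = "seed_row"),
    make_option("--seed-col", type = "integer", dest = "seed_col"),
    make_option("--controls", type = "character", default = NULL),
    make_option("--weight", type = "double", default = NULL),
    make_option("--config", type = "character", default = NULL),
    make_option("--out", type = "character", default = "efseg_out")
  )), args = rest)
  if (is.null(opts$input) || is.null(opts$seed_row) || is.null(opts$seed_col)) {
    die("segment needs --input, --seed-row, --seed-col")
  }
  series <- read_ct_series(opts$input)
  controls <- if (!is.null(opts$controls)) read_control_angles(opts$controls)
  cfg <- if (!is.null(opts$config)) {
    do.call(efseg_control, yaml::read_yaml(opts$config))
  } else efseg_control()
  fit <- efseg(series, c(opts$seed_slice, opts$seed_row, opts$seed_col),
               controls, config = cfg, weight = opts$weight)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(fit$mask, file.path(opts$out, "fat_mask.nii.gz"),
                     series[[1]]$pixel_spacing, series[[1]]$slice_thickness)
  write_ellipses_csv(fit, file.path(opts$out, "ellipses.csv"))
  rep <- fit$volume
  jsonlite::write_json(rep[!vapply(rep, is.null, logical(1))],
                       file.path(opts$out, "volume_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  print(fit)
} else if (cmd == "evaluate") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--pred", type = "character"),
    make_option("--truth", type = "character"),
    make_option("--weight", type = "double", default = NULL),
    make_option("--out", type = "character", default = NULL)
  )), args = rest)
  if (is.null(opts$pred) || is.null(opts$truth)) die("evaluate needs --pred and --truth")
  p <- read_ct_series(opts$pred); t <- read_ct_series(opts$truth)
  arr <- function(sl) array(unlist(lapply(sl, function(s) s$pixels)),
                            dim = c(dim(sl[[1]]$pixels), length(sl)))
  ev <- evaluate_segmentation(arr(p) != 0, arr(t) != 0,
                              p[[1]]$pixel_spacing, p[[1]]$slice_thickness,
                              weight = opts$weight)
  out <- list(dice = ev$dice, dice_per_slice = ev$dice_per_slice,
              pred_volume_mm3 = ev$pred_volume$volume_mm3,
              truth_volume_mm3 = ev$truth_volume$volume_mm3,
              relative_error_pct = ev$relative_error_pct,
              normalized_volume_mm3_kg = ev$normalized_volume_mm3_kg)
  txt <- jsonlite::toJSON(out[!vapply(out, is.null, logical(1))],
                          auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(opts$out)) writeLines(txt, opts$out) else cat(txt, "\n")
} else if (cmd == "phantom") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--out", type = "character", default = "phantom_out"),
    make_option("--n-slices", type = "integer", dest = "n_slices", default = 1L),
    make_option("--noise", type = "double", default = 25),
    make_option("--rng-seed", type = "integer", dest = "rng_seed", default = 1L)
  )), args = rest)
  spec <- phantom_spec(noise_sd = opts$noise, n_slices = opts$n_slices,
                       seed = opts$rng_seed)
  vol <- generate_volume(spec)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  arr <- array(unlist(lapply(vol$slices, function(s) s$pixels)),
               dim = c(spec$image_size, opts$n_slices))
  write_volume_nifti(arr, file.path(opts$out, "phantom.nii.gz"),
                     spec$pixel_spacing, spec$slice_thickness)
  write_volume_nifti(vol$fat, file.path(opts$out, "fat_truth.nii.gz"),
                     spec$pixel_spacing, spec$slice_thickness)
  write_volume_nifti(vol$heart, file.path(opts$out, "heart_truth.nii.gz"),
                     spec$pixel_spacing, spec$slice_thickness)
  manifest <- spec
  class(manifest) <- NULL
  manifest$seed_point <- phantom_seed_point(spec)
  jsonlite::write_json(manifest, file.path(opts$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  message("phantom written to ", opts$out)
} else {
  die("usage: efseg <segment|evaluate|phantom> [options]")
}
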