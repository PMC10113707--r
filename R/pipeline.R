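# End-to-end pipeline wiring: phantom generation -> shape model fitting ->
# mask generation -> adversarial texture training -> synthesis -> realism
# evaluation -> segmentation training/evaluation. All randomness flows from
# one root seed through named per-stage substreams; every stage artifact is
# stamped with the config hash + seed so identical reruns are no-ops.

PIPELINE_STAGES <- c("phantom", "fit-shapes", "gen-masks", "train-syn",
                     "synth", "eval-realism", "train-seg", "eval-seg")

#' Default pipeline configuration
#'
#' Nested configuration for \code{\link{run_pipeline}}. Numeric protocol
#' values default to the tuned full-scale settings where one exists
#' (loss weights 1/0.05/100, w1/w2 = 1/5, AMSGrad beta1/beta2 = 0.5/0.999,
#' generator/critic learning rates 1e-4/1e-5, segmentation batch 16 and
#' learning rate 3e-4); the problem sizes default to a small phantom
#' profile that runs end to end on one CPU in minutes.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Root seed.
#' @return Nested list of class \code{"pipeline_config"}.
#' @export
default_pipeline_config <- function(out_dir = file.path(tempdir(), "lesionsynth-run"),
                                    seed = 1L) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    phantom = list(n_slices = 20L, n_lesion_min = 1L, n_lesion_max = 2L,
                   height = 32L, width = 32L),
    shapes = list(n_points = 100L, n_components = 10L, weight_scale = 1.0,
                  n_masks_per_slice = 1L, max_tries = 200L),
    synthesis = list(n_stages = 4L, base_channels = 8L, disc_base_channels = 8L,
                     patch_size = 32L, steps = 120L, batch_size = 6L,
                     lr_generator = 1e-4, lr_discriminator = 1e-5,
                     beta1 = 0.5, beta2 = 0.999,
                     lambda_reconstruction = 1, lambda_perceptual = 0.05,
                     lambda_texture = 100, w1 = 1, w2 = 5, lambda_gp = 10),
    realism = list(n_gray_levels = 16L, n_bins = 20L, eps = 1e-8),
    segmentation = list(batch_size = 16L, epochs = 8L, learning_rate = 3e-4,
                        lambda_dice = 1, lambda_ce = 0.5, n_folds = 3L,
                        depth = 3L, base_width = 4L)
  ), class = "pipeline_config")
}

# Recursive schema check: every key in cfg must exist in the default.
check_config_keys <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad)) {
    stop("unknown config key", if (length(bad) > 1) "s", ": ",
         paste0(path, bad, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]])) check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

load_pipeline_config <- function(config) {
  ref <- default_pipeline_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) return(config)
  check_config_keys(config, ref)
  merge <- function(def, usr) {
    for (nm in names(usr)) {
      def[[nm]] <- if (is.list(def[[nm]]) && is.list(usr[[nm]]))
        merge(def[[nm]], usr[[nm]]) else usr[[nm]]
    }
    def
  }
  structure(merge(unclass(ref), config), class = "pipeline_config")
}

# Cheap deterministic FNV-style hash of the configuration.
config_hash <- function(cfg) {
  s <- yaml::as.yaml(unclass(cfg))
  h <- 216613626
  for (v in utf8ToInt(s)) h <- (h * 127 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stage_marker <- function(cfg, stage) {
  file.path(cfg$out_dir, paste0(".", stage, ".done"))
}

stage_done <- function(cfg, stage) {
  mk <- stage_marker(cfg, stage)
  file.exists(mk) && identical(readLines(mk, warn = FALSE)[1L],
                               paste(config_hash(cfg), cfg$seed))
}

mark_stage <- function(cfg, stage) {
  writeLines(paste(config_hash(cfg), cfg$seed), stage_marker(cfg, stage))
}

require_artifact <- function(cfg, path, producer) {
  p <- file.path(cfg$out_dir, path)
  if (!file.exists(p)) {
    stop("missing prerequisite '", path, "'; run stage '", producer, "' first")
  }
  p
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " [lesionsynth] ", ...)
}

#' Run the lesion-synthesis pipeline
#'
#' Executes the requested stages in dependency order:
#' \code{phantom} (seeded dataset), \code{fit-shapes} (point-distribution
#' model of training lesion contours), \code{gen-masks} (sampled + placed
#' new lesion masks on lesion-free tissue), \code{train-syn} (adversarial
#' texture training), \code{synth} (paint textures into the new masks),
#' \code{eval-realism} (GLCM/KL report), \code{train-seg} (segmentation
#' with and without synthetic augmentation) and \code{eval-seg} (test-split
#' metrics). Artifacts are written under \code{out_dir}; a completed stage
#' with an unchanged config and seed is skipped unless \code{force}.
#'
#' @param config A \code{\link{default_pipeline_config}}-style list, or a
#'   path to a YAML file with (a subset of) its keys.
#' @param stages Character vector of stage names (default: all).
#' @param force Re-run stages whose artifacts are already up to date.
#' @param verbose Log progress to stderr.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = PIPELINE_STAGES, force = FALSE,
                         verbose = TRUE) {
  cfg <- load_pipeline_config(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages are: ", paste(PIPELINE_STAGES, collapse = ", "))
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in stages) {
    if (!force && stage_done(cfg, stage)) {
      pipeline_log(verbose, "stage ", stage, " up to date, skipping")
      next
    }
    pipeline_log(verbose, "running stage ", stage)
    switch(stage,
           "phantom" = stage_phantom(cfg),
           "fit-shapes" = stage_fit_shapes(cfg),
           "gen-masks" = stage_gen_masks(cfg),
           "train-syn" = stage_train_syn(cfg),
           "synth" = stage_synth(cfg),
           "eval-realism" = stage_eval_realism(cfg),
           "train-seg" = stage_train_seg(cfg),
           "eval-seg" = stage_eval_seg(cfg))
    mark_stage(cfg, stage)
  }
  invisible(cfg$out_dir)
}

stage_phantom <- function(cfg) {
  p <- cfg$phantom
  ds <- generate_phantom_dataset(p$n_slices, c(p$n_lesion_min, p$n_lesion_max),
                                 seed = substream_seed(cfg$seed, "phantom"),
                                 height = p$height, width = p$width)
  saveRDS(ds, file.path(cfg$out_dir, "dataset.rds"))
  img_dir <- file.path(cfg$out_dir, "phantom")
  dir.create(img_dir, showWarnings = FALSE)
  for (i in seq_along(ds$slices)) {
    s <- ds$slices[[i]]
    base <- sprintf("s%03d_%03d", ds$subject[i], i)
    write_slice_png(s$image, file.path(img_dir, paste0(base, "_img.png")))
    write_slice_png(s$organ_mask, file.path(img_dir, paste0(base, "_organ.png")))
    write_slice_nifti(s$lesion_label_map, file.path(img_dir, paste0(base, "_lesions.nii.gz")))
  }
}

stage_fit_shapes <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  masks <- list()
  for (s in ds$slices) {
    lab <- s$lesion_label_map
    for (k in seq_len(max(lab, 0))) {
      m <- (lab == k) * 1L
      if (sum(m) > 10) masks[[length(masks) + 1L]] <- m
    }
  }
  model <- fit_shape_model(masks, n_points = cfg$shapes$n_points,
                           n_components = min(cfg$shapes$n_components,
                                              length(masks) - 1L))
  save_shape_model(model, file.path(cfg$out_dir, "shape_model.yaml"))
}

stage_gen_masks <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  model <- load_shape_model(require_artifact(cfg, "shape_model.yaml", "fit-shapes"))
  seed0 <- substream_seed(cfg$seed, "gen-masks")
  masks <- vector("list", length(ds$slices))
  for (i in seq_along(ds$slices)) {
    s <- ds$slices[[i]]
    existing <- (s$lesion_label_map > 0) * 1L
    per <- list()
    for (j in seq_len(cfg$shapes$n_masks_per_slice)) {
      sd <- substream_seed(seed0, paste0("m", i, "_", j))
      sh <- sample_shape(model, sd, cfg$shapes$weight_scale)
      sh <- transform_shape(sh, sample_area(model, sd))
      m <- place_mask(sh, list(organ_mask = s$organ_mask,
                               existing_lesions = existing,
                               max_tries = cfg$shapes$max_tries), sd)
      existing <- pmax(existing, m)  # keep multiple new masks disjoint
      per[[j]] <- m
    }
    masks[[i]] <- Reduce(pmax, per)
  }
  saveRDS(masks, file.path(cfg$out_dir, "generated_masks.rds"))
}

synthesis_config_from <- function(cfg) {
  s <- cfg$synthesis
  synthesis_config(
    gen = generator_config(s$n_stages, s$base_channels, cfg$phantom$height),
    disc = discriminator_config(s$patch_size, s$disc_base_channels),
    weights = loss_weights(s$lambda_reconstruction, s$lambda_perceptual,
                           s$lambda_texture, s$w1, s$w2, s$lambda_gp),
    extractor = random_conv_extractor(),
    batch_size = s$batch_size, steps = s$steps,
    lr_generator = s$lr_generator, lr_discriminator = s$lr_discriminator,
    beta1 = s$beta1, beta2 = s$beta2,
    seed = substream_seed(cfg$seed, "train-syn"))
}

stage_train_syn <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  train <- ds$slices[ds$split$train]
  train <- Filter(function(s) any(s$lesion_label_map > 0), train)
  r <- train_synthesis(train, synthesis_config_from(cfg))
  save_checkpoint(r$generator, file.path(cfg$out_dir, "generator.rds"))
  save_checkpoint(r$discriminator, file.path(cfg$out_dir, "discriminator.rds"))
  write.csv(r$history, file.path(cfg$out_dir, "train_history.csv"),
            row.names = FALSE)
}

stage_synth <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  masks <- readRDS(require_artifact(cfg, "generated_masks.rds", "gen-masks"))
  gen <- load_checkpoint(require_artifact(cfg, "generator.rds", "train-syn"))
  out <- synthesize_lesions(gen, ds$slices, masks)
  saveRDS(out, file.path(cfg$out_dir, "synthetic.rds"))
  img_dir <- file.path(cfg$out_dir, "synthetic")
  dir.create(img_dir, showWarnings = FALSE)
  for (i in seq_along(out)) {
    base <- sprintf("syn%03d", i)
    write_slice_png(out[[i]]$image, file.path(img_dir, paste0(base, "_img.png")))
    write_slice_png(out[[i]]$label, file.path(img_dir, paste0(base, "_label.png")))
  }
}

stage_eval_realism <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  syn <- readRDS(require_artifact(cfg, "synthetic.rds", "synth"))
  gcfg <- glcm_config(n_gray_levels = cfg$realism$n_gray_levels)
  realism_report(lesion_rois(ds$slices), lesion_rois(syn), gcfg,
                 n_bins = cfg$realism$n_bins, eps = cfg$realism$eps,
                 out_csv = file.path(cfg$out_dir, "realism_report.csv"))
}

seg_config_from <- function(cfg) {
  s <- cfg$segmentation
  seg_config(batch_size = s$batch_size, epochs = s$epochs,
             learning_rate = s$learning_rate, lambda_dice = s$lambda_dice,
             lambda_ce = s$lambda_ce, n_folds = s$n_folds, depth = s$depth,
             base_width = s$base_width,
             seed = substream_seed(cfg$seed, "train-seg"))
}

stage_train_seg <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  syn <- readRDS(require_artifact(cfg, "synthetic.rds", "synth"))
  scfg <- seg_config_from(cfg)
  base <- train_segmentation(ds, NULL, scfg)
  aug <- train_segmentation(ds, syn, scfg)
  write.csv(base$per_subject, file.path(cfg$out_dir, "seg_baseline.csv"),
            row.names = FALSE)
  write.csv(aug$per_subject, file.path(cfg$out_dir, "seg_augmented.csv"),
            row.names = FALSE)
  saveRDS(list(baseline = base$models, augmented = aug$models,
               summary = list(baseline = base$summary, augmented = aug$summary)),
          file.path(cfg$out_dir, "seg_models.rds"))
}

stage_eval_seg <- function(cfg) {
  ds <- readRDS(require_artifact(cfg, "dataset.rds", "phantom"))
  mo <- readRDS(require_artifact(cfg, "seg_models.rds", "train-seg"))
  test_idx <- ds$split$test
  rows <- list()
  for (arm in c("baseline", "augmented")) {
    net <- mo[[arm]][[1L]]
    for (s in unique(ds$subject[test_idx])) {
      sl <- test_idx[ds$subject[test_idx] == s]
      preds <- lapply(sl, function(i)
        (unet_forward(net, ds$slices[[i]]$image) >= 0.5) * 1)
      gts <- lapply(sl, function(i) (ds$slices[[i]]$lesion_label_map > 0) * 1)
      m <- segmentation_metrics(preds, gts)
      rows[[length(rows) + 1L]] <- data.frame(arm = arm, subject = s,
                                              dsc = m$dsc, vpsc = m$vpsc,
                                              vsen = m$vsen)
    }
  }
  write.csv(do.call(rbind, rows), file.path(cfg$out_dir, "test_metrics.csv"),
            row.names = FALSE)
}
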