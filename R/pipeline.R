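#' End-to-end pipelines and experiments
#'
#' Convenience drivers that wire the full workflow together: phantom
#' generation, repeated acquisitions, registration and averaging into
#' labels, training-set synthesis, adversarial training, depth-by-depth
#' enhancement, projections and metric reports. These run at reduced scale
#' by default so a desk machine can execute them; every size is a plain
#' argument.
#'
#' @name pipeline
NULL

#' Build a phantom en face training corpus
#'
#' For each phantom: a clean volume is generated, `n_repeats` noisy
#' acquisitions are simulated, each repeat is projected to an en face MIP,
#' and the repeats are combined into a reference label. With
#' \code{register = TRUE} the repeats drift rigidly and the label is the
#' registered-and-averaged crop resized back to the nominal frame; with
#' \code{register = FALSE} (default) the repeats are aligned by
#' construction and averaged directly, which exercises the same averaging
#' statistics at a fraction of the cost.
#'
#' @param n number of phantoms ("volumes")
#' @param shape phantom shape (depth, height, width)
#' @param seed root seed; phantom k uses seed + k substreams
#' @param n_repeats repeated acquisitions per phantom (default 10)
#' @param register run the keypoint registration workflow on drifting
#'   repeats instead of averaging aligned repeats
#' @param drift a [drift_params()] used when \code{register = TRUE}
#' @param config_template a [phantom_config()] supplying vessel/noise
#'   parameters (its shape and seed are overridden)
#' @return list of entries \code{list(E, label, gt, volume)}: single-shot
#'   en face image, averaged label, clean ground-truth MIP, and the first
#'   noisy volume
#' @export
make_phantom_enface_dataset <- function(n, shape = c(32, 64, 64), seed = 1L,
                                        n_repeats = 10, register = FALSE,
                                        drift = drift_params(2, 1),
                                        config_template = phantom_config()) {
  out <- vector("list", n)
  for (k in seq_len(n)) {
    cfg <- config_template
    cfg$shape <- as.integer(shape)
    cfg$seed <- as.integer(seed + 131 * k)
    clean <- generate_clean_volume(cfg)
    dk <- drift
    if (!register) { dk$max_shift <- 0; dk$max_rotation <- 0 }
    dk$seed <- as.integer(seed + 131 * k + 17)
    reps <- simulate_repeat_acquisitions(clean$volume, n_repeats, dk, cfg)
    mips <- lapply(reps$volumes, mip)
    label <- if (register) {
      reg <- register_enface(mips, reference_index = 1,
                             seed = seed + 131 * k + 29)
      avg <- average_registered(reg)
      as.matrix(EBImage::resize(EBImage::Image(avg),
                                w = shape[2], h = shape[3]))
    } else {
      average_registered(mips)
    }
    out[[k]] <- list(E = mips[[1]], label = label, gt = mip(clean$volume),
                     volume = reps$volumes[[1]], clean = clean$volume)
  }
  out
}

#' Train-and-evaluate over a grid of synthesis weights
#'
#' Trains one scaled-down model per (alpha, beta) setting on the same
#' phantom corpus and evaluates the enhanced test images, emitting one row
#' of vascular metrics per setting.
#'
#' @param dataset corpus from [make_phantom_enface_dataset()]
#' @param grid list of \code{c(alpha, beta)} pairs; the default four span
#'   noise-free to noise-dominated synthesis and include the (0.25, 0.75)
#'   operating point
#' @param config a [train_config()] (use few epochs here)
#' @param n_test number of trailing corpus entries held out for evaluation
#' @param base_channels network width
#' @param csv optional path to write the table as CSV
#' @param seed seed for noise-image generation and splits
#' @return data.frame with alpha, beta and mean CNR/VD/VDI/VC over the test
#'   images
#' @export
run_weight_grid <- function(dataset,
                            grid = list(c(1, 0), c(0.5, 0.5), c(0.25, 0.75),
                                        c(0.1, 0.9)),
                            config = train_config(epochs = 10),
                            n_test = 2, base_channels = 8, csv = NULL,
                            seed = 1L) {
  stopifnot(length(grid) >= 1, length(dataset) > n_test)
  n <- length(dataset)
  train_idx <- seq_len(n - n_test)
  test_idx <- setdiff(seq_len(n), train_idx)
  cfg_noise <- phantom_config(shape = c(8, dim(dataset[[1]]$E)),
                              seed = seed + 7)
  noise_pool <- lapply(1:8, function(i) avascular_cscan(cfg_noise, seed + i))
  rows <- NULL
  for (g in grid) {
    w <- synthesis_weights(g[1], g[2])
    pairs <- build_training_set(dataset[train_idx], noise_pool, w,
                                n_noise_only = 2, n_black = 2, seed = seed)
    fit <- train_gan(pairs, config, base_channels = base_channels)
    mets <- lapply(test_idx, function(i) {
      C <- noise_pool[[1 + (i %% length(noise_pool))]]
      x <- synthesize_input(dataset[[i]]$E, C, w)
      y <- generator_forward(fit$generator, x)
      tryCatch(as.data.frame(evaluate_image(y)),
               error = function(e) data.frame(cnr = NA, vd = NA, vdi = NA,
                                              vc = NA))
    })
    m <- do.call(rbind, mets)
    rows <- rbind(rows, data.frame(alpha = g[1], beta = g[2],
                                   cnr = mean(m$cnr), vd = mean(m$vd),
                                   vdi = mean(m$vdi), vc = mean(m$vc)))
  }
  if (!is.null(csv)) write.csv(rows, csv, row.names = FALSE)
  rows
}

#' Run the whole pipeline on a seeded phantom and write its artifacts
#'
#' Phantom, repeated acquisitions, registered-and-averaged label,
#' training-set synthesis, adversarial training, depth-by-depth enhancement
#' of a held-out volume, plain and depth-encoded projections, and a metric
#' report, all under one directory with a JSON manifest sufficient to
#' re-run the demo exactly.
#'
#' @param out_dir output directory (created)
#' @param seed root seed for every stage
#' @param shape phantom shape
#' @param n_volumes corpus size (the last volume is held out)
#' @param epochs training epochs
#' @param base_channels network width
#' @return invisibly, a list with the manifest and the metric comparison
#' @export
run_end_to_end_demo <- function(out_dir, seed = 1L, shape = c(32, 64, 64),
                                n_volumes = 8, epochs = 8,
                                base_channels = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # corpus: one registered label workflow on the first phantom (full
  # workflow demonstration), aligned averaging for the rest
  data_reg <- make_phantom_enface_dataset(1, shape, seed, register = TRUE)
  data_rest <- make_phantom_enface_dataset(n_volumes - 1, shape, seed + 1000)
  corpus <- c(data_reg, data_rest)
  held_out <- corpus[[n_volumes]]

  cfg_noise <- phantom_config(shape = shape, seed = seed + 7)
  noise_pool <- lapply(1:8, function(i) avascular_cscan(cfg_noise, seed + i))
  w <- synthesis_weights(0.25, 0.75)
  pairs <- build_training_set(corpus[seq_len(n_volumes - 1)], noise_pool, w,
                              n_noise_only = 2, n_black = 2, seed = seed)
  tc <- train_config(epochs = epochs, seed = seed)
  fit <- train_gan(pairs, tc, base_channels = base_channels)

  enhanced <- enhance_volume(held_out$volume, fit$generator)
  band <- c(1, max(2, shape[1] %/% 8))
  cnr_in <- cross_sectional_cnr(held_out$volume, band)
  cnr_out <- cross_sectional_cnr(enhanced, band)

  write_volume(held_out$volume, file.path(out_dir, "input_volume.tiff"))
  write_volume(enhanced, file.path(out_dir, "enhanced_volume.tiff"))
  write_enface_png(mip(enhanced), file.path(out_dir, "enhanced_mip.png"))
  png::writePNG(depth_encoded_mip(enhanced),
                file.path(out_dir, "enhanced_depth_mip.png"))
  utils::write.csv(fit$epochs, file.path(out_dir, "loss_curves.csv"),
                   row.names = FALSE)
  met_in <- tryCatch(as.data.frame(evaluate_image(mip(held_out$volume))),
                     error = function(e) NULL)
  met_out <- tryCatch(as.data.frame(evaluate_image(mip(enhanced))),
                      error = function(e) NULL)
  metrics <- list(
    mean_bscan_cnr_input = mean(cnr_in, na.rm = TRUE),
    mean_bscan_cnr_enhanced = mean(cnr_out, na.rm = TRUE),
    enface_input = met_in, enface_enhanced = met_out)
  manifest <- list(
    package_version = as.character(utils::packageVersion("octa3d")),
    seed = seed, shape = shape, n_volumes = n_volumes, epochs = epochs,
    base_channels = base_channels, alpha = w$alpha, beta = w$beta,
    lambda_content = tc$lambda_content, learning_rate = tc$learning_rate,
    metrics = metrics)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, fit = fit, enhanced = enhanced,
                 held_out = held_out))
}
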