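#' Coronal cut index of a phantom's pectoral plane on another grid
#'
#' Converts the phantom's chest-wall plane (defined on its native grid) to
#' the equivalent 1-based coronal cut index on a grid of different spacing,
#' preserving the physical position of the cut plane.
#'
#' @param phantom a `Phantom`.
#' @param target_spacing_mm spacing of the grid the cut is needed on.
#' @return integer cut index.
#' @export
phantom_cut_index <- function(phantom, target_spacing_mm = phantom$spacing_mm) {
  cut_mm <- (phantom$chest_wall_plane_index - 1) * phantom$spacing_mm[2]
  as.integer(round(cut_mm / target_spacing_mm[2])) + 1L
}

#' Acquire, reconstruct, segment and quantify one phantom
#'
#' Runs the full measurement pipeline for one acquisition: Dixon simulation,
#' two-point separation, optional multi-planar reformat to the acquisition
#' grid, breast segmentation (threshold on the water-plus-fat image, with
#' the pectoral cut read from the phantom), and per-breast calibrated %FGT
#' quantification. A pre-made pair of breast masks can be supplied to share
#' a segmentation across datasets.
#'
#' @param phantom a `Phantom`.
#' @param seq a `SequenceParams` or preset name.
#' @param tissues a `TissueProperties`.
#' @param reformat_to `NULL` (stay on the phantom grid) or a target spacing.
#' @param masks `NULL`, or a list with `L` and `R` `SegmentationMask`s on
#'   the (possibly reformatted) pair's grid.
#' @param dataset label for the result rows; defaults to the preset name.
#' @param subject subject label.
#' @param threshold,erosion_iters segmentation settings (see [body_mask()]).
#' @param mode separation mode, `"complex"` or `"magnitude"`.
#' @param ... passed to [quantify_breast()].
#' @return list with `results` (two-row data.frame, sides L and R), `pair`
#'   (the `DixonPair` quantified), and `masks`.
#' @export
acquire_and_quantify <- function(phantom, seq, tissues = tissue_properties(),
                                 reformat_to = NULL, masks = NULL,
                                 dataset = NULL, subject = "phantom",
                                 threshold = "auto", erosion_iters = 1L,
                                 mode = "complex", ...) {
  if (is.character(seq)) seq <- sequence_preset(seq)
  dataset <- dataset %||% seq$name
  echoes <- simulate_dixon_acquisition(phantom, tissues, seq)
  pair <- two_point_separation(echoes, mode = mode)
  if (!is.null(reformat_to)) pair <- reformat_pair(pair, reformat_to)
  if (is.null(masks)) {
    ipmag <- volume_image(pair$water$data + pair$fat$data, pair$water$spacing_mm)
    body <- body_mask(ipmag, threshold = threshold, erosion_iters = erosion_iters)
    masks <- pectoral_cut_and_split(body,
                                    phantom_cut_index(phantom, pair$water$spacing_mm))
  }
  rows <- do.call(rbind, lapply(c("L", "R"), function(side) {
    quantify_breast(pair, masks[[side]], dataset = dataset, ...)
  }))
  rows <- cbind(data.frame(subject = subject, stringsAsFactors = FALSE), rows)
  list(results = rows, pair = pair, masks = masks)
}

#' Default run configuration
#'
#' The configuration consumed by [run_experiment()]. Phantom geometry and
#' acquisition settings default to the simulator's study presets; cohort
#' size, composition fractions and jitter are the knobs an experiment
#' script may set.
#'
#' @param n_subjects phantoms per cohort.
#' @param fractions true fibroglandular fractions used across the cohort
#'   (recycled over subjects); the defaults span the density range typical
#'   of a healthy volunteer cohort (roughly 18-65 %FGT, mean near 36).
#' @param grid_shape,voxel_spacing_mm phantom grid.
#' @param noise_sd acquisition noise level (fraction of mean tissue signal).
#' @param jitter_vox maximum repositioning jitter between repeat exams, in
#'   voxels per axis (integer; drawn uniformly from `-jitter_vox:jitter_vox`).
#' @param delta_fraction correction-factor perturbation for the sensitivity
#'   experiment.
#' @param rng_seed master seed.
#' @param output_dir where [run_experiment()] writes its files.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(n_subjects = 5L,
                               fractions = c(0.18, 0.28, 0.36, 0.5, 0.65),
                               grid_shape = c(96L, 64L, 64L),
                               voxel_spacing_mm = c(1.3, 1.3, 1.0),
                               noise_sd = 0.02,
                               jitter_vox = 2L,
                               delta_fraction = 0.15,
                               rng_seed = 1L,
                               output_dir = tempfile("dixonfgt_run_")) {
  structure(list(n_subjects = as.integer(n_subjects), fractions = fractions,
                 grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 noise_sd = noise_sd, jitter_vox = as.integer(jitter_vox),
                 delta_fraction = delta_fraction, rng_seed = as.integer(rng_seed),
                 output_dir = output_dir),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; unknown fields are rejected.
#'
#' @param path YAML file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  base[names(vals)] <- vals
  base$n_subjects <- as.integer(base$n_subjects)
  base$grid_shape <- as.integer(base$grid_shape)
  base$rng_seed <- as.integer(base$rng_seed)
  base
}

.cohort_phantom <- function(config, i, seed) {
  f <- config$fractions[((i - 1L) %% length(config$fractions)) + 1L]
  generate_phantom(phantom_spec(grid_shape = config$grid_shape,
                                voxel_spacing_mm = config$voxel_spacing_mm,
                                composition = list(type = "blobs", fraction = f,
                                                   scale_mm = 8),
                                noise_sd = config$noise_sd,
                                rng_seed = seed))
}

# Shift a phantom by integer voxels (repositioning between repeat exams);
# tissue moved out of the grid is dropped, exposed voxels become background.
.jitter_phantom <- function(phantom, shift_vox) {
  v <- phantom$v; lab <- phantom$labels
  for (a in 1:3) {
    v <- .shift3d(v, a, shift_vox[a], 0)
    lab <- .shift3d(lab, a, shift_vox[a], LABEL_BACKGROUND)
  }
  ph <- phantom
  ph$v <- v; ph$labels <- lab
  ph$chest_wall_plane_index <- phantom$chest_wall_plane_index + shift_vox[2]
  ph$true_fgt_percent <- c(L = true_fgt_percent(ph, "L"),
                           R = true_fgt_percent(ph, "R"))
  ph
}

#' Run one of the three study experiments on simulated cohorts
#'
#' * `"repeatability"`: each subject phantom is acquired twice with the
#'   proton-density gradient-echo preset, with an integer-voxel
#'   repositioning jitter and an independent noise realisation between
#'   "exams"; each exam is segmented and quantified independently and the
#'   paired per-breast measures are summarised by [bland_altman()] for FGT
#'   volume, total volume and %FGT.
#' * `"comparison"`: each subject is acquired with the three presets; the
#'   high-resolution gradient-echo pairs are additionally reformatted to
#'   the low-resolution grid, giving five datasets per subject. The breast
#'   masks are segmented once per resolution on the proton-density data and
#'   shared across datasets after a mutual-information registration (zero
#'   expected shift here), and the cohort is summarised by
#'   [cohort_compare()] against the high-resolution proton-density
#'   reference.
#' * `"sensitivity"`: the correction factor of each low-resolution
#'   T1-weighted dataset is perturbed by `+/- delta_fraction` and the %FGT
#'   changes reported per subject.
#'
#' All randomness derives from `config$rng_seed`. A results CSV, a JSON
#' report and a manifest (config and seed) are written to
#' `config$output_dir`.
#'
#' @param config a `RunConfig`.
#' @param experiment one of `"repeatability"`, `"comparison"`,
#'   `"sensitivity"`.
#' @return the report list, invisibly; its elements are also written to
#'   disk.
#' @export
run_experiment <- function(config = default_run_config(),
                           experiment = c("repeatability", "comparison",
                                          "sensitivity")) {
  experiment <- match.arg(experiment)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$rng_seed)
  seeds <- sample.int(1e6, config$n_subjects * 4L)

  report <- switch(experiment,
    repeatability = .exp_repeatability(config, seeds),
    comparison = .exp_comparison(config, seeds),
    sensitivity = .exp_sensitivity(config, seeds))

  utils::write.csv(report$results, file.path(config$output_dir,
                                             paste0(experiment, "_results.csv")),
                   row.names = FALSE)
  jsonlite::write_json(report$report, file.path(config$output_dir,
                                                paste0(experiment, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  manifest <- list(experiment = experiment,
                   config = unclass(config),
                   rng_seed = config$rng_seed,
                   package_version = as.character(utils::packageVersion("dixonfgt")))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.exp_repeatability <- function(config, seeds) {
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    ph <- .cohort_phantom(config, i, seeds[i])
    jit <- if (config$jitter_vox > 0)
      sample(-config$jitter_vox:config$jitter_vox, 3L, replace = TRUE)
    else c(0L, 0L, 0L)
    ph2 <- .jitter_phantom(ph, jit)
    for (exam in 1:2) {
      p <- if (exam == 1) ph else ph2
      noise_seed <- seeds[config$n_subjects * exam + i]
      echoes <- simulate_dixon_acquisition(p, seq = "hr_gre_pd",
                                           rng_seed = noise_seed)
      pair <- two_point_separation(echoes)
      ipmag <- volume_image(pair$water$data + pair$fat$data, pair$water$spacing_mm)
      body <- body_mask(ipmag)
      masks <- pectoral_cut_and_split(body, phantom_cut_index(p))
      for (side in c("L", "R")) {
        r <- quantify_breast(pair, masks[[side]],
                             dataset = if (exam == 1) "hr_gre_pd" else "hr_gre_pd_r")
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(subject = paste0("S", i), exam = exam), r)
      }
    }
  }
  results <- do.call(rbind, rows)
  ba <- lapply(c("fgt_cm3", "total_cm3", "pct_fgt", "c"), function(mname) {
    a <- results[results$exam == 1, ]; b <- results[results$exam == 2, ]
    ord <- function(x) x[order(x$subject, x$laterality), ]
    a <- ord(a); b <- ord(b)
    bland_altman(data.frame(value_1 = a[[mname]], value_2 = b[[mname]]), mname)
  })
  names(ba) <- c("fgt_cm3", "total_cm3", "pct_fgt", "c")
  list(results = results, report = ba)
}

.exp_comparison <- function(config, seeds) {
  lr_spacing <- sequence_preset("lr_se_t1")$acq_spacing_mm
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    ph <- .cohort_phantom(config, i, seeds[i])
    subject <- paste0("S", i)
    # reference HR PD acquisition and its segmentation
    hr_pd <- acquire_and_quantify(ph, "hr_gre_pd", subject = subject)
    rows[[length(rows) + 1L]] <- hr_pd$results
    # HR T1 shares the HR masks (same grid, no repositioning within the exam)
    hr_t1 <- acquire_and_quantify(ph, "hr_gre_t1", masks = hr_pd$masks,
                                  subject = subject)
    rows[[length(rows) + 1L]] <- hr_t1$results
    # LR datasets: reformat the HR pairs; segment once on LR PD
    lr_pd <- acquire_and_quantify(ph, "hr_gre_pd", reformat_to = lr_spacing,
                                  dataset = "lr_gre_pd", subject = subject)
    rows[[length(rows) + 1L]] <- lr_pd$results
    lr_t1 <- acquire_and_quantify(ph, "hr_gre_t1", reformat_to = lr_spacing,
                                  masks = lr_pd$masks, dataset = "lr_gre_t1",
                                  subject = subject)
    rows[[length(rows) + 1L]] <- lr_t1$results
    # native SE acquisition, registered to the LR PD grid before mask share
    se_echoes <- simulate_dixon_acquisition(ph, seq = "lr_se_t1")
    se_pair <- reformat_pair(two_point_separation(se_echoes), lr_spacing)
    se_ip <- volume_image(se_pair$water$data + se_pair$fat$data, lr_spacing)
    lr_ip <- volume_image(lr_pd$pair$water$data + lr_pd$pair$fat$data, lr_spacing)
    shift <- register_translation(lr_ip, se_ip, search_radius_mm = 2)
    se_masks <- lapply(lr_pd$masks, transfer_mask, shift = shift,
                       target_dim = dim(se_ip$data), target_spacing_mm = lr_spacing)
    for (side in c("L", "R")) {
      r <- quantify_breast(se_pair, se_masks[[side]], dataset = "lr_se_t1")
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = subject, stringsAsFactors = FALSE), r)
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) r[, c("subject", "dataset",
                                                           "laterality", "fgt_cm3",
                                                           "total_cm3", "pct_fgt", "c")]))
  list(results = results,
       report = cohort_compare(results, reference = "hr_gre_pd"))
}

.exp_sensitivity <- function(config, seeds) {
  lr_spacing <- sequence_preset("lr_se_t1")$acq_spacing_mm
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    ph <- .cohort_phantom(config, i, seeds[i])
    subject <- paste0("S", i)
    lr_pd <- acquire_and_quantify(ph, "hr_gre_pd", reformat_to = lr_spacing,
                                  dataset = "lr_gre_pd", subject = subject)
    for (preset in c("hr_gre_t1", "lr_se_t1")) {
      seq <- sequence_preset(preset)
      echoes <- simulate_dixon_acquisition(ph, seq = seq)
      pair <- reformat_pair(two_point_separation(echoes), lr_spacing)
      dataset <- if (preset == "hr_gre_t1") "lr_gre_t1" else "lr_se_t1"
      for (side in c("L", "R")) {
        cf <- correction_factor(select_calibration_roi(pair, lr_pd$masks[[side]]))
        sens <- sensitivity(pair, lr_pd$masks[[side]], cf, config$delta_fraction)
        rows[[length(rows) + 1L]] <-
          data.frame(subject = subject, dataset = dataset, laterality = side,
                     c = cf$c, pct_fgt = sens$pct_fgt,
                     delta_plus = sens$delta_plus, delta_minus = sens$delta_minus)
      }
    }
  }
  results <- do.call(rbind, rows)
  list(results = results,
       report = list(delta_fraction = config$delta_fraction,
                     mean_delta_plus = mean(results$delta_plus),
                     mean_delta_minus = mean(results$delta_minus)))
}
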