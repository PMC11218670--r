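#' Experiment configuration
#'
#' Parses and validates a whole-experiment description (typically from
#' YAML): phantom block, geometry block, optional noise block, training
#' block, pipeline block, the method list, and a single global seed from
#' which every stage derives its own seed by a fixed counter scheme
#' (`stage_seed = (seed * 1000 + offset) mod 2^31-1`), so stages can be
#' rerun in isolation reproducibly.  Unknown keys anywhere are rejected by
#' name; a parsed configuration serializes back to the same YAML.
#'
#' @param config a named list (e.g. from `yaml::read_yaml()`).
#' @return A validated object of class `experiment_config`.
#' @export
experiment_config <- function(config) {
  allowed <- list(
    seed = NULL, output_dir = NULL, methods = NULL,
    phantom = c("n", "n_slices", "n_structures", "n_lesions",
                "mismatch_magnitude", "voxel_size"),
    geometry = c("mode", "total_angle", "sampling_density", "detector_pixels",
                 "detector_pitch", "source_to_isocenter", "source_to_detector",
                 "beam_mode"),
    noise = c("enabled", "photons_per_pixel", "electronic_variance",
              "attenuation_per_unit"),
    train = c("n_volumes", "hidden", "depth", "iterations", "batch_size",
              "learning_rate", "sigma_min", "sigma_max", "num_steps"),
    pfgdm = c("total_steps", "drop_frac", "corrector_steps", "snr",
              "tv_weight", "penalty", "cg_iters"),
    admm_tv = c("tv_weight", "penalty", "outer_iters", "cg_iters")
  )
  unknown_top <- setdiff(names(config), names(allowed))
  if (length(unknown_top)) stop("unknown config key: ", unknown_top[1])
  for (blk in setdiff(names(allowed), c("seed", "output_dir", "methods"))) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), allowed[[blk]])
      if (length(bad)) stop(sprintf("unknown config key: %s.%s", blk, bad[1]))
    }
  }
  defaults <- list(
    seed = 1L, output_dir = NULL,
    methods = c("fdk", "admm_tv", "pfgdm_a", "pfgdm_b"),
    phantom = list(n = 64L, n_slices = 3L, n_structures = 14L, n_lesions = 2L,
                   mismatch_magnitude = 0.5, voxel_size = 4.13),
    geometry = list(mode = "ortho", total_angle = 90, sampling_density = 0.25,
                    detector_pixels = 64L, detector_pitch = 6.2,
                    source_to_isocenter = 1000, source_to_detector = 1500,
                    beam_mode = "fan_per_slice"),
    noise = list(enabled = FALSE, photons_per_pixel = 1e5,
                 electronic_variance = 10, attenuation_per_unit = 0.02),
    train = list(n_volumes = 40L, hidden = 12L, depth = 5L, iterations = 4000L,
                 batch_size = 4L, learning_rate = 1e-3, sigma_min = 0.01,
                 sigma_max = NULL, num_steps = 100L),
    pfgdm = list(total_steps = 150L, drop_frac = 1400 / 3000,
                 corrector_steps = 1L, snr = 0.16, tv_weight = 1.0,
                 penalty = 1.0, cg_iters = 12L),
    admm_tv = list(tv_weight = 3.0, penalty = 30.0, outer_iters = 40L,
                   cg_iters = 8L)
  )
  merged <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !nm %in% c("methods")) {
      for (k in names(config[[nm]])) merged[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  bad_m <- setdiff(merged$methods, c("fdk", "admm_tv", "pfgdm_a", "pfgdm_b"))
  if (length(bad_m)) stop("unknown method: ", bad_m[1])
  structure(merged, class = "experiment_config")
}

stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% 2147483647)
}

#' Run a full reconstruction experiment
#'
#' Executes phantom synthesis, projection, optional noise injection, score
#' model training (one model per required variant), every requested
#' reconstruction method, and evaluation against the ground-truth phantom.
#' When `output_dir` is set, reconstructed volumes (NIfTI), the metric table
#' (CSV), per-method reports (JSON) and a manifest recording the config hash
#' and stage seeds are written there; a failure leaves a `FAILED` marker
#' next to any partial artifacts.
#'
#' @param config an [experiment_config()], or a named list / YAML path
#'   coerced through it.
#' @return `list(status, metrics, results, manifest)`; `status` is 0 on
#'   success, 1 on failure.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "experiment_config")) config <- experiment_config(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- tryCatch(
    run_experiment_stages(config, out_dir),
    error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
      }
      list(status = 1L, error = conditionMessage(e))
    }
  )
  res
}

run_experiment_stages <- function(config, out_dir) {
  gb <- config$geometry
  angles <- make_limited_angle_set(gb$mode, gb$total_angle, gb$sampling_density)
  geometry <- scan_geometry(angles,
                            detector_pixels = gb$detector_pixels,
                            detector_pitch = gb$detector_pitch,
                            source_to_isocenter = gb$source_to_isocenter,
                            source_to_detector = gb$source_to_detector,
                            beam_mode = gb$beam_mode)
  pb <- config$phantom
  spec <- phantom_spec(n = pb$n, n_slices = pb$n_slices,
                       n_structures = pb$n_structures, n_lesions = pb$n_lesions,
                       mismatch_magnitude = pb$mismatch_magnitude,
                       voxel_size = pb$voxel_size,
                       seed = stage_seed(config$seed, 1L))
  pair <- generate_phantom_pair(spec)
  target <- pair$current

  sino <- forward_project(target, geometry)
  nb <- config$noise
  if (isTRUE(nb$enabled)) {
    nm <- noise_model(nb$photons_per_pixel, nb$electronic_variance,
                      nb$attenuation_per_unit, enabled = TRUE)
    sino <- add_projection_noise(sino, nm, seed = stage_seed(config$seed, 2L))
  }

  needs <- config$methods
  models <- list()
  if (any(c("pfgdm_a", "pfgdm_b") %in% needs)) {
    tb <- config$train
    corpus <- build_training_corpus(tb$n_volumes, spec,
                                    seed = stage_seed(config$seed, 3L))
    smax <- if (is.null(tb$sigma_max)) {
      estimate_sigma_max(lapply(corpus$items, `[[`, "slice"))
    } else tb$sigma_max
    schedule <- diffusion_schedule(tb$sigma_min, smax, tb$num_steps)
    for (v in c("A", "B")) {
      if (!paste0("pfgdm_", tolower(v)) %in% needs) next
      cfg_t <- train_config(v, batch_size = tb$batch_size,
                            learning_rate = tb$learning_rate,
                            iterations = tb$iterations,
                            seed = stage_seed(config$seed, 4L + (v == "B")))
      models[[v]] <- train_score_model(corpus, schedule, cfg_t,
                                       hidden = tb$hidden, depth = tb$depth)
    }
  }

  reports <- list()
  volumes <- list()
  n <- pb$n
  if ("fdk" %in% needs) {
    v <- fdk_reconstruct(sino, geometry, n, voxel_size = pb$voxel_size)
    v$voxels <- pmin(pmax(v$voxels, 0), 1)
    volumes$fdk <- v
    reports$fdk <- simple_report("FDK", v, target)
  }
  if ("admm_tv" %in% needs) {
    ab <- config$admm_tv
    cfg_a <- admm_config(tv_weight = ab$tv_weight, penalty = ab$penalty,
                         outer_iters = ab$outer_iters, cg_iters = ab$cg_iters)
    v <- admm_tv_reconstruct(sino, geometry, n, cfg_a,
                             voxel_size = pb$voxel_size)
    v$voxels <- pmin(pmax(v$voxels, 0), 1)
    volumes$admm_tv <- v
    reports$admm_tv <- simple_report("ADMM-TV", v, target)
  }
  fb <- config$pfgdm
  for (v in c("A", "B")) {
    key <- paste0("pfgdm_", tolower(v))
    if (!key %in% needs) next
    cfg_p <- pfgdm_config(v, total_steps = fb$total_steps,
                          drop_frac = fb$drop_frac,
                          admm = admm_config(tv_weight = fb$tv_weight,
                                             penalty = fb$penalty,
                                             outer_iters = 1L,
                                             cg_iters = fb$cg_iters,
                                             tv_axes = "z"),
                          corrector_steps = fb$corrector_steps, snr = fb$snr,
                          seed = stage_seed(config$seed, 6L + (v == "B")))
    r <- pfgdm_engine(sino, geometry, pair$prior, models[[v]], cfg_p,
                      reference = target)
    volumes[[key]] <- r$volume
    reports[[key]] <- r$report
  }

  metrics <- compare_table(reports)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    stage_seeds = list(phantom = stage_seed(config$seed, 1L),
                       noise = stage_seed(config$seed, 2L),
                       corpus = stage_seed(config$seed, 3L),
                       train_a = stage_seed(config$seed, 4L),
                       train_b = stage_seed(config$seed, 5L),
                       recon_a = stage_seed(config$seed, 6L),
                       recon_b = stage_seed(config$seed, 7L)),
    metrics = lapply(seq_len(nrow(metrics)), function(i) as.list(metrics[i, ]))
  )
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    for (nm in names(volumes)) {
      write_volume(volumes[[nm]], file.path(out_dir, paste0(nm, ".nii")))
    }
    jsonlite::write_json(
      lapply(reports, function(r) list(method = r$method, psnr = r$psnr,
                                       ssim = r$ssim)),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
  }
  list(status = 0L, metrics = metrics, results = list(volumes = volumes,
                                                      reports = reports,
                                                      target = target,
                                                      prior = pair$prior,
                                                      sino = sino,
                                                      models = models),
       manifest = manifest)
}

simple_report <- function(method, volume, reference) {
  m <- evaluate_reconstruction(volume, reference)
  structure(
    list(method = method,
         steps = tibble::tibble(step = integer(), residual = numeric(),
                                cond_nonzero = integer(), sigma = numeric()),
         psnr = m$psnr, ssim = m$ssim,
         reference_hash = rlang::hash(reference$voxels)),
    class = "recon_report"
  )
}

#' Summary table of reconstruction reports
#'
#' Aggregates a list of [recon_report]s into a method-by-metric table of
#' mean and sample standard deviation (0 for a single report), mirroring the
#' usual methods-by-angles accuracy tables.  Reports evaluated against
#' different references are rejected.
#'
#' @param reports list of `recon_report` objects.
#' @return A tibble with columns `method`, `n`, `psnr_mean`, `psnr_sd`,
#'   `ssim_mean`, `ssim_sd`.
#' @export
compare_table <- function(reports) {
  if (length(reports) < 1L) stop("need at least one report")
  stopifnot(all(vapply(reports, inherits, logical(1), "recon_report")))
  refs <- unique(unlist(lapply(reports, function(r) r$reference_hash)))
  if (length(refs) > 1L) stop("reports use mixed references")
  methods <- vapply(reports, `[[`, character(1), "method")
  psnrs <- vapply(reports, function(r) r$psnr %||% NA_real_, numeric(1))
  ssims <- vapply(reports, function(r) r$ssim %||% NA_real_, numeric(1))
  agg <- lapply(unique(methods), function(m) {
    i <- methods == m
    sdz <- function(v) if (sum(i) > 1L) sd(v[i]) else 0
    tibble::tibble(method = m, n = sum(i),
                   psnr_mean = mean(psnrs[i]), psnr_sd = sdz(psnrs),
                   ssim_mean = mean(ssims[i]), ssim_sd = sdz(ssims))
  })
  do.call(rbind, agg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
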