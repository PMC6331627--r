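#' Pipeline configuration
#'
#' Nested configuration for every stage, with defaults equal to the package's
#' documented stage defaults. Values can be overridden from a YAML file
#' and/or an override list; unknown keys are rejected so typos fail loudly.
#'
#' @param path Optional YAML file whose nested keys override the defaults.
#' @param overrides Optional nested list applied after the file
#'   (precedence: overrides > file > defaults).
#' @return A `breathtex_config` nested list with sections `synth`, `filter`,
#'   `segmentation`, `stft`, `enhance`, `glcm`, `selection`, `classifier`
#'   and a global `seed`.
#' @export
breathtex_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    synth = list(n_per_class = 110L, n_cycles = 4L, cycle_s = 3,
                 gap_s = 1.5, burst_rate = 4, burst_bandwidth_hz = 6000,
                 snr_db = 12, breath_low_hz = 100, breath_high_hz = 1500,
                 inhale_frac = 0.40, pause_frac = 0.07, pause_floor = 0.15,
                 amplitude = 0.3, rate = 44100L),
    filter = list(order = 3L, low_hz = 20, high_hz = 6000,
                  zero_phase = FALSE),
    segmentation = list(frame_len = 2048L, hop = 1024L, a = 1, b = 10,
                        k_min = 20L, noise_floor_frames = 40L,
                        min_breath_s = 0.5, min_gap_s = 0.3),
    stft = list(window_len = 1024L, hop = 512L, window = "blackmanharris"),
    enhance = list(strengthen = TRUE, sigma = 1.0, kernel_size = 7L,
                   zcr_th = 0.25, sbe_window = 32L, sbe_th = 0.75,
                   te_th = 0.75, zero_band = 0.05, fill_threshold = 0.25,
                   fill_full_column = FALSE),
    glcm = list(d = 1L, g = 16L, classic_contrast = FALSE),
    selection = list(k = 13L, criterion = "information_gain",
                     select_once = FALSE),
    classifier = list(ridge = 1e-8, folds = 10L)
  )
  cfg <- defaults
  if (!is.null(path))
    cfg <- merge_config(cfg, yaml::read_yaml(path), "config file")
  if (length(overrides))
    cfg <- merge_config(cfg, overrides, "overrides")
  structure(cfg, class = "breathtex_config")
}

merge_config <- function(base, new, what, prefix = "") {
  if (!is.list(new)) stop(what, ": expected a nested list at ", prefix)
  for (nm in names(new)) {
    key <- paste0(prefix, nm)
    if (!nm %in% names(base))
      stop(what, ": unknown configuration key '", key, "'")
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], new[[nm]], what,
                                 paste0(key, "."))
    else base[[nm]] <- new[[nm]]
  }
  base
}

cfg_synth_spec <- function(cfg, seed, burst_rate = NULL) {
  s <- cfg$synth
  synth_spec(n_cycles = s$n_cycles, cycle_s = s$cycle_s, gap_s = s$gap_s,
             burst_rate = if (is.null(burst_rate)) s$burst_rate
                          else burst_rate,
             burst_bandwidth_hz = s$burst_bandwidth_hz, snr_db = s$snr_db,
             breath_low_hz = s$breath_low_hz,
             breath_high_hz = s$breath_high_hz, inhale_frac = s$inhale_frac,
             pause_frac = s$pause_frac, pause_floor = s$pause_floor,
             amplitude = s$amplitude, seed = seed, rate = s$rate)
}

cfg_filter_spec <- function(cfg)
  filter_spec(cfg$filter$order, cfg$filter$low_hz, cfg$filter$high_hz,
              cfg$filter$zero_phase)

cfg_segmentation_spec <- function(cfg) {
  s <- cfg$segmentation
  segmentation_spec(s$frame_len, s$hop, s$a, s$b, s$k_min,
                    s$noise_floor_frames, s$min_breath_s, s$min_gap_s)
}

cfg_stft_spec <- function(cfg)
  stft_spec(cfg$stft$window_len, cfg$stft$hop, cfg$stft$window)

cfg_enhance_spec <- function(cfg) {
  e <- cfg$enhance
  enhance_spec(sigma = e$sigma, kernel_size = e$kernel_size,
               zcr_th = e$zcr_th, sbe_window = e$sbe_window,
               sbe_th = e$sbe_th, te_th = e$te_th, zero_band = e$zero_band,
               fill_threshold = e$fill_threshold,
               fill_full_column = e$fill_full_column)
}

#' Texture features of one breath waveform
#'
#' Spectrogram, then (by default) the full texture-enhancement method — edge
#' mask, LoG filtering and triple-threshold line strengthening — then the 16
#' GLCM features. With `strengthen = FALSE` the enhancement method is skipped
#' entirely and the features are read from the plain dB spectrogram: the
#' no-strengthening comparison arm.
#'
#' @param x Numeric breath samples.
#' @param rate Sampling rate (Hz).
#' @param config A [breathtex_config()].
#' @param strengthen Apply the texture-enhancement method (default from
#'   config).
#' @return Named 16-feature vector.
#' @export
breath_features <- function(x, rate, config = breathtex_config(),
                            strengthen = config$enhance$strengthen) {
  spg <- spectrogram(x, cfg_stft_spec(config), rate = rate)
  espec <- cfg_enhance_spec(config)
  img <- if (isTRUE(strengthen)) enhance_spectrogram(spg, espec)$values
         else spg$values
  extract_features(img, d = config$glcm$d, g = config$glcm$g,
                   classic_contrast = config$glcm$classic_contrast)
}

# strengthen: TRUE, FALSE or "both" (list of the two feature matrices,
# sharing the filter/segmentation/spectrogram work)
featurize_signal <- function(signal, config, strengthen,
                             source = NA_character_,
                             label = NA_character_) {
  filt <- bandpass_filter(signal, cfg_filter_spec(config))
  segs <- segment_breaths(filt, cfg_segmentation_spec(config))
  if (nrow(segs) == 0L) {
    warning("no breath detected in ", source)
    return(NULL)
  }
  espec <- cfg_enhance_spec(config)
  sspec <- cfg_stft_spec(config)
  both <- identical(strengthen, "both")
  feat <- function(img)
    extract_features(img, d = config$glcm$d, g = config$glcm$g,
                     classic_contrast = config$glcm$classic_contrast)
  fs <- fr <- matrix(0, nrow(segs), 16L,
                     dimnames = list(NULL, feature_names()))
  for (i in seq_len(nrow(segs))) {
    x <- segment_samples(filt, segs$start[i], segs$end[i])
    spg <- spectrogram(x, sspec, rate = filt$rate)
    if (both || isTRUE(strengthen))
      fs[i, ] <- feat(enhance_spectrogram(spg, espec)$values)
    if (both || isFALSE(strengthen)) fr[i, ] <- feat(spg$values)
  }
  wrap <- function(feats)
    data.frame(file = source, label = label, breath = seq_len(nrow(segs)),
               start = segs$start, end = segs$end, feats,
               check.names = FALSE)
  if (both) list(strengthened = wrap(fs), raw = wrap(fr))
  else if (isTRUE(strengthen)) wrap(fs) else wrap(fr)
}

#' Featurize an in-memory corpus
#'
#' Runs filtering, segmentation and per-breath feature extraction on a list
#' of recordings from [synthesize_corpus()], without touching disk.
#'
#' @param corpus List of `labelled_recording`s.
#' @param config A [breathtex_config()].
#' @param strengthen `TRUE`, `FALSE`, or `"both"` to get the strengthened and
#'   unstrengthened feature tables in one pass (the comparison arms share all
#'   the work up to the edge-enhanced image).
#' @return data.frame: one row per detected breath with provenance columns
#'   (`file` = corpus index, `label`, `breath`, `start`, `end`) and the 16
#'   features. With `strengthen = "both"`, a list of two such data.frames
#'   (`strengthened`, `raw`).
#' @export
featurize_corpus <- function(corpus, config = breathtex_config(),
                             strengthen = config$enhance$strengthen) {
  rows <- lapply(seq_along(corpus), function(i)
    featurize_signal(corpus[[i]]$audio, config, strengthen,
                     source = sprintf("recording_%03d", i),
                     label = corpus[[i]]$label))
  if (identical(strengthen, "both")) {
    out <- list(strengthened = do.call(rbind, lapply(rows, `[[`,
                                                     "strengthened")),
                raw = do.call(rbind, lapply(rows, `[[`, "raw")))
    if (is.null(out$strengthened)) stop("no breaths detected in the corpus")
    return(out)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no breaths detected in the whole corpus")
  out
}

#' Simulate a labelled corpus to disk
#'
#' Writes one WAV per recording, a `manifest.csv` (columns `file`, `label`,
#' `seed`) and a JSON truth sidecar per recording (cycle boundaries, burst
#' times). Deterministic given the config seed.
#'
#' @param config A [breathtex_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(config = breathtex_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- synthesize_corpus(config$synth$n_per_class,
                              cfg_synth_spec(config, seed = config$seed),
                              seed = config$seed)
  manifest <- data.frame(file = sprintf("recording_%03d.wav",
                                        seq_along(corpus)),
                         label = vapply(corpus, `[[`, "", "label"),
                         seed = vapply(corpus, function(r) r$spec$seed, 1L))
  for (i in seq_along(corpus)) {
    write_wav(file.path(out_dir, manifest$file[i]), corpus[[i]]$audio)
    jsonlite::write_json(
      list(label = corpus[[i]]$label,
           truth_segments = corpus[[i]]$truth_segments,
           truth_burst_times = corpus[[i]]$truth_burst_times),
      file.path(out_dir, sub("\\.wav$", ".json", manifest$file[i])),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Featurize a corpus on disk
#'
#' @param manifest Manifest data.frame or path to a `manifest.csv` with
#'   columns `file`, `label` (paths relative to the manifest's directory).
#' @param config A [breathtex_config()].
#' @param strengthen Apply texture strengthening.
#' @param out_csv Optional path for the feature table.
#' @return Feature data.frame as in [featurize_corpus()]. Unreadable files
#'   are skipped with a warning; if every file fails, an error is raised.
#' @export
run_featurize <- function(manifest, config = breathtex_config(),
                          strengthen = config$enhance$strengthen,
                          out_csv = NULL) {
  base <- "."
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  stopifnot(all(c("file", "label") %in% names(manifest)))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- file.path(base, manifest$file[i])
    sig <- tryCatch(read_wav(path), error = function(e) {
      warning("skipping ", path, ": ", conditionMessage(e)); NULL
    })
    if (is.null(sig)) return(NULL)
    featurize_signal(sig, config, strengthen, source = manifest$file[i],
                     label = manifest$label[i])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable recordings in the manifest")
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Rank features, select, and cross-validate
#'
#' The evaluation stage: scores all 16 features by the three filter criteria,
#' then runs the stratified 10-fold cross-validated logistic classifier on
#' the top-k subset (selection redone inside each training fold unless
#' `selection.select_once` is set).
#'
#' @param features Feature data.frame (from [featurize_corpus()] /
#'   [run_featurize()]) or path to its CSV.
#' @param config A [breathtex_config()].
#' @param out_dir Optional directory for `ranking.csv`, `report.json` and
#'   `report.txt`.
#' @return List with `ranking` (data.frame), `report` (`breath_cv`) and
#'   `selected` (feature names ranked on the full data).
#' @export
run_evaluate <- function(features, config = breathtex_config(),
                         out_dir = NULL) {
  if (is.character(features)) features <- utils::read.csv(features,
                                                          check.names = FALSE)
  missing_cols <- setdiff(c("label", feature_names()), names(features))
  if (length(missing_cols))
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, feature_names()])
  y <- features$label
  ranking <- rank_features(X, y)
  sel_full <- rank_and_select(
    stats::setNames(ranking[[config$selection$criterion]], ranking$feature),
    config$selection$k)
  report <- cross_validate(X, y, folds = config$classifier$folds,
                           seed = config$seed,
                           ridge = config$classifier$ridge,
                           select_k = config$selection$k,
                           select_criterion = config$selection$criterion,
                           select_once = config$selection$select_once)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = as.list(report$counts),
           sensitivity = report$sensitivity,
           specificity = report$specificity,
           accuracy = report$accuracy,
           folds = report$folds, seed = report$seed,
           selected = names(sel_full)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::capture.output(print(report),
                          file = file.path(out_dir, "report.txt"))
  }
  list(ranking = ranking, report = report, selected = names(sel_full))
}
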