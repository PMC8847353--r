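## End-to-end orchestration: phantom generation (or volume ingest),
## preprocessing, thresholding, composition, ROI scoring and statistics,
## driven by one YAML config, with a manifest of every artifact produced.

#' Read an experiment configuration
#'
#' @param path YAML file path.
#' @return Config list with defaults materialized (the stored config copy
#'   in the run manifest carries these explicit values, not hidden
#'   defaults).
#' @export
readExperimentConfig <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  .fill_config_defaults(cfg)
}

.fill_config_defaults <- function(cfg) {
  cfg$seed <- cfg$seed %||% 1L
  cfg$sides <- cfg$sides %||% "anterior"
  cfg$slices_per_region <- cfg$slices_per_region %||% 3L
  cfg$regions_per_sample <- cfg$regions_per_sample %||% 5L
  cfg$depth_crop_mm <- cfg$depth_crop_mm %||% 2.0
  cfg$roi <- utils::modifyList(
    list(n_cancerous = 20L, n_noncancerous = 30L, side_mm = 0.66),
    cfg$roi %||% list())
  cfg$thresholds <- utils::modifyList(
    list(otsu_bins = 256L, fallback_percentile = 0.95),
    cfg$thresholds %||% list())
  cfg$enhancement <- utils::modifyList(
    list(detail_gain = 1.0, edge_threshold = 0.1, radius = 8L),
    cfg$enhancement %||% list())
  cfg$stats <- utils::modifyList(list(dunn_adjust = "holm"),
                                 cfg$stats %||% list())
  cfg
}

#' Validate an experiment configuration
#'
#' Structural and geometric checks: 3-slice regions, ROI size against the
#' phantom extent, channel-file completeness for real-data samples. An
#' empty return value means the config is runnable.
#'
#' @param config config list (from \code{\link{readExperimentConfig}} or
#'   built in code).
#' @return Character vector of findings (empty when valid).
#' @export
validateConfig <- function(config) {
  config <- .fill_config_defaults(config)
  findings <- character(0)
  if (config$slices_per_region != 3L)
    findings <- c(findings, sprintf(
      "slices_per_region is %s; analysis regions are defined as exactly 3 slices",
      config$slices_per_region))
  if (is.null(config$phantom) && is.null(config$samples))
    findings <- c(findings,
                  "config needs either a 'phantom' block or 'samples'")
  if (!is.null(config$phantom)) {
    ext <- config$phantom$extentMM %||% c(5.34, 1.98, 4.71)
    if (config$roi$side_mm > min(ext[2], ext[3]))
      findings <- c(findings, sprintf(
        "ROI side %.2f mm exceeds the in-plane extent (%.2f x %.2f mm)",
        config$roi$side_mm, ext[2], ext[3]))
    scan_step <- (config$phantom$patSpacingMM %||% c(0.193, 0.03, 0.05))[1]
    n_slices <- floor(ext[1] / scan_step)
    if (n_slices < 3L * config$regions_per_sample)
      findings <- c(findings, sprintf(
        "%d scan slices cannot host %d 3-slice regions",
        n_slices, config$regions_per_sample))
  }
  if (!is.null(config$samples)) {
    for (s in config$samples) {
      for (ch in names(s$channels)) {
        if (!file.exists(s$channels[[ch]]))
          findings <- c(findings, sprintf(
            "sample %s: channel file missing: %s",
            s$id %||% "?", s$channels[[ch]]))
      }
    }
  }
  if (!is.null(config[["regions"]])) {
    for (r in config[["regions"]]) {
      if (length(r$slices) != 3L)
        findings <- c(findings, sprintf(
          "region %s has %d slices; exactly 3 are required",
          r$index %||% "?", length(r$slices)))
    }
  }
  findings
}

## Build PhantomParams from the config's phantom block (argument names as
## in phantomParams()).
.params_from_config <- function(block, seed) {
  block <- block %||% list()
  known <- names(formals(phantomParams))
  args <- block[intersect(names(block), known)]
  for (nm in c("extentMM", "patSpacingMM", "ispimSpacingMM",
               "truthSpacingMM", "patBlurSigmaMM"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.numeric(unlist(args[[nm]]))
  for (nm in c("fractions", "nucleiDensity", "noiseSD"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (is.null(args$seed)) args$seed <- seed
  do.call(phantomParams, args)
}

## Downsample a light-sheet channel to the PAT lattice (block mean).
.to_pat_grid <- function(vol, patSpacing) {
  d_dst <- .grid_dim(dim(vol@voxels) * vol@spacing, patSpacing)
  arr <- .resample3(vol@voxels, vol@spacing, patSpacing, d_dst)
  channelVolume(arr, patSpacing, vol@modality, vol@side, vol@wavelengthNM)
}

#' Run the full pipeline
#'
#' Executes phantom generation (or volume ingest), depth cropping,
#' per-slice edge-aware contrast enhancement, channel binarization (Otsu
#' per slice for PAT; region-averaged histogram thresholds for the
#' light-sheet channels, with lipid read as the eosin-dim complement
#' inside tissue), composition-positive maps and percent composition per
#' analysis region, ROI placement and rubric scoring, rank AUC per
#' channel, and the statistical battery. All tabular artifacts are written
#' under \code{outDir} together with a run manifest; re-running with the
#' same config and seed reproduces every numeric output.
#'
#' @param config config list or path to a YAML config.
#' @param outDir output directory (created if needed); defaults to the
#'   config's \code{output_dir} or a temporary directory.
#' @return The run manifest (list), invisibly the same as written to
#'   \code{manifest.json}.
#' @export
runFull <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readExperimentConfig(config)
  config <- .fill_config_defaults(config)
  findings <- validateConfig(config)
  if (length(findings))
    stop("stage 'validate' failed:\n  ", paste(findings, collapse = "\n  "),
         call. = FALSE)
  outDir <- outDir %||% config$output_dir %||% tempfile("patquant_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  manifest <- list(package_version = as.character(utils::packageVersion("patquant")),
                   seed = config$seed, stages = list(), outputs = character(0))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- "failed"
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    res
  }

  seeds <- .derive_seeds(config$seed, 4L)

  ## ---- ingest / phantom -------------------------------------------------
  ph <- stage("phantom", {
    .assert(!is.null(config$phantom),
            "real-data ingest requires 'samples' with existing files; none given")
    params <- .params_from_config(config$phantom, seeds[1])
    generatePhantom(params, sides = config$sides)
  })
  truth <- ph$truth
  params <- ph$params
  patSp <- params@patSpacingMM

  comp_rows <- list(); score_rows <- list(); thr_rows <- list()
  ## ROI counts are totals for the run, spread over sides and regions
  rem_c <- config$roi$n_cancerous
  rem_n <- config$roi$n_noncancerous
  sides_left <- length(config$sides)
  for (side in config$sides) {
    chans <- ph[[side]]
    ## ---- preprocess ----------------------------------------------------
    chans <- stage(paste0("preprocess_", side), {
      crop_of <- function(v)  # volumes shallower than the crop stay whole
        min(config$depth_crop_mm, dim(v@voxels)[2] * v@spacing[2])
      for (nm in c("pat_lipid", "pat_hemoglobin", "pat_off", "ultrasound"))
        chans[[nm]] <- cropToDepth(chans[[nm]], crop_of(chans[[nm]]))
      ## nuclei keep native in-plane resolution (nucleus-scale contrast
      ## does not survive block-meaning to the PAT grid); only the scan
      ## axis is binned onto the PAT slice positions
      nat <- cropToDepth(chans$ispim_nuclei, crop_of(chans$ispim_nuclei))
      n_scan_pat <- dim(chans$pat_lipid@voxels)[1]
      nat_arr <- .bin_axis(nat@voxels, 1L, nat@spacing[1], patSp[1],
                           n_scan_pat)
      chans$ispim_nuclei_native <- channelVolume(
        nat_arr, c(patSp[1], nat@spacing[2:3]), "ispim_nuclei", side, 647)
      for (nm in c("ispim_eosin", "ispim_nuclei"))
        chans[[nm]] <- .to_pat_grid(cropToDepth(chans[[nm]],
                                                crop_of(chans[[nm]])),
                                    patSp)
      g <- config$enhancement$detail_gain
      if (g > 0) {
        for (nm in c("pat_lipid", "pat_hemoglobin", "ispim_eosin",
                     "ispim_nuclei", "ispim_nuclei_native")) {
          arr <- chans[[nm]]@voxels
          for (s in seq_len(dim(arr)[1]))
            arr[s, , ] <- localContrastEnhance(
              arr[s, , ], g, config$enhancement$edge_threshold,
              config$enhancement$radius)
          chans[[nm]] <- channelVolume(arr, chans[[nm]]@spacing,
                                       chans[[nm]]@modality, side,
                                       chans[[nm]]@wavelengthNM)
        }
      }
      chans
    })

    mask <- stage(paste0("tissue_mask_", side), tissueMask(chans$ultrasound))
    ## regions live on the scan slices that contain tissue
    in_tissue <- which(apply(mask, 1, any))
    .assert(length(in_tissue) >= 3L * config$regions_per_sample,
            "too few tissue-bearing slices for the requested regions")
    offset <- min(in_tissue) - 1L
    regions <- lapply(
      layoutRegions(max(in_tissue) - offset, config$regions_per_sample,
                    sampleID = "phantom", side = side),
      function(r) analysisRegion(r@sampleID, r@side, r@regionIndex,
                                 r@sliceIndices + offset))

    ## ---- thresholding --------------------------------------------------
    bins <- stage(paste0("threshold_", side), {
      b <- list()
      for (nm in c("pat_lipid", "pat_hemoglobin"))
        b[[nm]] <- otsuBinarize(chans[[nm]],
                                nBins = config$thresholds$otsu_bins)
      ## light-sheet: one histogram threshold per region (from in-tissue
      ## intensities), averaged across regions
      nat_sp <- chans$ispim_nuclei_native@spacing
      d_nat <- dim(chans$ispim_nuclei_native@voxels)
      mask_nat <- mask[, .nn_index(dim(mask)[2], patSp[2], d_nat[2],
                                   nat_sp[2]),
                       .nn_index(dim(mask)[3], patSp[3], d_nat[3],
                                 nat_sp[3])]
      for (nm in c("ispim_eosin", "ispim_nuclei", "ispim_nuclei_native")) {
        msk <- if (nm == "ispim_nuclei_native") mask_nat else mask
        th <- vapply(regions, function(r) {
          vals <- chans[[nm]]@voxels[r@sliceIndices, , ]
          vals <- vals[msk[r@sliceIndices, , ]]
          withCallingHandlers(
            histogramRegionThreshold(
              vals,
              fallbackPercentile = config$thresholds$fallback_percentile),
            warning = function(w) {
              note("%s %s region %d: %s", side, nm, r@regionIndex,
                   conditionMessage(w))
              invokeRestart("muffleWarning")
            })
        }, numeric(1))
        thr_rows[[paste(side, nm)]] <- data.frame(
          side = side, channel = nm, region = seq_along(th), threshold = th,
          scheme = "histogram_region_avg")
        b[[nm]] <- averageAndApply(th, chans[[nm]])
        if (nm == "ispim_eosin") {
          ## lipid = eosin-dim complement inside tissue
          b[["ispim_lipid"]] <- averageAndApply(th, chans[[nm]],
                                                invert = TRUE)
          b[["ispim_lipid"]]@voxels[!mask] <- 0L
          b[["ispim_lipid"]]@sourceModality <- "ispim_lipid"
        }
      }
      for (nm in c("pat_lipid", "pat_hemoglobin"))
        thr_rows[[paste(side, nm)]] <- data.frame(
          side = side, channel = nm,
          region = seq_along(b[[nm]]@thresholds),
          threshold = b[[nm]]@thresholds, scheme = "otsu_per_slice")
      b
    })

    ## ---- composition ---------------------------------------------------
    analysis_chans <- c("pat_lipid", "pat_hemoglobin", "ispim_lipid",
                        "ispim_nuclei")
    cmaps <- stage(paste0("composition_", side), {
      cm <- list()
      for (r in regions) {
        ## nuclei rubric maps at native light-sheet in-plane resolution
        cm[[sprintf("ispim_nuclei_native_%d", r@regionIndex)]] <-
          compositionPositiveMap(bins$ispim_nuclei_native,
                                 sliceIndices = r@sliceIndices,
                                 regionID = sprintf("%s_r%d", side,
                                                    r@regionIndex))
        for (nm in analysis_chans) {
          cmap <- compositionPositiveMap(bins[[nm]],
                                         sliceIndices = r@sliceIndices,
                                         regionID = sprintf("%s_r%d", side,
                                                            r@regionIndex))
          cm[[sprintf("%s_%d", nm, r@regionIndex)]] <- cmap
          for (k in seq_along(r@sliceIndices)) {
            s <- r@sliceIndices[k]
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              sample = "phantom", side = side, region = r@regionIndex,
              channel = nm, slice = s,
              percent = percentComposition(
                array(bins[[nm]]@voxels[s, , ], c(dim(mask)[2:3])),
                mask[s, , ]))
          }
        }
      }
      cm
    })

    ## ---- ROI scoring ---------------------------------------------------
    stage(paste0("roi_scoring_", side), {
      lab_pat <- .resample3_nn(
        if (side == "posterior") .flip_depth(truth@labels) else truth@labels,
        truth@spacingMM, patSp, .grid_dim(dim(truth@labels) *
                                            truth@spacingMM, patSp))
      regs_with_canc <- which(vapply(regions, function(r)
        any(lab_pat[r@histologySlice, seq_len(dim(mask)[2]), ] ==
              .PHANTOM_CLASSES[["carcinoma"]]), logical(1)))
      .assert(length(regs_with_canc) > 0 || config$roi$n_cancerous == 0,
              "no carcinoma visible in any region plane")
      n_reg <- length(regions)
      roi_seeds_all <- .derive_seeds(seeds[2], 2L * n_reg)
      roi_seeds <- roi_seeds_all[(match(side, .SIDES) - 1L) * n_reg +
                                   seq_len(n_reg)]
      ## even quotas per region; shortfall rolls into later regions/sides
      side_c <- ceiling(rem_c / sides_left)
      side_n <- ceiling(rem_n / sides_left)
      for (i in seq_len(n_reg)) {
        canc_left <- sum(regs_with_canc >= i)
        quota_c <- if (i %in% regs_with_canc && canc_left > 0)
          max(0L, min(ceiling(side_c / canc_left), rem_c)) else 0L
        quota_n <- max(0L, min(ceiling(side_n / (n_reg - i + 1L)), rem_n))
        if (quota_c + quota_n == 0L) next
        r <- regions[[i]]
        plane <- lab_pat[r@histologySlice, seq_len(dim(mask)[2]), ]
        rois <- placeROIs(plane, patSp[2:3], quota_c, quota_n,
                          config$roi$side_mm, seed = roi_seeds[i],
                          bestEffort = TRUE)
        labs <- vapply(rois, function(b) b@label, character(1))
        rem_c <- rem_c - sum(labs == "cancerous")
        side_c <- side_c - sum(labs == "cancerous")
        rem_n <- rem_n - sum(labs == "non_cancerous")
        side_n <- side_n - sum(labs == "non_cancerous")
        for (roi in rois) {
          for (nm in c("pat_lipid", "ispim_lipid", "pat_hemoglobin")) {
            row <- scoreROIVascularLipid(
              cmaps[[sprintf("%s_%d", nm, r@regionIndex)]], roi, patSp[2:3])
            row$side <- side; row$region <- r@regionIndex
            score_rows[[length(score_rows) + 1L]] <- row
          }
          row <- scoreROINuclei(
            cmaps[[sprintf("ispim_nuclei_native_%d", r@regionIndex)]], roi,
            chans$ispim_nuclei_native@spacing[2:3])
          row$side <- side; row$region <- r@regionIndex
          score_rows[[length(score_rows) + 1L]] <- row
        }
      }
      NULL
    })
    sides_left <- sides_left - 1L
  }
  if (rem_c > 0L || rem_n > 0L)
    stop(sprintf(
      "stage 'roi_scoring' failed: placed %d/%d cancerous and %d/%d non-cancerous ROIs",
      config$roi$n_cancerous - max(rem_c, 0L), config$roi$n_cancerous,
      config$roi$n_noncancerous - max(rem_n, 0L),
      config$roi$n_noncancerous), call. = FALSE)

  composition <- do.call(rbind, comp_rows)
  scores <- do.call(rbind, score_rows)
  thresholds <- do.call(rbind, thr_rows)

  ## ---- statistics -------------------------------------------------------
  statres <- stage("stats", {
    out <- list()
    pooled <- function(ch) {
      sub <- composition[composition$channel == ch, ]
      tapply(sub$percent, interaction(sub$side, sub$region, drop = TRUE),
             mean)
    }
    px <- pooled("pat_lipid"); py <- pooled("ispim_lipid")
    out$lipid_regression <- regressionR2(as.numeric(px), as.numeric(py))
    ph_ <- pooled("pat_hemoglobin"); pn <- pooled("ispim_nuclei")
    out$hgb_nuclei_regression <- regressionR2(as.numeric(ph_),
                                              as.numeric(pn))
    ## composition across regions: normality-gated ANOVA route
    lip <- composition[composition$channel == "pat_lipid", ]
    grp <- split(lip$percent, lip$region)
    if (all(lengths(grp) >= 3L)) {
      gate <- normalityGate(grp)
      out$region_anova_transform <- gate$transform
      tr <- switch(gate$transform, log = function(v) log(v),
                   reciprocal = function(v) 1 / v, identity)
      if (gate$transform %in% c("none", "log", "reciprocal"))
        out$region_anova <- anovaTukey(lapply(grp, tr))
      else out$region_kruskal <- kruskalDunn(grp,
                                             config$stats$dunn_adjust)
    }
    ## ROI score comparisons and AUC per channel (low score marks cancer)
    out$roi <- list()
    for (nm in unique(scores$channel)) {
      sub <- scores[scores$channel == nm, ]
      if (length(unique(sub$label)) == 2L &&
          length(unique(sub$score)) > 1L) {
        out$roi[[nm]] <- list(
          kruskal_dunn = kruskalDunn(split(sub$score, sub$label),
                                     config$stats$dunn_adjust),
          auc = aucFromScores(sub$score, sub$label, polarity = "low"),
          mean_cancerous = mean(sub$score[sub$label == "cancerous"]),
          mean_non_cancerous = mean(sub$score[sub$label ==
                                                "non_cancerous"]))
      }
    }
    out
  })

  ## ---- artifacts --------------------------------------------------------
  paths <- list(composition = "region_composition.csv",
                scores = "roi_scores.csv", thresholds = "thresholds.csv",
                stats = "stats.json", config = "config_used.yaml")
  write.csv(composition, file.path(outDir, paths$composition),
            row.names = FALSE)
  write.csv(scores, file.path(outDir, paths$scores), row.names = FALSE)
  write.csv(thresholds, file.path(outDir, paths$thresholds),
            row.names = FALSE)
  jsonlite::write_json(statres, file.path(outDir, paths$stats),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  yaml::write_yaml(config, file.path(outDir, paths$config))
  manifest$config_hash <- unname(tools::md5sum(file.path(outDir,
                                                         paths$config)))
  manifest$warnings <- warnings_log
  manifest$outputs <- c(unlist(paths), "manifest.json")
  manifest$auc <- lapply(statres$roi, `[[`, "auc")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest$tables <- list(composition = composition, scores = scores,
                          thresholds = thresholds)
  manifest$stats <- statres
  manifest$outDir <- outDir
  invisible(manifest)
}
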