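#' Read an image file as 8-bit data
#'
#' Reads PNG/TIFF/JPEG via `EBImage`, reorients to row-major (row, col)
#' matrices, and scales intensities to integers in [0, 255] (higher bit
#' depths are rescaled down). Returns a matrix for single-channel images
#' or an h x w x channels array otherwise.
#'
#' @param path image file path.
#' @return integer matrix or array.
#' @export
readImage8 <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  img <- EBImage::imageData(EBImage::readImage(path))
  img <- round(pmin(pmax(img, 0), 1) * 255)
  if (length(dim(img)) == 2L) t(img)
  else aperm(img, c(2L, 1L, 3L))
}

.writeImg <- function(m, path) {
  EBImage::writeImage(EBImage::Image(t(m / 255)), path)
}

#' Write a binary mask as an 8-bit PNG
#' @param mask a [BinaryMask-class].
#' @param path output path (.png).
#' @export
writeMaskPNG <- function(mask, path) {
  .writeImg(.asMaskMatrix(mask) * 255, path)
  invisible(path)
}

#' Write a score map to disk
#'
#' Raw scores go to a 16-bit TIFF (counts above 65535 are clamped there,
#' never internally); the 8-bit rendering of [renderScores8bit()] goes to
#' PNG.
#'
#' @param scoreMap a [ScoreMap-class].
#' @param path output path; `.tif`/`.tiff` selects the 16-bit raw export,
#'   anything else the 8-bit rendering.
#' @export
writeScoreMap <- function(scoreMap, path) {
  stopifnot(is(scoreMap, "ScoreMap"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- pmin(scoreMap@.Data, 65535L) / 65535
    EBImage::writeImage(EBImage::Image(t(v)), path, bits.per.sample = 16L)
  } else {
    .writeImg(renderScores8bit(scoreMap)@.Data, path)
  }
  invisible(path)
}

#' Write a bridge overlay as an RGB PNG
#'
#' Input foreground in white, bridged pixels in green.
#'
#' @param input a [BinaryMask-class], the pre-bridging mask.
#' @param bridgedMask a [BinaryMask-class] of painted bridge pixels.
#' @param path output path (.png).
#' @export
writeBridgeOverlay <- function(input, bridgedMask, path) {
  m <- .asMaskMatrix(input); b <- .asMaskMatrix(bridgedMask)
  rgb <- array(0, dim = c(ncol(m), nrow(m), 3L)) # EBImage x,y order
  rgb[, , 1] <- t(m * 1); rgb[, , 3] <- t(m * 1)
  rgb[, , 2] <- t(pmax(m, b) * 1)
  EBImage::writeImage(EBImage::Image(rgb, colormode = "Color"), path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The reference defaults: gray-level threshold 100 (strict), score
#' threshold 1, 8-connectivity (radius 3), maxScore 350, maxDist 4,
#' closing last.
#'
#' @return named list of defaults, the schema accepted by [runPipeline()].
#' @export
pipelineDefaults <- function() {
  list(
    mode = "lscf",            # frangi-only | cf | cf+closing | lscf
    input = character(0),
    truth = NULL,
    fov = NULL,
    skip_frangi = FALSE,
    threshold = list(level = 100L, strict = TRUE),
    score_threshold = 1L,
    neighborhood = list(w1 = 1, w2 = 1, p = 1, radius = 3),
    frangi = list(scale_min = 1, scale_max = 8, scale_step = 1,
                  beta = 0.5, gamma = 15, invert = TRUE),
    lscf = list(max_score = 350L, max_dist = 4),
    closing_first = FALSE,
    dump_stages = FALSE,
    out_dir = ".",
    seed = 1L
  )
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML keys override [pipelineDefaults()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(pipelineDefaults()))
  if (length(bad)) stop(sprintf("unknown config key(s): %s",
                                paste(bad, collapse = ", ")))
  .mergeConfig(pipelineDefaults(), cfg)
}

#' Run the segmentation pipeline
#'
#' Executes the staged flow — green channel, vesselness, gray-level
#' threshold, connectivity filtering, score threshold, optional closing —
#' for each input image, writing the final mask (and, on request, every
#' intermediate stage) plus a metrics CSV when ground truth is supplied.
#' The resolved configuration is written beside the outputs, and identical
#' configurations reproduce identical files.
#'
#' @param config configuration list (see [pipelineDefaults()] /
#'   [readPipelineConfig()]). `input` may also be a list of
#'   [BinaryMask-class] objects when `skip_frangi` is TRUE, which skips
#'   image reading (used for in-memory batch runs).
#' @return invisibly, a list with per-image outputs and the metrics table
#'   (or NULL).
#' @export
runPipeline <- function(config) {
  cfg <- .mergeConfig(pipelineDefaults(), config)
  if (!cfg$mode %in% c("frangi-only", "cf", "cf+closing", "lscf"))
    stop(sprintf("invalid mode: %s", cfg$mode))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- NeighborhoodSpec(cfg$neighborhood$w1, cfg$neighborhood$w2,
                           cfg$neighborhood$p, cfg$neighborhood$radius)
  fp <- FrangiParams(cfg$frangi$scale_min, cfg$frangi$scale_max,
                     cfg$frangi$scale_step, cfg$frangi$beta,
                     cfg$frangi$gamma, cfg$frangi$invert)
  lp <- LSCFParams(cfg$lscf$max_score, cfg$lscf$max_dist)
  sMin <- cfg$score_threshold

  inputs <- cfg$input
  fromFiles <- is.character(inputs)
  if (fromFiles && length(inputs) == 0L) stop("no input images given")
  n <- if (fromFiles) length(inputs) else length(inputs)
  ids <- if (fromFiles) sub("\\.[^.]+$", "", basename(inputs))
         else sprintf("input_%02d", seq_len(n))

  truthPaths <- cfg$truth; fovPaths <- cfg$fov
  results <- vector("list", n)
  preds <- list(); truths <- list(); fovs <- NULL
  log <- character(0)
  for (i in seq_len(n)) {
    if (fromFiles) {
      raw <- readImage8(inputs[[i]])
      gray <- extractGreenChannel(raw)
      if (cfg$skip_frangi) {
        binary <- binarize(gray, 0L, strict = TRUE) # nonzero = foreground
      } else {
        ves <- computeVesselness(gray, fp)
        binary <- binarize(ves, cfg$threshold$level, cfg$threshold$strict)
      }
    } else {
      binary <- inputs[[i]]
      gray <- NULL
    }
    res <- switch(cfg$mode,
      "frangi-only" = list(seg = binary),
      "cf" = list(scores = connectivityScores(binary, spec)),
      "cf+closing" = list(seg = cfPlusClosing(binary, spec, sMin,
                                              closingFirst = cfg$closing_first)),
      "lscf" = {
        r <- lsConnectivity(binary, spec, lp, sMin)
        list(scores = scores(r), bridgedMask = bridged(r), seg = segmented(r))
      })
    if (cfg$mode == "cf") res$seg <- thresholdScores(res$scores, sMin)
    stem <- file.path(cfg$out_dir, ids[i])
    writeMaskPNG(res$seg, paste0(stem, "_seg.png"))
    if (isTRUE(cfg$dump_stages)) {
      if (!is.null(gray)) .writeImg(gray@.Data, paste0(stem, "_green.png"))
      if (fromFiles && !cfg$skip_frangi)
        .writeImg(ves@.Data, paste0(stem, "_vesselness.png"))
      writeMaskPNG(binary, paste0(stem, "_binary.png"))
      if (!is.null(res$scores)) {
        writeScoreMap(res$scores, paste0(stem, "_scores.tif"))
        writeScoreMap(res$scores, paste0(stem, "_scores8.png"))
      }
      if (!is.null(res$bridgedMask))
        writeBridgeOverlay(binary, res$bridgedMask, paste0(stem, "_bridged.png"))
    }
    log <- c(log, sprintf("[%s] mode=%s foreground=%d", ids[i], cfg$mode,
                          sum(res$seg@.Data)))
    if (!is.null(truthPaths)) {
      tr <- if (is.character(truthPaths)) {
        binarize(extractGreenChannel(readImage8(truthPaths[[i]])), 0L)
      } else truthPaths[[i]]
      preds[[length(preds) + 1L]] <- res$seg
      truths[[length(truths) + 1L]] <- tr
      if (!is.null(fovPaths)) {
        f <- if (is.character(fovPaths)) {
          binarize(extractGreenChannel(readImage8(fovPaths[[i]])), 0L)
        } else fovPaths[[i]]
        fovs <- c(fovs, list(f))
      }
    }
    results[[i]] <- res
  }
  metrics <- NULL
  if (length(preds)) {
    metrics <- metricsTable(preds, truths, fovs, ids = ids[seq_along(preds)])
    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  cfgOut <- cfg
  cfgOut$out_dir <- "." # parameters, not location: keeps re-runs comparable
  if (!fromFiles) cfgOut$input <- sprintf("<in-memory:%d masks>", n)
  if (!is.character(cfgOut$truth) && !is.null(cfgOut$truth))
    cfgOut$truth <- "<in-memory>"
  if (!is.character(cfgOut$fov) && !is.null(cfgOut$fov))
    cfgOut$fov <- "<in-memory>"
  yaml::write_yaml(cfgOut, file.path(cfg$out_dir, "config_resolved.yaml"))
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  invisible(list(results = results, metrics = metrics, config = cfg))
}
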