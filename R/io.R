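# Reading mask sequences (directory of PNG/TIFF or multi-page TIFF) and
# writing per-frame tables / summaries.

#' Construct a mask sequence
#'
#' @param frames List of binary matrices (all the same shape; any nonzero
#'   pixel is foreground).
#' @param spacing Pixel spacing in mm/px (isotropic).
#' @param frame_rate Optional frame rate in Hz (metadata only).
#' @return Object of class `mask_sequence`.
#' @export
mask_sequence <- function(frames, spacing = 1, frame_rate = NULL) {
  if (length(frames) < 2L)
    dtw_abort("empty_input", "a mask sequence needs at least 2 frames")
  dims <- vapply(frames, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0L)
    dtw_abort("shape_mismatch",
              sprintf("frame %d has shape %dx%d, expected %dx%d", bad[1],
                      dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1]))
  frames <- lapply(frames, function(f) {
    m <- matrix(as.integer(f != 0), nrow(f), ncol(f))
    m
  })
  structure(list(frames = frames, spacing = spacing, frame_rate = frame_rate),
            class = "mask_sequence")
}

#' @export
length.mask_sequence <- function(x) length(x$frames)

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("mask_sequence: %d frames of %dx%d px, spacing %.3g mm/px\n",
              length(x$frames), d[1], d[2], x$spacing))
  invisible(x)
}

read_frame_file <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(img != 0), nrow(img), ncol(img))
}

#' Read a mask sequence from disk
#'
#' @param path Directory of single-frame PNG/TIFF files (ordered by natural
#'   sort of their names) or a single multi-page TIFF.
#' @param layout `"auto"` (directory vs. file), `"dir"`, or `"tiff"`.
#' @param spacing Pixel spacing in mm/px.
#' @param frame_rate Optional frame rate in Hz.
#' @return A [mask_sequence()].
#' @export
read_mask_sequence <- function(path, layout = c("auto", "dir", "tiff"),
                               spacing = 1, frame_rate = NULL) {
  layout <- match.arg(layout)
  if (layout == "auto") layout <- if (dir.exists(path)) "dir" else "tiff"
  if (layout == "dir") {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      dtw_abort("empty_input", sprintf("no PNG/TIFF frames found in %s", path))
    files <- files[natural_order(basename(files))]
    frames <- lapply(files, read_frame_file)
  } else {
    if (!file.exists(path))
      dtw_abort("empty_input", sprintf("file not found: %s", path))
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(pages, function(img) {
      if (length(dim(img)) == 3L) img <- img[, , 1]
      matrix(as.integer(img != 0), nrow(img), ncol(img))
    })
  }
  mask_sequence(frames, spacing = spacing, frame_rate = frame_rate)
}

#' Write a mask sequence as numbered PNG frames
#'
#' @param masks A [mask_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"frame_"`).
#' @return Invisibly, the written file paths.
#' @export
write_mask_sequence <- function(masks, dir, prefix = "frame_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(masks$frames))
  for (i in seq_along(masks$frames)) {
    paths[i] <- file.path(dir, sprintf("%s%04d.png", prefix, i - 1L))
    png::writePNG(matrix(as.numeric(masks$frames[[i]]),
                         nrow(masks$frames[[i]])), paths[i])
  }
  invisible(paths)
}

#' Write strain results to disk
#'
#' Writes `strain.csv` (one row per frame: cavity area, centerline length,
#' global and segmental strain, cycle id, ED flag) and `summary.json`
#' (peak strain overall, per cycle and per segment, ED/ES indices, config).
#'
#' @param result A `dtw_strain` result.
#' @param outdir Output directory (created if missing).
#' @param diagnostics Also write `keypoints.csv` and per-frame block border
#'   coordinates (`borders.csv`)? Default `FALSE`.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir, diagnostics = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$curve$table
  seg <- result$regional$curves
  df <- data.frame(
    frame = tab$frame,
    cavity_area = result$cavity$areas,
    centerline_length = tab$length,
    strain_global = tab$strain,
    seg[, -1, drop = FALSE],
    cycle_id = tab$cycle,
    is_ed = tab$is_ed,
    check.names = FALSE
  )
  csv <- file.path(outdir, "strain.csv")
  write.csv(df, csv, row.names = FALSE)
  summary <- list(
    schema_version = "1.0",
    n_frames = nrow(tab),
    spacing_mm_per_px = result$config$spacing,
    ed_frames = result$curve$ed_frames,
    es_frame = result$cavity$es,
    peak_strain = result$curve$peak_signed,
    peak_strain_pct = 100 * result$curve$peak,
    cycle_peak_strain = result$curve$cycle_peaks,
    segment_peak_strain = as.list(result$regional$peaks),
    config = result$config
  )
  js <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(csv, js)
  if (diagnostics) {
    kp <- file.path(outdir, "keypoints.csv")
    write.csv(result$keypoints, kp, row.names = FALSE)
    bt <- do.call(rbind, lapply(seq_along(result$partitions), function(f) {
      bd <- result$partitions[[f]]$borders
      data.frame(frame = f, border_id = seq_along(bd),
                 endo_x = vapply(bd, function(b) b["endo", 1], 0),
                 endo_y = vapply(bd, function(b) b["endo", 2], 0),
                 epi_x = vapply(bd, function(b) b["epi", 1], 0),
                 epi_y = vapply(bd, function(b) b["epi", 2], 0))
    }))
    bc <- file.path(outdir, "borders.csv")
    write.csv(bt, bc, row.names = FALSE)
    paths <- c(paths, kp, bc)
  }
  invisible(paths)
}
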