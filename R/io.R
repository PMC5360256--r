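#' Write a recording as TSV plus JSON metadata sidecar
#'
#' The time series goes to `<prefix>.tsv` (columns `time_s`, `v_defl_V`,
#' `z_servo_nm`, `fnum`, tab-separated, with unit header comments) and the
#' metadata, including the acquisition schedule, to `<prefix>_meta.json`.
#'
#' @param recording An `afm_recording`.
#' @param prefix Output path prefix.
#' @return The TSV path, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "afm_recording"))
  tsv <- paste0(prefix, ".tsv")
  con <- file(tsv, "w")
  writeLines(c("# AFM force-clamp recording",
               "# columns: time_s [s], v_defl_V [V], z_servo_nm [nm], fnum [frame/1000]"),
             con)
  utils::write.table(
    data.frame(time_s = recording$times, v_defl_V = recording$v_defl,
               z_servo_nm = recording$z_servo, fnum = recording$fnum),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  meta <- recording$meta
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(tsv)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `afm_recording`.
#' @export
read_recording <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  mj <- paste0(prefix, "_meta.json")
  if (!file.exists(tsv) || !file.exists(mj))
    stop("recording files not found under prefix '", prefix, "'")
  d <- utils::read.table(tsv, header = TRUE, sep = "\t", comment.char = "#")
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  if (!is.null(meta$schedule)) meta$schedule <- as.data.frame(meta$schedule)
  structure(list(times = d$time_s, v_defl = d$v_defl_V,
                 z_servo = d$z_servo_nm, fnum = d$fnum, meta = meta),
            class = "afm_recording")
}

#' Write a table (events, segments, ground truth) as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comment Optional header comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  df <- as.data.frame(x)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Write a TIRF stack as multi-page TIFF
#'
#' Counts are stored as 16-bit integers; values are clipped to
#' `[0, 65535]`.
#'
#' @param stack A `tirf_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_tirf_stack <- function(stack, path) {
  stopifnot(inherits(stack, "tirf_stack"))
  nf <- dim(stack$frames)[3]
  pages <- lapply(seq_len(nf), function(f)
    pmin(pmax(stack$frames[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF into a stack array
#'
#' @param path TIFF path.
#' @param frame_rate Frame rate used to reconstruct the time base (Hz).
#' @param pixel_size_nm Pixel size (nm).
#' @return A `tirf_stack` with counts on the original 16-bit scale.
#' @export
read_tirf_stack <- function(path, frame_rate = 10, pixel_size_nm = 160) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * 65535
  structure(list(frames = frames,
                 frame_times = (seq_along(pages) - 1) / frame_rate,
                 pixel_size_nm = pixel_size_nm,
                 center_px = c(floor(ncol(pages[[1]]) / 2),
                               floor(nrow(pages[[1]]) / 2))),
            class = "tirf_stack")
}

# deterministic hash of a string (md5 via a temporary file), for provenance
config_hash <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
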