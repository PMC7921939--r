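#' A 4D fluorescence record
#'
#' Container for an ordered list of 3D intensity arrays (axis order z, y, x)
#' with physical voxel spacing and per-frame timestamps.
#'
#' @param frames list of 3D numeric arrays, all of identical dimension.
#' @param spacing named numeric vector `c(z=, y=, x=)` in micrometres.
#' @param timestamps frame acquisition times in seconds.
#' @param meta optional named list of free-form metadata.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(frames, spacing, timestamps, meta = list()) {
  stopifnot(is.list(frames), length(frames) >= 1,
            length(spacing) == 3, all(spacing > 0),
            length(timestamps) == length(frames))
  dm <- dim(frames[[1]])
  stopifnot(length(dm) == 3)
  for (f in frames) stopifnot(identical(dim(f), dm))
  names(spacing) <- c("z", "y", "x")
  structure(list(frames = frames, spacing = spacing,
                 timestamps = as.numeric(timestamps), meta = meta),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  dm <- dim(x$frames[[1]])
  cat(sprintf("volume_series: %d frame(s) of %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g um\n",
              length(x$frames), dm[1], dm[2], dm[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
length.volume_series <- function(x) length(x$frames)
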