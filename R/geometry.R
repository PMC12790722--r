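#' Electrode grid geometry
#'
#' Describes the regular lattice of recording/stimulation channels of a
#' high-density microelectrode array (HD-MEA). The default is the 64 x 64
#' grid of 4,096 channels used throughout the package, with a 60 um pitch.
#' Channel ids are 1-based and row-major: channel `c` sits at row
#' `(c - 1) %/% n_cols + 1`, column `(c - 1) %% n_cols + 1`.
#'
#' @param n_rows,n_cols Grid dimensions (channels).
#' @param pitch Electrode pitch in micrometres.
#' @return A `grid_geometry` object.
#' @examples
#' g <- grid_geometry()
#' n_channels(g)
#' head(channel_positions(g))
#' @export
grid_geometry <- function(n_rows = 64L, n_cols = 64L, pitch = 60) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, is.numeric(pitch), pitch > 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = as.numeric(pitch)),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param geometry A `grid_geometry`.
#' @export
n_channels <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  geometry$n_rows * geometry$n_cols
}

#' @rdname grid_geometry
#' @param channels Optional integer vector of channel ids; default all.
#' @return `channel_positions()` returns a data frame with columns
#'   `channel`, `x`, `y` (micrometres).
#' @export
channel_positions <- function(geometry, channels = NULL) {
  stopifnot(inherits(geometry, "grid_geometry"))
  n <- n_channels(geometry)
  if (is.null(channels)) channels <- seq_len(n)
  channels <- as.integer(channels)
  if (any(channels < 1L | channels > n))
    stop("channel id outside [1, ", n, "]")
  col <- (channels - 1L) %% geometry$n_cols
  row <- (channels - 1L) %/% geometry$n_cols
  data.frame(channel = channels,
             x = col * geometry$pitch,
             y = row * geometry$pitch)
}

#' Euclidean distances between channels
#'
#' @param geometry A `grid_geometry`.
#' @param from,to Channel id vectors (recycled against each other).
#' @return Distances in micrometres.
#' @export
channel_distance <- function(geometry, from, to) {
  p1 <- channel_positions(geometry, from)
  p2 <- channel_positions(geometry, to)
  sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d channels, pitch %g um\n",
              x$n_rows, x$n_cols, x$pitch))
  invisible(x)
}
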