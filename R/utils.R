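`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_vec3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

#' Voxel-to-physical scaling
#'
#' Per-axis nanometre-per-voxel factors applied once, at load time. Serial
#' sectioning compresses tissue anisotropically, so EM coordinates are
#' frequently stored in voxel units with a per-axis physical calibration
#' (for the reference volume, 26 nm x 20 nm x 40 nm).
#'
#' @param scale Numeric length-3 vector of nm-per-unit factors (x, y, z),
#'   all strictly positive. The default `c(1, 1, 1)` leaves coordinates
#'   untouched (already in nm).
#' @return An object of class `voxel_scaling`.
#' @examples
#' voxel_scaling(c(26, 20, 40))
#' @export
voxel_scaling <- function(scale = c(1, 1, 1)) {
  scale <- as.numeric(scale)
  if (!is_vec3(scale) || any(scale <= 0)) {
    stopf("voxel scaling must be 3 finite positive numbers, got: %s",
          paste(scale, collapse = ", "))
  }
  structure(list(scale = scale), class = "voxel_scaling")
}

#' @export
print.voxel_scaling <- function(x, ...) {
  cat(sprintf("<voxel_scaling> %g x %g x %g nm per unit\n",
              x$scale[1], x$scale[2], x$scale[3]))
  invisible(x)
}

apply_scaling <- function(xyz, scaling) {
  stopifnot(inherits(scaling, "voxel_scaling"))
  sweep(as.matrix(xyz), 2L, scaling$scale, `*`)
}

# Deterministic quasi-uniform directions on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}
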