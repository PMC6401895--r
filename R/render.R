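#' Render a field to a PNG file
#'
#' Writes a colour-mapped raster of a field directly as a PNG (no graphics
#' device required), for quick inspection of snapshots: the phase field,
#' solute fraction, temperature, volumetric flow rate, density, viscosity,
#' speed or vorticity panels of a run.
#'
#' @param state a `field_state` (or a snapshot list from [load_snapshot()]).
#' @param file output PNG path.
#' @param field field name, see [field_matrix()].
#' @param palette a [grDevices::hcl.colors()] palette name.
#' @param zlim optional fixed colour range (default: data range).
#' @param params a [material_params()] object for derived fields.
#' @return `file`, invisibly.
#' @export
render_field <- function(state, file, field = "phi_c", palette = "viridis",
                         zlim = NULL, params = material_params()) {
  if (!inherits(state, "field_state") && is.list(state) &&
      !is.null(state$state))
    state <- state$state
  m <- field_matrix(state, field, params)
  if (is.null(zlim)) zlim <- range(m)
  if (zlim[2] <= zlim[1]) zlim[2] <- zlim[1] + 1
  idx <- pmin(pmax(1L + floor(255 * (m - zlim[1]) / (zlim[2] - zlim[1])),
                   1L), 256L)
  pal <- grDevices::hcl.colors(256, palette)
  rgb <- grDevices::col2rgb(pal) / 255
  n <- nrow(m)
  img <- array(0, dim = c(n, n, 3))
  # flip rows so y increases upward in the image
  flip <- n:1
  img[, , 1] <- matrix(rgb[1, idx], n, n)[flip, ]
  img[, , 2] <- matrix(rgb[2, idx], n, n)[flip, ]
  img[, , 3] <- matrix(rgb[3, idx], n, n)[flip, ]
  png::writePNG(img, file)
  invisible(file)
}
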