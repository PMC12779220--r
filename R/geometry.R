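#' Layered slab geometry for the transient diffusion problem
#'
#' Describes the stack of one or two layers sitting on the glass dish bottom
#' (z = 0, zero flux) with the gas-controlled surface on top. Heights are in
#' mm measured from the dish bottom; diffusivities in cm^2 s^-1.
#'
#' @param thickness_mm numeric vector (length 1 or 2) of layer thicknesses,
#'   ordered from the dish bottom upward.
#' @param D_cm2_s diffusivities of the layers, same length and order.
#' @param probe_height_mm height of the probe sensing spot above the dish
#'   bottom (default 1.8, the needle-tip offset of the measurement rig).
#' @param dish_diameter_mm dish diameter (default 50).
#' @return A `layer_stack` object.
#' @seealso [geometry_preset()] for the standard water and gel geometries.
#' @examples
#' layer_stack(c(3.5, 1.5), c(2.4e-5, 3.1e-5))
#' @export
layer_stack <- function(thickness_mm, D_cm2_s, probe_height_mm = 1.8,
                        dish_diameter_mm = 50) {
  n <- length(thickness_mm)
  if (n < 1 || n > 2) stop("1 or 2 layers supported", call. = FALSE)
  if (length(D_cm2_s) != n)
    stop("one diffusivity per layer required", call. = FALSE)
  if (any(thickness_mm <= 0)) stop("layer thicknesses must be > 0", call. = FALSE)
  if (any(D_cm2_s <= 0)) stop("diffusivities must be > 0", call. = FALSE)
  H <- sum(thickness_mm)
  if (probe_height_mm < 0 || probe_height_mm > H)
    stop("probe height must lie within the stack", call. = FALSE)
  if (dish_diameter_mm <= 0) stop("dish diameter must be > 0", call. = FALSE)
  structure(list(thickness_mm = as.numeric(thickness_mm),
                 D_cm2_s = as.numeric(D_cm2_s),
                 probe_height_mm = probe_height_mm,
                 dish_diameter_mm = dish_diameter_mm),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat("Layer stack (bottom to top):\n")
  for (i in seq_along(x$thickness_mm))
    cat(sprintf("  layer %d: %.3g mm, D = %.3g cm^2/s\n",
                i, x$thickness_mm[i], x$D_cm2_s[i]))
  cat(sprintf("  probe at %.3g mm; dish diameter %.3g mm\n",
              x$probe_height_mm, x$dish_diameter_mm))
  invisible(x)
}

#' Standard measurement geometries
#'
#' `"water"`: a single 4 mm liquid column (the liquid-validation geometry).
#' `"gel"`: a 3.5 mm gel slab under a 1.5 mm top-up medium layer; the medium
#' takes the diffusivity of water at 37 C unless overridden. The probe sits
#' 1.8 mm above the dish bottom in both.
#'
#' @param name `"water"` or `"gel"`.
#' @param D_cm2_s diffusivity of the (single or gel) layer; defaults to
#'   `registry$D_water_37C` for `"water"` and must be supplied for `"gel"`.
#' @param D_medium_cm2_s diffusivity of the top-up medium (gel preset only);
#'   defaults to `registry$D_water_37C`.
#' @param registry an [o2_constants()] registry.
#' @return A [layer_stack()].
#' @examples
#' geometry_preset("water")
#' geometry_preset("gel", D_cm2_s = 2.4e-5)
#' @export
geometry_preset <- function(name = c("water", "gel"), D_cm2_s = NULL,
                            D_medium_cm2_s = NULL,
                            registry = o2_constants()) {
  name <- match.arg(name)
  if (name == "water") {
    if (is.null(D_cm2_s)) D_cm2_s <- registry$D_water_37C
    layer_stack(4, D_cm2_s)
  } else {
    if (is.null(D_cm2_s))
      stop("the gel preset needs the gel diffusivity", call. = FALSE)
    if (is.null(D_medium_cm2_s)) D_medium_cm2_s <- registry$D_water_37C
    layer_stack(c(3.5, 1.5), c(D_cm2_s, D_medium_cm2_s))
  }
}
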