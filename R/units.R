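# Unit conventions used throughout: masses in ng, volumes in m^3, areas in
# m^2, flows in m^3/h, elapsed time in h (series timestamps in s). Number
# concentrations are 1/cm^3, mass concentrations ng/m^3. Conversion happens
# only at I/O boundaries; internal computation stays in these units.

#' Material constants for titanium dioxide accounting
#'
#' Fixed IUPAC standard atomic masses used to convert gravimetric titanium
#' mass into the corresponding TiO2 mass. The TiO2 molar mass is derived as
#' Ti + 2 O, never stored independently, so the set is internally consistent
#' by construction.
#'
#' @return A named list with `molar_mass_ti`, `molar_mass_o` and
#'   `molar_mass_tio2` (g/mol), plus `ti_to_tio2_factor`.
#' @examples
#' material_constants()$ti_to_tio2_factor # ~ 1.6685
#' @export
material_constants <- function() {
  ti <- 47.867
  o <- 15.999
  tio2 <- ti + 2 * o
  list(
    molar_mass_ti = ti,
    molar_mass_o = o,
    molar_mass_tio2 = tio2,
    ti_to_tio2_factor = tio2 / ti
  )
}

#' Convert a titanium mass to the equivalent TiO2 mass
#'
#' Gravimetric filter analysis reports elemental Ti; release factors are
#' expressed as TiO2. The conversion is the ratio of molar masses
#' (TiO2/Ti ~ 1.6685), applied element-wise.
#'
#' @param mass_ti Ti mass in ng (vectorised, must be non-negative).
#' @return TiO2 mass in ng.
#' @seealso [tio2_to_ti()] for the inverse.
#' @examples
#' ti_to_tio2(1) # 1.6685 ng TiO2 per ng Ti
#' @export
ti_to_tio2 <- function(mass_ti) {
  if (any(mass_ti < 0, na.rm = TRUE)) {
    abort("`mass_ti` must be non-negative.")
  }
  mass_ti * material_constants()$ti_to_tio2_factor
}

#' @rdname ti_to_tio2
#' @param mass_tio2 TiO2 mass in ng (non-negative).
#' @export
tio2_to_ti <- function(mass_tio2) {
  if (any(mass_tio2 < 0, na.rm = TRUE)) {
    abort("`mass_tio2` must be non-negative.")
  }
  mass_tio2 / material_constants()$ti_to_tio2_factor
}

#' Round to a number of significant figures, half away from zero
#'
#' Reproduces reported-table precision: `signif()` rounds half to even,
#' whereas printed exposure tables conventionally round half away from zero
#' (e.g. 4422 at two significant figures prints as 4400, 0.003293 at one as
#' 0.003).
#'
#' @param x Numeric vector.
#' @param digits Number of significant figures (>= 1).
#' @return `x` rounded to `digits` significant figures.
#' @examples
#' round_sig(4422, 2)
#' round_sig(0.003293, 1)
#' @export
round_sig <- function(x, digits = 2) {
  if (length(digits) != 1 || is.na(digits) || digits < 1) {
    abort("`digits` must be a single integer >= 1.")
  }
  out <- x
  nz <- !is.na(x) & is.finite(x) & x != 0
  if (any(nz)) {
    p <- ceiling(log10(abs(x[nz]))) - digits
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) / 10^p + 0.5) * 10^p
  }
  out
}

# exact scalar factors to the internal units (ng, m3, m2, h, s for series)
.unit_factors <- list(
  volume = c("m3" = 1, "L" = 1e-3, "l" = 1e-3, "cm3" = 1e-6),
  time = c("h" = 1, "s" = 1 / 3600, "min" = 1 / 60, "d" = 24),
  flow = c("m3/h" = 1, "m3/s" = 3600, "m3/min" = 60, "L/min" = 0.06),
  mass = c("ng" = 1, "ug" = 1e3, "mg" = 1e6, "g" = 1e9),
  mass_conc = c("ng/m3" = 1, "ug/m3" = 1e3, "mg/m3" = 1e6),
  area = c("m2" = 1, "cm2" = 1e-4)
)

#' Convert between declared units of one physical quantity
#'
#' Exact scalar conversions between the units the package accepts at its I/O
#' boundaries. Round-trip conversion is the identity to within 1e-12
#' relative.
#'
#' @param x Numeric vector.
#' @param from,to Unit labels, e.g. `"L"` and `"m3"`.
#' @param quantity One of `"volume"`, `"time"`, `"flow"`, `"mass"`,
#'   `"mass_conc"`, `"area"`.
#' @return `x` expressed in `to` units.
#' @examples
#' convert_units(220, "L", "m3") # 0.22 m3 chamber
#' @export
convert_units <- function(x, from, to, quantity = "volume") {
  fac <- .unit_factors[[quantity]]
  if (is.null(fac)) {
    abort(paste0("Unknown quantity `", quantity, "`."))
  }
  if (!from %in% names(fac) || !to %in% names(fac)) {
    abort(paste0(
      "Unknown unit for ", quantity, ": expected one of ",
      paste(names(fac), collapse = ", "), "."
    ))
  }
  x * unname(fac[from]) / unname(fac[to])
}

# Volume expressed in the unit that makes rate / volume match the state
# unit: cm^3 when concentrations are number per cm^3, m^3 for mass per m^3.
state_volume <- function(volume_m3, metric = c("number", "mass")) {
  metric <- match.arg(metric)
  if (metric == "number") volume_m3 * 1e6 else volume_m3
}
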