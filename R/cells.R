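#' Compartment specification
#'
#' One cylindrical compartment of a model neuron.  `z_offset` is the position
#' of the compartment center along the vertical (pia-directed) axis relative
#' to the soma center; apical compartments lie above the soma (positive
#' offset), basal and oblique dendrites below (negative offset).
#'
#' @param name One of `"basal"`, `"oblique"`, `"soma"`, `"apical_trunk"`,
#'   `"apical_tuft"`.
#' @param length,diameter Cylinder dimensions, micrometers.
#' @param z_offset Center offset along the vertical axis, micrometers.
#' @param channels Named numeric vector of peak conductance densities
#'   (S/cm^2); recognised names are `leak`, `na`, `kdr`, `ca`, `kca`.
#' @return A `compartment_spec` object.
#' @export
compartment_spec <- function(name, length, diameter, z_offset, channels) {
  allowed <- c("basal", "oblique", "soma", "apical_trunk", "apical_tuft")
  if (!name %in% allowed)
    stop("unknown compartment name: ", name)
  if (length <= 0 || diameter <= 0)
    stop("compartment '", name, "' must have positive length and diameter")
  if (name %in% c("apical_trunk", "apical_tuft") && z_offset <= 0)
    stop("apical compartments must have positive z_offset")
  if (name %in% c("basal", "oblique") && z_offset >= 0)
    stop("basal/oblique compartments must have negative z_offset")
  known <- c("leak", "na", "kdr", "ca", "kca")
  bad <- setdiff(names(channels), known)
  if (length(bad) > 0)
    stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  if (!"leak" %in% names(channels) || channels[["leak"]] <= 0)
    stop("every compartment needs a positive leak density")
  structure(list(name = name, length = length, diameter = diameter,
                 z_offset = z_offset, channels = channels),
            class = "compartment_spec")
}

#' Cell specification
#'
#' @param cell_class One of `"L23_PN"`, `"L5_PN"`, `"L23_basket"`,
#'   `"L5_basket"`.
#' @param compartments List of [compartment_spec()] objects.
#' @param spike_threshold Somatic spike-detection threshold, mV.
#' @param resting_potential Initial membrane potential, mV.
#' @return A `cell_spec` object.
#' @export
cell_spec <- function(cell_class, compartments, spike_threshold = 0,
                      resting_potential = -65) {
  classes <- c("L23_PN", "L5_PN", "L23_basket", "L5_basket")
  if (!cell_class %in% classes) stop("unknown cell class: ", cell_class)
  nm <- vapply(compartments, `[[`, character(1), "name")
  if (grepl("_PN$", cell_class)) {
    if (length(compartments) < 4 || !"apical_tuft" %in% nm)
      stop("pyramidal cells need >= 4 compartments including an apical tuft")
  } else {
    if (length(compartments) != 1 || nm != "soma")
      stop("basket cells have exactly one somatic compartment")
  }
  if (anyDuplicated(nm)) stop("duplicate compartment names")
  if (!"soma" %in% nm) stop("a soma compartment is required")
  structure(list(cell_class = cell_class, compartments = compartments,
                 spike_threshold = spike_threshold,
                 resting_potential = resting_potential),
            class = "cell_spec")
}

# total apical extent (trunk + tuft length) of a pyramidal spec
.apical_extent <- function(spec) {
  sum(vapply(spec$compartments, function(cm)
    if (cm$name %in% c("apical_trunk", "apical_tuft")) cm$length else 0,
    numeric(1)))
}

#' Default cell specifications
#'
#' The four cell classes of the reduced column.  Layer-V pyramidal cells are
#' given an apical extent of 1000 um against 300 um for layer II/III, and
#' carry a high-voltage-activated calcium channel plus a calcium-dependent
#' potassium channel on the apical trunk and tuft, supporting the
#' calcium-dependent somatic bursting that distinguishes them from
#' layer-II/III cells.  Exact geometry and densities are package defaults
#' (only relative extent and orientation shape the dipole qualitatively).
#'
#' @return Named list of [cell_spec()] objects.
#' @export
default_cell_specs <- function() {
  dend <- c(leak = 4e-5, na = 0.015, kdr = 0.01)
  # low-Na / high-K apical tree keeps tuft input subthreshold in L2/3 cells
  l23_apical <- c(leak = 4e-5, na = 0.004, kdr = 0.06)
  soma23 <- c(leak = 4e-5, na = 0.15, kdr = 0.1)
  # higher delayed-rectifier density at the L5 soma favors passive dipole
  # build-up over early firing; the leaky thick trunk routes basal charge
  # up the column
  soma5 <- c(leak = 4e-5, na = 0.15, kdr = 0.2)
  l5_trunk <- c(leak = 3e-4, na = 0.015, kdr = 0.01, ca = 0.002, kca = 0.001)
  l5_tuft <- c(dend, ca = 0.008, kca = 0.003)
  bsk <- c(leak = 1e-4, na = 0.2, kdr = 0.15)
  list(
    L23_PN = cell_spec("L23_PN", list(
      compartment_spec("basal", 250, 4, -137.5, dend),
      compartment_spec("oblique", 200, 3, -100, dend),
      compartment_spec("soma", 25, 25, 0, soma23),
      compartment_spec("apical_trunk", 200, 2.5, 112.5, l23_apical),
      compartment_spec("apical_tuft", 100, 2, 262.5, l23_apical))),
    L5_PN = cell_spec("L5_PN", list(
      compartment_spec("basal", 500, 8, -267.5, dend),
      compartment_spec("oblique", 300, 5, -150, dend),
      compartment_spec("soma", 35, 35, 0, soma5),
      compartment_spec("apical_trunk", 800, 10, 417.5, l5_trunk),
      compartment_spec("apical_tuft", 200, 4, 917.5, l5_tuft))),
    L23_basket = cell_spec("L23_basket", list(
      compartment_spec("soma", 20, 20, 0, bsk))),
    L5_basket = cell_spec("L5_basket", list(
      compartment_spec("soma", 20, 20, 0, bsk)))
  )
}

# membrane area in cm^2, capacitance in nF (1 uF/cm^2), absolute channel
# conductances in uS for one compartment
.comp_electrical <- function(cm) {
  area <- pi * cm$diameter * cm$length * 1e-8        # um^2 -> cm^2
  dens <- function(label) {
    d <- cm$channels[label]
    if (is.na(d)) 0 else unname(d)
  }
  list(area = area,
       C = 1.0 * area * 1e3,                         # nF
       gL = dens("leak") * area * 1e6,               # uS
       gNa = dens("na") * area * 1e6,
       gK = dens("kdr") * area * 1e6,
       gCa = dens("ca") * area * 1e6,
       gKCa = dens("kca") * area * 1e6)
}

# axial half-resistance of a compartment (MOhm), Ra in Ohm*cm
.half_axial_mohm <- function(cm, ra = 100) {
  l_cm <- cm$length * 1e-4 / 2
  d_cm <- cm$diameter * 1e-4
  ra * 4 * l_cm / (pi * d_cm^2) * 1e-6
}

#' Initialize per-cell state
#'
#' Sets every compartment to the spec's resting potential, every gating
#' variable to its steady state at that voltage, and the calcium pool (where
#' present) to its baseline concentration.
#'
#' @param spec A [cell_spec()].
#' @param kinetics Channel kinetics, see [default_channel_kinetics()].
#' @return List with `v` (mV per compartment), gating variables `m`, `h`,
#'   `n`, `p`, and `ca` (mM, `NA` for compartments without a calcium pool).
#' @export
build_cell <- function(spec, kinetics = default_channel_kinetics()) {
  stopifnot(inherits(spec, "cell_spec"))
  nm <- vapply(spec$compartments, `[[`, character(1), "name")
  v <- stats::setNames(rep(spec$resting_potential, length(nm)), nm)
  has_ca <- vapply(spec$compartments, function(cm)
    !is.na(cm$channels["ca"]) && cm$channels["ca"] > 0, logical(1))
  list(v = v,
       m = stats::setNames(kinetics$na_m(v)$inf, nm),
       h = stats::setNames(kinetics$na_h(v)$inf, nm),
       n = stats::setNames(kinetics$k_n(v)$inf, nm),
       p = stats::setNames(kinetics$ca_p(v)$inf, nm),
       ca = stats::setNames(ifelse(has_ca, kinetics$ca0, NA_real_), nm))
}
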