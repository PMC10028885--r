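#' Construct the reduced two-layer column
#'
#' Builds a network of pyramidal (PN) and basket cells laid out on a
#' horizontal grid, two layers stacked along the vertical axis.  The default
#' column has 100 PNs per layer on a ten-by-ten grid at 100-um pitch plus 35
#' basket cells per layer interleaved at half-pitch positions, 270 cells in
#' total.  Geometry is deterministic; the seed is stored for downstream
#' drive sampling.  The dipole scale factor does not instantiate extra
#' cells; it multiplies the dipole output so that the default column stands
#' in for `200 * scale` synchronously driven pyramidal cells.
#'
#' @param seed Integer seed stored on the network.
#' @param scale Positive integer dipole scaling factor.
#' @param n_pn Number of pyramidal cells per layer.
#' @param n_basket Number of basket cells per layer.
#' @param specs Cell specifications, see [default_cell_specs()].
#' @param connectivity Local connectivity table, see
#'   [default_local_connectivity()].
#' @param kinetics Channel kinetics, see [default_channel_kinetics()].
#' @param pitch Grid pitch, micrometers.
#' @return A `column_network` object.
#' @export
build_column <- function(seed = 0, scale = 300, n_pn = 100, n_basket = 35,
                         specs = default_cell_specs(),
                         connectivity = default_local_connectivity(),
                         kinetics = default_channel_kinetics(),
                         pitch = 100) {
  if (!is.numeric(scale) || length(scale) != 1 || scale != round(scale) || scale < 1)
    stop("scale must be a positive integer")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("seed must be an integer")
  stopifnot(.apical_extent(specs$L5_PN) > .apical_extent(specs$L23_PN))

  z_soma <- c(L23 = -400, L5 = -1200)
  pn_side <- ceiling(sqrt(n_pn))
  pn_xy <- expand.grid(x = seq_len(pn_side), y = seq_len(pn_side))[seq_len(n_pn), ] * pitch
  bk_side <- ceiling(sqrt(n_basket))
  bk_xy <- expand.grid(x = seq_len(bk_side), y = seq_len(bk_side))[seq_len(n_basket), ] *
    pitch * pn_side / (bk_side + 1) + pitch / 2

  cells <- do.call(rbind, list(
    data.frame(cell_class = "L23_PN", x = pn_xy$x, y = pn_xy$y, z_soma = z_soma[["L23"]]),
    data.frame(cell_class = "L5_PN", x = pn_xy$x, y = pn_xy$y, z_soma = z_soma[["L5"]]),
    data.frame(cell_class = "L23_basket", x = bk_xy$x, y = bk_xy$y, z_soma = z_soma[["L23"]]),
    data.frame(cell_class = "L5_basket", x = bk_xy$x, y = bk_xy$y, z_soma = z_soma[["L5"]])))
  cells <- data.frame(cell_id = seq_len(nrow(cells)), cells, row.names = NULL)

  net <- structure(list(cells = cells, specs = specs, kinetics = kinetics,
                        connectivity = connectivity, drives = list(),
                        scale = as.integer(scale), seed = as.integer(seed),
                        grid_shape = c(pn_side, pn_side), pitch = pitch),
                   class = "column_network")
  net$flat <- .flatten_network(net)
  net
}

#' @rdname build_column
#' @export
build_default_column <- function(seed = 0, scale = 300) {
  build_column(seed = seed, scale = scale)
}

#' Effective number of contributing cells
#'
#' The dipole scale factor multiplies the simulated dipole so that the
#' column's pyramidal population stands in for `n_PN * scale` synchronously
#' driven pyramidal neurons (60,000 for the default column at scale 300).
#'
#' @param network A `column_network`.
#' @return Integer count.
#' @export
effective_cell_count <- function(network) {
  sum(grepl("_PN$", network$cells$cell_class)) * network$scale
}

#' Cell-class counts of a column
#' @param network A `column_network`.
#' @return Named integer vector of per-class counts plus `total`.
#' @export
cell_counts <- function(network) {
  counts <- table(factor(network$cells$cell_class,
                         levels = c("L23_PN", "L5_PN", "L23_basket", "L5_basket")))
  c(stats::setNames(as.integer(counts), names(counts)),
    total = nrow(network$cells))
}

#' Describe a column as a plain list
#'
#' Counts, grid shape and per-class geometry; convertible to JSON with
#' `jsonlite::toJSON()`.
#'
#' @param network A `column_network`.
#' @return A list.
#' @export
describe_column <- function(network) {
  list(counts = as.list(cell_counts(network)),
       grid_shape = network$grid_shape,
       pitch_um = network$pitch,
       scale = network$scale,
       effective_cells = effective_cell_count(network),
       apical_extent_um = list(
         L23_PN = .apical_extent(network$specs$L23_PN),
         L5_PN = .apical_extent(network$specs$L5_PN)))
}

#' @export
print.column_network <- function(x, ...) {
  counts <- cell_counts(x)
  cat("<column_network> ", counts[["total"]], " cells (",
      counts[["L23_PN"]] + counts[["L5_PN"]], " PNs), scale ", x$scale,
      ", ", length(x$drives), " drive(s)\n", sep = "")
  invisible(x)
}

# Flatten the network into the per-compartment / per-connection arrays the
# compiled integrator consumes.  EL is balanced per compartment so that the
# stated resting potential is an exact fixed point of the unstimulated
# dynamics.
.flatten_network <- function(net) {
  kin <- net$kinetics
  specs <- net$specs
  cells <- net$cells
  # per-class flat template
  tmpl <- lapply(specs, function(spec) {
    el <- lapply(spec$compartments, .comp_electrical)
    v0 <- spec$resting_potential
    ss <- list(m = kin$na_m(v0)$inf, h = kin$na_h(v0)$inf,
               n = kin$k_n(v0)$inf, p = kin$ca_p(v0)$inf,
               q = kin$ca_q(v0)$inf)
    z0 <- kin$ca0^2 / (kin$ca0^2 + kin$kca_kd^2)
    df <- data.frame(
      name = vapply(spec$compartments, `[[`, character(1), "name"),
      z_off = vapply(spec$compartments, `[[`, numeric(1), "z_offset"),
      C = vapply(el, `[[`, numeric(1), "C"),
      gL = vapply(el, `[[`, numeric(1), "gL"),
      gNa = vapply(el, `[[`, numeric(1), "gNa"),
      gK = vapply(el, `[[`, numeric(1), "gK"),
      gCa = vapply(el, `[[`, numeric(1), "gCa"),
      gKCa = vapply(el, `[[`, numeric(1), "gKCa"),
      half_r = vapply(spec$compartments, .half_axial_mohm, numeric(1)))
    iion0 <- with(df, gNa * ss$m^3 * ss$h * (v0 - kin$ena) +
                    gK * ss$n^4 * (v0 - kin$ek) +
                    gCa * ss$p^2 * ss$q * (v0 - kin$eca) +
                    gKCa * z0 * (v0 - kin$ek))
    df$EL <- v0 + iion0 / df$gL
    df$v0 <- v0
    df
  })
  # per-class intracellular connections (indices into the template rows)
  conn_tmpl <- lapply(specs, function(spec) {
    nm <- vapply(spec$compartments, `[[`, character(1), "name")
    idx <- function(x) match(x, nm)
    pairs <- list(c("basal", "soma"), c("oblique", "soma"),
                  c("soma", "apical_trunk"), c("apical_trunk", "apical_tuft"))
    pairs <- Filter(function(p) all(p %in% nm), pairs)
    if (length(pairs) == 0) return(data.frame(i = integer(), j = integer()))
    data.frame(i = vapply(pairs, function(p) idx(p[1]), integer(1)),
               j = vapply(pairs, function(p) idx(p[2]), integer(1)))
  })

  comp <- list(); conn <- list(); soma_comp <- integer(nrow(cells))
  offset <- 0L
  for (ci in seq_len(nrow(cells))) {
    cls <- cells$cell_class[ci]
    df <- tmpl[[cls]]
    n <- nrow(df)
    comp[[ci]] <- data.frame(cell_id = cells$cell_id[ci], cell_class = cls,
                             name = df$name, z = cells$z_soma[ci] + df$z_off,
                             C = df$C, gL = df$gL, EL = df$EL, gNa = df$gNa,
                             gK = df$gK, gCa = df$gCa, gKCa = df$gKCa,
                             v0 = df$v0)
    soma_comp[ci] <- offset + match("soma", df$name)
    ct <- conn_tmpl[[cls]]
    if (nrow(ct) > 0) {
      conn[[ci]] <- data.frame(
        i = offset + ct$i, j = offset + ct$j,
        g = 1 / (df$half_r[ct$i] + df$half_r[ct$j]),   # uS (1/MOhm)
        dz = df$z_off[ct$j] - df$z_off[ct$i],
        cell_id = cells$cell_id[ci],
        is_pn = grepl("_PN$", cls))
    }
    offset <- offset + n
  }
  comp <- do.call(rbind, comp)
  comp$comp_id <- seq_len(nrow(comp))
  conn <- do.call(rbind, conn)
  ca_on <- comp$gCa > 0
  list(comp = comp, conn = conn, soma_comp = soma_comp,
       ca_tau = ifelse(ca_on, net$kinetics$ca_tau, 0),
       ca_f = ifelse(ca_on, 5e-4, 0),   # mM per nA*ms of calcium influx
       tables = .channel_tables(net$kinetics))
}

# comp_ids of a given compartment name restricted to given cell classes
.comps_of <- function(network, classes, names) {
  comp <- network$flat$comp
  comp$comp_id[comp$cell_class %in% classes & comp$name %in% names]
}
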