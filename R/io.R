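#' Read / write waveforms as two-column text
#'
#' Tab-separated `time_ms` / `amplitude_nAm` tables, the package's exchange
#' format for target and simulated waveforms.
#'
#' @param x A `target_waveform` or `dipole_trace`.
#' @param path File path.
#' @return `read_waveform()` returns a [target_waveform()].
#' @export
write_waveform <- function(x, path) {
  df <- data.frame(time_ms = .wave_time(x), amplitude_nAm = .wave_amp(x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @param condition Condition label to attach on read.
#' @export
read_waveform <- function(path, condition = "undetected") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  target_waveform(df[[1]], df[[2]], condition, provenance = path)
}

#' Read / write a network specification
#'
#' A structured-text (YAML) description of the column: per-layer cell
#' counts, grid pitch, dipole scale, and per-class compartment geometry
#' and channel densities.  `build_column_from_config()` constructs the
#' network it describes; `write_network_config()` serializes an existing
#' network's specification.
#'
#' @param path YAML file path.
#' @return `read_network_config()` returns the parsed list;
#'   `build_column_from_config()` a `column_network`.
#' @export
read_network_config <- function(path) yaml::read_yaml(path)

#' @rdname read_network_config
#' @param network A `column_network`.
#' @export
write_network_config <- function(network, path) {
  cls_list <- lapply(network$specs, function(spec) {
    list(spike_threshold = spec$spike_threshold,
         resting_potential = spec$resting_potential,
         compartments = lapply(spec$compartments, function(cm)
           list(name = cm$name, length = cm$length, diameter = cm$diameter,
                z_offset = cm$z_offset, channels = as.list(cm$channels))))
  })
  yaml::write_yaml(list(
    counts = list(pn_per_layer = sum(network$cells$cell_class == "L23_PN"),
                  basket_per_layer = sum(network$cells$cell_class == "L23_basket")),
    pitch_um = network$pitch, scale = network$scale, seed = network$seed,
    cell_classes = cls_list), path)
  invisible(path)
}

#' @rdname read_network_config
#' @export
build_column_from_config <- function(path) {
  cfg <- read_network_config(path)
  specs <- lapply(names(cfg$cell_classes), function(cls) {
    cc <- cfg$cell_classes[[cls]]
    cell_spec(cls,
              lapply(cc$compartments, function(cm)
                compartment_spec(cm$name, cm$length, cm$diameter,
                                 cm$z_offset, unlist(cm$channels))),
              spike_threshold = cc$spike_threshold %||% 0,
              resting_potential = cc$resting_potential %||% -65)
  })
  names(specs) <- names(cfg$cell_classes)
  build_column(seed = cfg$seed %||% 0, scale = cfg$scale %||% 300,
               n_pn = cfg$counts$pn_per_layer,
               n_basket = cfg$counts$basket_per_layer,
               specs = specs, pitch = cfg$pitch_um %||% 100)
}
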