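#' Record spike events as a raster
#'
#' A spike raster is a data frame with columns `module` (character label),
#' `neuron_index` (1-based integer) and `time_ms` (non-negative), sorted by
#' time. It is the canonical record of a simulation and serializes to CSV.
#'
#' @param module Character vector of module labels (or a single label).
#' @param neuron_index Integer vector of neuron indices.
#' @param time_ms Numeric vector of spike times (ms).
#' @return An object of classes `spike_raster` and `data.frame`.
#' @export
record_raster <- function(module = character(), neuron_index = integer(),
                          time_ms = numeric()) {
  n <- max(length(neuron_index), length(time_ms))
  if (length(module) %in% c(0L, 1L) && n > 0L) module <- rep(module, length.out = n)
  df <- data.frame(module = as.character(module),
                   neuron_index = as.integer(neuron_index),
                   time_ms = as.numeric(time_ms),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$time_ms < 0)) stop("spike times must be non-negative")
    if (any(df$neuron_index < 1L)) stop("neuron indices must be positive")
    df <- df[order(df$time_ms, df$module, df$neuron_index), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("spike_raster", "data.frame")
  df
}

#' Write a spike raster to CSV
#'
#' @param raster A [record_raster()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.csv(as.data.frame(raster)[, c("module", "neuron_index", "time_ms")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' @param path File written by [write_raster()].
#' @return A `spike_raster`.
#' @export
read_raster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  record_raster(df$module, df$neuron_index, df$time_ms)
}

# First spike time of a module (optionally restricted to a neuron subset),
# or NA if it never fired.
raster_onset <- function(raster, module, neurons = NULL) {
  df <- as.data.frame(raster)
  df <- df[df$module == module, , drop = FALSE]
  if (!is.null(neurons)) df <- df[df$neuron_index %in% neurons, , drop = FALSE]
  if (nrow(df) == 0L) return(NA_real_)
  min(df$time_ms)
}

# Set of neurons of a module with at least one spike in the raster.
raster_fired <- function(raster, module, neurons = NULL) {
  df <- as.data.frame(raster)
  df <- df[df$module == module, , drop = FALSE]
  if (!is.null(neurons)) df <- df[df$neuron_index %in% neurons, , drop = FALSE]
  sort(unique(df$neuron_index))
}
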