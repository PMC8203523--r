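# end-to-end synthetic dataset generation

#' Generate a complete synthetic session
#'
#' Builds the epoch table and light-pulse train, generates the spike units
#' (so that spike-triggered gamma effects can be driven by real spike
#' times), then the LFP, and optionally writes the whole dataset to disk in
#' the container read by [load_session()]. The same configuration and seed
#' always produce an identical dataset.
#'
#' @param config A [synth_config()].
#' @param dir Optional output directory; when given, the dataset is written
#'   with [write_dataset()].
#' @return Session list: `lfp`, `units`, `epochs`, `light`,
#'   `ground_truth`, `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  epochs <- make_epoch_table(config)
  light <- make_light_events(config, epochs)
  gu <- generate_units(config, epochs, light,
                       seed = derive_seed(config$seed, 1))
  lfp <- generate_lfp(config, epochs, units = gu$units,
                      seed = derive_seed(config$seed, 2))
  session <- list(lfp = lfp, units = gu$units, epochs = epochs,
                  light = light, ground_truth = gu$ground_truth,
                  config = config)
  if (!is.null(dir)) write_dataset(session, dir)
  session
}
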