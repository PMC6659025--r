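# Reaction-norm calibration is the most expensive step of the pipeline;
# memoize it across test files within one run.
.calib_store <- new.env(parent = emptyenv())

calibrated_preset <- function(name) {
  if (is.null(.calib_store[[name]])) {
    .calib_store[[name]] <- calibrate_wstar(fish_preset(name))
  }
  .calib_store[[name]]
}
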