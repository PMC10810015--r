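# one shared calibration object for the whole suite
CAL <- calibration_set()

expect_rel <- function(actual, expected, rel) {
  expect_lt(abs(actual - expected) / abs(expected), rel)
}
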