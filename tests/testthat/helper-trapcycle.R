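rel_err <- function(est, true) abs(est - true) / abs(true)

# convenience: noise-free exponential buildup trace
exp_trace <- function(k, A, t = seq(0, 5 / k, length.out = 60),
                      offset = 0, slope = 0, unit = "min") {
  kinetic_trace(t, offset + A * (1 - exp(-k * t)) + slope * t,
                time_unit = unit, kind = "delta_fret")
}
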