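# Shared waveform builders. 0.69 MHz is the reference carrier; 0.2 MHz is
# used where a property is known to be carrier-insensitive, to keep the
# carrier-resolved integration cheap.

cal_drive <- function(amp = 0.8, coverage = 1) {
  sinusoidal_drive(amp, coverage = coverage)
}

pulsed_train <- function(duration = 0.3, duty = 0.05, prf = 100,
                         carrier = 0.69e6, onset = 0) {
  pulse_train(carrier, prf = prf, duty = duty, duration = duration,
              onset = onset)
}

cw_train <- function(duration = 0.05, carrier = 0.69e6) {
  pulse_train(carrier, duty = 1, duration = duration)
}
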