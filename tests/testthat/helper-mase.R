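# shared fixtures for the exchange-model tests

# noiseless exchange series at the closed-form curve
noiseless_series <- function(k_off, t) {
  data.frame(t = t, R = exchange_ratio(k_off, t))
}

default_rates <- function(k_off = 1e-4, k_on = 1e6) {
  rate_constants(k_on = k_on, k_off = k_off)
}

hours <- function(h) h * 3600
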