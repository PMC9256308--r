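# Decimal rounding with ties going up (the convention used for printed
# percentages), unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
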