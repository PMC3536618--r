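# Shared fixture builders; all randomness is seeded at the call site.

# A plate with constant counts: every treated well at `frac` times the
# control level, so every SF equals `frac` exactly.
flat_plate <- function(id = "CL1", frac = 1, control = c(200, 200, 200)) {
  dr_plate(id,
           treated = data.frame(dose_index = rep(1:10, each = 3),
                                count = frac * mean(control)),
           control = control)
}

# Random valid plate with integer counts.
random_plate <- function(id = "CLr", seed = 1) {
  set.seed(seed)
  dr_plate(id,
           treated = data.frame(dose_index = rep(1:10, each = 3),
                                count = rpois(30, 400)),
           control = rpois(4, 800))
}

# Random expression matrix with dimnames.
random_matrix <- function(p, n, seed = 1, mean = 7, sd = 1.5) {
  set.seed(seed)
  matrix(rnorm(p * n, mean, sd), p, n,
         dimnames = list(sprintf("P%04d", seq_len(p)),
                         sprintf("S%03d", seq_len(n))))
}
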