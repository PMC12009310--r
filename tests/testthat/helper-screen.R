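# Independent brute-force median/MAD oracle: sort-based, no calls into
# stats::median/mad, used to cross-check robust_z.
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_robust_z <- function(x, controls, scale_constant = 1.4826) {
  m <- oracle_median(controls)
  mad_raw <- oracle_median(abs(controls - m))
  (x - m) / (scale_constant * mad_raw)
}

# Construct a sample with exact first and second sample moments.
sample_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  z <- (x - base::mean(x)) / stats::sd(x)
  mean + sd * z
}

# Small screen fixture shared across tests.
tiny_config <- function(...) {
  screen_config(n_batches = 2, seed = 7, ...)
}

# Minimal z-record data frame builder for rule tests.
zrec <- function(condition, replicate, batch, plate, z_cell, z_cilia,
                 role = "test") {
  data.frame(condition = condition, replicate = replicate, batch = batch,
             plate = plate, role = role, z_cell = z_cell,
             z_cilia = z_cilia, stringsAsFactors = FALSE)
}
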