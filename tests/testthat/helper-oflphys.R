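# Shared fixtures and oracles for the test suite.

# Noise-free, deterministic-amplitude generator settings: every response equals
# its condition mean exactly.
params_deterministic <- function(...) {
  synth_params(eda_noise_sd = 0, emg_noise_sd = 0, lognormal_amp_cv = 0,
               response_prob = 1, tonic_drift = 0, ...)
}

# Brute-force window oracle: max over [onset + w1, onset + w2) minus mean over
# [onset - b, onset), computed by masking the time axis directly (independent
# of the package's index arithmetic).
oracle_window_score <- function(x, fs, onset, w1, w2, bspan) {
  t <- (seq_along(x) - 1) / fs
  peak <- max(x[t >= onset + w1 - 1e-12 & t < onset + w2 - 1e-12])
  base <- mean(x[t >= onset - bspan - 1e-12 & t < onset - 1e-12])
  peak - base
}

# All orderings of n_plus CS+ / n_minus CS- labels satisfying the run-length
# constraint, enumerated exhaustively.
enumerate_valid_sequences <- function(n_plus, n_minus, max_run) {
  n <- n_plus + n_minus
  combos <- utils::combn(n, n_plus)
  seqs <- apply(combos, 2, function(idx) {
    s <- rep("CS_MINUS", n)
    s[idx] <- "CS_PLUS"
    s
  })
  keep <- apply(seqs, 2, function(s) max(rle(s)$lengths) <= max_run)
  apply(seqs[, keep, drop = FALSE], 2, paste, collapse = ",")
}

# A small synthetic phasic trace: one SCR kernel of amplitude `amp` whose
# driver fires at `event_t` seconds.
kernel_trace <- function(amp, event_t, dur = 30, fs = 2000) {
  t <- seq(0, dur, by = 1 / fs)
  amp * scr_kernel(pmax(t - event_t, 0)) * (t >= event_t)
}
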