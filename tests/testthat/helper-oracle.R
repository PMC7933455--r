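# Independent oracles used to cross-check the implementation.

# Brute-force LZ'76 exhaustive-history parser: at each component start,
# grow the candidate word until it is no longer a substring (fixed-string
# search, self-overlap allowed via the prefix ending one symbol before
# the candidate's end) of the already-seen text; each component counts,
# including a final truncated one. Deliberately string-based, unlike the
# package's pointer-scan implementation.
lz76_oracle <- function(bits) {
  if (is.character(bits) && length(bits) == 1L) {
    s <- bits
  } else {
    s <- paste(as.integer(bits), collapse = "")
  }
  n <- nchar(s)
  stopifnot(n >= 1)
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    while (i + k - 1L <= n) {
      w <- substr(s, i, i + k - 1L)
      prefix <- substr(s, 1L, i + k - 2L)
      if (grepl(w, prefix, fixed = TRUE)) k <- k + 1L else break
    }
    cnt <- cnt + 1L
    i <- i + k
  }
  cnt
}

# All binary strings of a given length, as integer vectors.
all_binary_strings <- function(len) {
  lapply(0:(2^len - 1), function(v) {
    as.integer(intToBits(v)[seq_len(len)])
  })
}

# Tie-adjusted pairwise-concordance AUC: fraction of (case, control)
# pairs where the case scores higher, ties counting one half.
auc_concordance_oracle <- function(scores, labels) {
  s1 <- scores[labels == "case"]
  s0 <- scores[labels == "control"]
  gr <- outer(s1, s0, ">")
  eq <- outer(s1, s0, "==")
  mean(gr + 0.5 * eq)
}

# A deterministic clean sinus-rhythm strip with known beat positions.
clean_strip <- function(hr = 75, seed = 42, jitter = 0, snr_db = Inf,
                        n_strips_id = 1L) {
  p <- synth_patient_params("fixture", "control", base_hr = hr,
                            hr_day_sd = 0, rr_jitter_sd = jitter,
                            rr_jitter_day_sd = 0, morph_day_sd = 0,
                            snr_db = snr_db)
  generate_strip(p, strip_index = n_strips_id, seed = seed)
}
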