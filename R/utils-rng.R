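# Internal RNG plumbing: every user-facing stochastic function takes an integer
# seed and leaves the caller's RNG state untouched (withr::with_seed).

# Derive per-subject seed triples (params / stimuli / session) from a master
# seed. Draws are sequential under the master seed, so subject i always
# receives the same seeds regardless of cohort size (stable under subsetting).
derive_subject_seeds <- function(master_seed, n, per = 3L) {
  stopifnot(length(master_seed) == 1L, n >= 0L)
  if (n == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = per))
  }
  withr::with_seed(as.integer(master_seed), {
    matrix(sample.int(2147483646L, n * per, replace = TRUE),
           nrow = n, ncol = per, byrow = TRUE)
  })
}

# FNV-1a hash of a string, returned as 8 hex digits. Used only to fingerprint
# configurations in cohort bundles and reports. Arithmetic stays in doubles;
# the byte XOR only ever touches the low 8 bits, so it is done by hand.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # modular multiply by the FNV prime 16777619 = 2^24 + 403 without overflow
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
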