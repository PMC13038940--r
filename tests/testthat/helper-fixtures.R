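# Shared fixtures: random records/profiles and independent naive-loop
# oracles that every vectorised encoder is checked against.

AA <- pvpstack::AA_ALPHABET

random_sequence <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(50, 80)) {
  lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  protein_records(paste0("r", seq_len(n)),
                  vapply(lens, random_sequence, character(1)))
}

random_profile <- function(L) {
  scores <- matrix(sample(-10:10, L * 20, replace = TRUE), L, 20)
  pssm_profile(sample(AA, L, replace = TRUE), scores)
}

# ---- naive-loop oracles (kept deliberately dumb and index-wise) ----------

oracle_aac_pssm <- function(profile) {
  s <- profile$scores; L <- nrow(s)
  out <- numeric(20)
  for (j in 1:20) {
    acc <- 0
    for (k in 1:L) acc <- acc + s[k, j]
    out[j] <- acc / L
  }
  out
}

oracle_dpc_pssm <- function(profile) {
  s <- profile$scores; L <- nrow(s)
  out <- numeric(400)
  idx <- 0
  for (i in 1:20) for (j in 1:20) {
    idx <- idx + 1
    acc <- 0
    for (k in 1:(L - 1)) acc <- acc + s[k, i] * s[k + 1, j]
    out[idx] <- acc / (L - 1)
  }
  out
}

oracle_pssm_com <- function(profile, normalize = TRUE) {
  s <- profile$scores; L <- nrow(s)
  out <- matrix(0, 20, 20)
  for (i in 1:20) {
    for (k in 1:L) {
      if (profile$residues[k] == AA[i]) out[i, ] <- out[i, ] + s[k, ]
    }
  }
  if (normalize) out <- out / L
  as.vector(t(out))
}

oracle_pse_pssm <- function(profile, xi = 1) {
  z <- normalize_pssm(profile, "row_standard")$scores
  L <- nrow(z)
  means <- numeric(20); lags <- numeric(20)
  for (j in 1:20) {
    for (k in 1:L) means[j] <- means[j] + z[k, j] / L
    for (k in 1:(L - xi)) {
      lags[j] <- lags[j] + (z[k, j] - z[k + xi, j])^2 / (L - xi)
    }
  }
  c(means, lags)
}

oracle_counts <- function(sequence, alphabet) {
  chars <- strsplit(sequence, "")[[1]]
  vapply(alphabet, function(a) sum(chars == a), numeric(1))
}
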