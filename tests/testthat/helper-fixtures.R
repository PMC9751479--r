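# Shared fixtures: one reference model and MER11A parent reused across tests.
REF <- build_reference(1)
MER <- build_mer11a_parent(1)

rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Independent affine-gap alignment score oracle: cubic DP over explicit gap
# lengths (Needleman-Wunsch with affine penalties), structurally different
# from the three-state Gotoh implementation it checks.
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  S <- matrix(-Inf, n + 1, m + 1)
  S[1, 1] <- 0
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (ca[i] == cb[j] && ca[i] != "N") match else mismatch
      best <- max(best, S[i, j] + s)
    }
    if (i > 0) for (k in 1:i) {
      best <- max(best, S[i - k + 1, j + 1] - gap_open - k * gap_extend)
    }
    if (j > 0) for (k in 1:j) {
      best <- max(best, S[i + 1, j - k + 1] - gap_open - k * gap_extend)
    }
    S[i + 1, j + 1] <- best
  }
  S[n + 1, m + 1]
}
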