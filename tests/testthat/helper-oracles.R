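# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately share no code with the implementation.

# Smith-Waterman with affine gaps by explicit Gotoh dynamic programming.
# A gap of length L costs gap_open + gap_extend * L (the same convention as
# the implementation's backend).
sw_dp_oracle <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  open_cost <- gap_open + gap_extend
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0
  M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- mat[ca[i - 1], cb[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, Ix[i - 1, j - 1] + sub, Iy[i - 1, j - 1] + sub)
      Ix[i, j] <- max(M[i - 1, j] - open_cost, Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - open_cost, Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Mutual information in bits as the literal four-term sum.
mi_sum_oracle <- function(p, q) {
  n <- length(p)
  total <- 0
  for (x in 0:1) {
    for (y in 0:1) {
      fxy <- sum(p == x & q == y) / n
      fx <- sum(p == x) / n
      fy <- sum(q == y) / n
      if (fxy > 0) total <- total + fxy * log2(fxy / (fx * fy))
    }
  }
  total
}

# AUC as the O(n^2) pairwise comparison probability with ties counted half.
auc_pairwise_oracle <- function(pos_scores, neg_scores) {
  total <- 0
  for (s_pos in pos_scores) {
    for (s_neg in neg_scores) {
      total <- total + (s_pos > s_neg) + 0.5 * (s_pos == s_neg)
    }
  }
  total / (length(pos_scores) * length(neg_scores))
}

# Sensitivity/specificity/accuracy/MCC evaluated directly from their
# defining formulas.
metrics_formula_oracle <- function(tp, fp, tn, fn) {
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
}

random_aa_seq <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
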