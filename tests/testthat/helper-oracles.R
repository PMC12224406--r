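# Independent oracle implementations used to cross-check the package:
# a naive O(N^2) DFT, textbook t statistics, and small builders for random
# fixtures. These deliberately avoid the package's own computational paths.

# One-sided complex DFT of a windowed segment, summed term by term.
naive_dft <- function(x, w) {
  N <- length(x)
  xs <- x * w
  n <- 0:(N - 1)
  vapply(0:(N %/% 2), function(f) {
    sum(xs * exp(-2i * pi * f * n / N))
  }, complex(1))
}

one_sample_t_oracle <- function(x) {
  mean(x) / (stats::sd(x) / sqrt(length(x)))
}

# Pooled-variance independent-samples t (group a minus group b).
two_sample_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Random K x F x C magnitude-like STFT with positive values.
random_stft <- function(K, nf, nc = 1, offset = 10) {
  stft_object(array(stats::rnorm(K * nf * nc, offset), dim = c(K, nf, nc)),
              freqs = seq_len(nf))
}

constant_design <- function(K) {
  assemble_design(list(finalize_regressor(rep(1, K), "constant", "mean")))
}

# Two-group dummy design (n1 rows of group a, n2 of group b).
two_group_design <- function(n1, n2) {
  assemble_design(list(
    finalize_regressor(rep(c(1, 0), c(n1, n2)), "categorical", "a"),
    finalize_regressor(rep(c(0, 1), c(n1, n2)), "categorical", "b")
  ))
}

# Single-bin STFT from a plain vector of per-segment values.
vector_stft <- function(y) {
  stft_object(array(y, dim = c(length(y), 1, 1)), freqs = 1)
}
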