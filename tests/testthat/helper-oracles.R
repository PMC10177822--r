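# Independent statistical oracles, kept separate from the implementations
# they check.

# ICC(3,1) from stats::aov mean squares (two-way, items random rows)
icc31_aov_oracle <- function(m) {
  df <- data.frame(
    score = as.vector(m),
    item = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(stats::aov(score ~ item + rater, data = df))[[1]][["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (ncol(m) - 1) * ms[3])
}
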