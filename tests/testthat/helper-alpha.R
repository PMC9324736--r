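# Independent agreement oracle: Krippendorff's alpha by direct enumeration
# of rating pairs, no coincidence matrix. D_obs averages nominal
# disagreement over all ordered pairs within units (weight 1/(m_u - 1));
# D_exp does the same over the pooled pairable values.
alpha_oracle <- function(r) {
  r <- as.matrix(r)
  pooled <- c()
  d_obs <- 0
  n <- 0
  for (u in seq_len(nrow(r))) {
    vals <- unname(r[u, !is.na(r[u, ])])
    m <- length(vals)
    if (m < 2) next
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) d_obs <- d_obs + (vals[i] != vals[j]) / (m - 1)
      }
    }
    pooled <- c(pooled, vals)
    n <- n + m
  }
  if (n < 4) return(NULL)
  d_exp <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d_exp <- d_exp + (pooled[i] != pooled[j])
    }
  }
  d_obs <- d_obs / n
  d_exp <- d_exp / (n * (n - 1))
  if (d_exp == 0) NA_real_ else 1 - d_obs / d_exp
}
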