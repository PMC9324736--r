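# Shared fixtures, all generated in code.

# random normalized pair on a small grid
random_pair <- function(shape = c(4L, 8L, 8L), seed = 1L) {
  set.seed(seed)
  n <- prod(shape)
  normalized_pair(array(runif(n), shape), array(runif(n), shape))
}

# tiny noise-free phantom for fast pipeline tests
small_phantom <- function(seed = 1L, noise_sigma = 0) {
  generate_phantom(phantom_spec(shape = c(8L, 32L, 32L),
                                noise_sigma = noise_sigma, seed = seed))
}

# mean (adc, dwi) coordinate of a histogram2d
hist_centroid <- function(h) {
  cnt <- unclass(h)
  centers <- (seq_len(nrow(cnt)) - 0.5) / nrow(cnt)
  c(adc = sum(rowSums(cnt) * centers) / sum(cnt),
    dwi = sum(colSums(cnt) * centers) / sum(cnt))
}
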