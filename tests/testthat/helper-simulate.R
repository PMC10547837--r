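# Shared simulation helpers for the modelling tests.

# n x k standardized Gaussian design as a data frame
std_design <- function(n, k, prefix = "x") {
  d <- as.data.frame(matrix(stats::rnorm(n * k), n, k))
  names(d) <- paste0(prefix, seq_len(k))
  d[] <- lapply(d, function(v) as.numeric(scale(v)))
  d
}

# Poisson counts from a named coefficient vector on the design's columns
sim_counts <- function(design, beta, seed) {
  y <- generate_richness(design, list(y = beta), seed)
  design$y <- y$y
  design
}
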