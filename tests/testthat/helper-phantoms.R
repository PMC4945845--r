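# shared fixtures: built once per test run, in code (no stored data)

dice <- function(a, b) {
  if (inherits(a, "region_mask")) a <- a$mask
  if (inherits(b, "region_mask")) b <- b$mask
  2 * sum(a & b) / (sum(a) + sum(b))
}

# small single-airway phantom: fast, for density/lungseg unit tests
small_spec <- function(...) {
  args <- list(grid_shape = c(72, 56, 80), voxel_spacing = 1.6,
               airway_generations = 1, root_radius = 7, root_length = 35)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

.cache <- new.env()

# the full-size six-generation study phantom (built lazily, reused)
study_phantom <- function() {
  if (is.null(.cache$study)) .cache$study <- build_phantom(phantom_spec())
  .cache$study
}

small_phantom <- function() {
  if (is.null(.cache$small)) .cache$small <- build_phantom(small_spec())
  .cache$small
}

# moment-level SE estimate by block splitting (for Monte-Carlo tolerance)
block_se <- function(x, stat, blocks = 100) {
  n <- length(x)
  idx <- rep(seq_len(blocks), length.out = n)
  vals <- vapply(split(x, idx), stat, numeric(1))
  sd(vals) / sqrt(blocks)
}
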