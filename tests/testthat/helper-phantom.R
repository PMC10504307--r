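# Shared fixtures, all generated in code.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small rendered phantom with identity alignment
tiny_phantom <- function(seed = 5, size = 128, misalignment = NULL) {
  sp <- phantom_spec(image_size = size, px_per_mm = 24, seed = seed)
  if (!is.null(misalignment)) sp$misalignment <- misalignment
  render_phantom_pair(grow_vessel_tree(sp), sp)
}

# a loaded phantom cohort written to a session-persistent temp dir
tiny_cohort <- function(n = 8, seed = 11) {
  memo(sprintf("cohort_%d_%d", n, seed), {
    dir <- file.path(tempdir(), sprintf("octasyn_cohort_%d_%d", n, seed))
    generate_phantom_dataset(dir, n, seed = seed,
                             template = phantom_spec(image_size = 128,
                                                     px_per_mm = 24))
    load_phantom_dataset(dir)
  })
}

# random binary blob mask for transform round-trips
blob_mask <- function(size = 64, seed = 3) {
  with_seed_test(seed, {
    m <- matrix(0, size, size)
    ctr <- size / 2
    for (i in 1:6) {
      c0 <- ctr + runif(2, -size / 6, size / 6)
      r <- runif(1, 3, 7)
      rr <- matrix(0:(size - 1), size, size)
      cc <- t(rr)
      m[(rr - c0[1])^2 + (cc - c0[2])^2 <= r^2] <- 1
    }
    m
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
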