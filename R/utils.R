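# Internal helpers shared across modules.

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds (< 2^31) from a master seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip_gray <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

as_gray_image <- function(image) {
  if (is.null(dim(image))) stop("`image` must be a matrix of gray values")
  image <- as.matrix(image)
  if (!is.numeric(image)) stop("`image` must be numeric")
  if (anyNA(image)) stop("`image` contains missing values")
  image
}

check_gray_range <- function(image) {
  if (min(image) < 0 || max(image) > 255)
    stop("gray values must lie in [0, 255]")
  invisible(image)
}

# All c! permutations of 1..c as a matrix (one permutation per row).
all_permutations <- function(c) {
  if (c == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(c - 1L)
  out <- matrix(0L, nrow(sub) * c, c)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(c)) {
      out[row, ] <- append(sub[i, ], c, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}
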