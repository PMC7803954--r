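# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL leaves the current stream in place.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

vl_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "voicelight_error")))
}

vl_assert <- function(cond, msg, class = "voicelight_invalid") {
  if (!isTRUE(cond)) vl_error(msg, class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Linear index <-> voxel (i, j, k) conversion on a 3D grid, 1-based.
lin_to_ijk <- function(lin, dim) {
  lin0 <- lin - 1L
  i <- lin0 %% dim[1L]
  j <- (lin0 %/% dim[1L]) %% dim[2L]
  k <- lin0 %/% (dim[1L] * dim[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dim) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  (ijk[, 3L] - 1L) * dim[1L] * dim[2L] + (ijk[, 2L] - 1L) * dim[1L] + ijk[, 1L]
}
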