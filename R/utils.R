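#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded helpers do not disturb the global stream.
#'
#' @param seed integer seed, or `NULL` to run with the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive reproducible child seeds from a root seed
#'
#' One root seed per acquisition or repeat series; per-frame / per-repeat
#' child seeds are drawn deterministically from it so that any sub-experiment
#' can be replayed in isolation.
#'
#' @param root integer root seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
child_seeds <- function(root, n) {
  with_seed(root, sample.int(.Machine$integer.max - 1L, n))
}

#' Euclidean distance-from-center map
#'
#' @param dims `c(rows, cols)`.
#' @param center `c(row, col)` in pixel coordinates (pixel centers at
#'   integers).
#' @return matrix of distances.
#' @keywords internal
rho_matrix <- function(dims, center) {
  dr <- (seq_len(dims[1]) - center[1])^2
  dc <- (seq_len(dims[2]) - center[2])^2
  sqrt(outer(dr, dc, `+`))
}

#' Box-sum downsampling of an image
#'
#' Sums disjoint `f` x `f` cells; counts are additive photon tallies so the
#' detector model sums (never averages) high-resolution cells.
#'
#' @param x matrix with dimensions divisible by `f`.
#' @param f integer decimation factor.
#' @return matrix of size `dim(x)/f`.
#' @export
box_sum <- function(x, f) {
  f <- as.integer(f)
  if (f == 1L) return(x)
  d <- dim(x)
  if (any(d %% f != 0L)) stop("dimensions not divisible by f")
  nr <- d[1] %/% f
  nc <- d[2] %/% f
  # sum rows within blocks, then columns
  xr <- rowsum(x, rep(seq_len(nr), each = f))
  t(rowsum(t(xr), rep(seq_len(nc), each = f)))
}

default_center <- function(dims) (dims + 1) / 2

is_odd <- function(n) n %% 2L == 1L
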