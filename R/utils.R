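#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stream seed from a root seed
#'
#' A single root seed drives every generator; each generator draws from its
#' own derived stream so adding a generator never changes existing output.
#' The derivation is a fixed affine map modulo the Mersenne prime 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param stream Small non-negative integer stream index.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), is.numeric(stream))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + stream * 2654435) %% m)
}

#' FNV-1a hash of a character string
#'
#' 32-bit Fowler-Noll-Vo hash, used as a provenance checksum for configs
#' and input files in run manifests.
#'
#' @param x A character scalar (or raw vector).
#' @return Hex digest string.
#' @export
fnv1a <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = "\n"))
  stopifnot(is.raw(x))
  h <- 2166136261
  for (b in as.integer(x)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.numeric(h) %% 2^32) * 16777619 %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# angle helpers -----------------------------------------------------------

#' Wrap an angle in degrees to (-180, 180]
#' @param deg Numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @keywords internal
wrap_angle <- function(deg) {
  out <- deg %% 360
  out[out > 180] <- out[out > 180] - 360
  out
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Normalise a direction argument to a unit 2-vector
#'
#' Accepts `"+x"`, `"-x"`, `"+y"`, `"-y"`, an angle in degrees, or a
#' numeric length-2 vector.
#' @param axis Direction specification.
#' @return Unit numeric vector of length 2.
#' @keywords internal
as_unit_axis <- function(axis) {
  if (is.character(axis)) {
    axis <- switch(axis,
      "+x" = c(1, 0), "-x" = c(-1, 0),
      "+y" = c(0, 1), "-y" = c(0, -1),
      stop("unknown axis label: ", axis, call. = FALSE)
    )
  }
  if (length(axis) == 1L && is.numeric(axis)) {
    axis <- c(cos(deg2rad(axis)), sin(deg2rad(axis)))
  }
  stopifnot(is.numeric(axis), length(axis) == 2L)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be a nonzero direction", call. = FALSE)
  axis / n
}
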