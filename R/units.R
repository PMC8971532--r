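# Unit conventions: kPa internally, mmHg at I/O; lengths mm, volumes ul
# (1 mm^3 = 1 ul), areas mm^2.

#' Convert pressures between mmHg and kPa
#'
#' All internal mechanics are expressed in kPa; pressures cross the package
#' boundary (EDPVR files, pressure grids) in mmHg and are converted with a
#' fixed factor of 0.133322 kPa per mmHg.
#'
#' @param p Numeric vector of pressures.
#' @return Converted numeric vector.
#' @export
mmHg_to_kPa <- function(p) p * 0.133322

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(p) p / 0.133322

# Evaluate a function with a temporary RNG state so that seeded draws do not
# disturb (and are not disturbed by) the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Gauss-Legendre nodes and weights on [-1, 1] via the Golub-Welsch
# eigenproblem of the Jacobi matrix.
gauss_legendre <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = 2 * e$vectors[1, ord]^2)
}

# exp() with the argument clamped so large trial deformations during root
# bracketing stay finite (exp(500) ~ 7e216) rather than overflowing to Inf.
exp_clamped <- function(x) exp(pmin(x, 500))
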