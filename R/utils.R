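#' Vectorize the strict upper triangle of an FC matrix
#'
#' Flattens the R(R-1)/2 unique off-diagonal correlations into a 1D feature
#' vector, row-major (edge (1,2), (1,3), ..., (1,R), (2,3), ...). This is
#' the representation the CNN, the GAN, and the SVM baseline all consume;
#' the redundant lower triangle and constant diagonal carry no information.
#'
#' @param m square numeric matrix, or an [FCMatrix-class].
#' @return Numeric vector of length R(R-1)/2.
#' @seealso [vecToSymmetric()]
#' @export
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.5
#' upperTriVec(m)
upperTriVec <- function(m) {
  if (is(m, "FCMatrix")) m <- m@values
  # row-major strict upper triangle == column-major strict lower of transpose
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its row-major upper-triangle vector
#'
#' Inverse of [upperTriVec()] up to the diagonal, which is set to `diagValue`.
#'
#' @param v numeric vector of length R(R-1)/2.
#' @param diagValue value placed on the diagonal (1 for correlation matrices).
#' @return Symmetric R x R numeric matrix.
#' @export
vecToSymmetric <- function(v, diagValue = 1) {
  p <- length(v)
  r <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(r - round(r)) > 1e-8)
    stop("length ", p, " is not R(R-1)/2 for integer R")
  r <- as.integer(round(r))
  m <- matrix(0, r, r)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diagValue
  m
}

# Derive a stage-specific 31-bit seed from a global seed and a stage name,
# so every pipeline stage is individually reproducible from one seed.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0 + 12345) %% 2147483647)
}

# A length-1 numeric check used across validators.
isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
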