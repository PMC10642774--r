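#' Check the compartmental property of a matrix
#'
#' A matrix \code{B} is compartmental when its off-diagonal entries are
#' non-negative, its diagonal entries non-positive, and every column sum
#' non-positive.  The negative column sums are the per-pool release rates
#' to the environment.  Invertibility is additionally required for steady
#' states and distribution moments to exist.
#'
#' @param B a square numeric matrix (1/yr).
#' @param tol numeric tolerance for the sign and column-sum checks.
#' @return A list with elements \code{valid} (logical), \code{violations}
#'   (character vector, empty when valid), \code{releaseRates} (numeric,
#'   the negative column sums) and \code{invertible} (logical).
#' @examples
#' validateCompartmental(matrix(-1))            # valid one-pool decay
#' validateCompartmental(matrix(1))$violations  # positive diagonal
#' @export
validateCompartmental <- function(B, tol = 1e-12) {
  if (!is.matrix(B) || !is.numeric(B) || nrow(B) != ncol(B))
    stop("B must be a square numeric matrix", call. = FALSE)
  if (any(!is.finite(B)))
    stop("B contains non-finite entries", call. = FALSE)
  n <- nrow(B)
  msgs <- character()
  offd <- B; diag(offd) <- 0
  if (any(offd < -tol))
    msgs <- c(msgs, "off-diagonal entries of B must be >= 0")
  if (any(diag(B) > tol))
    msgs <- c(msgs, "diagonal entries of B must be <= 0")
  release <- -colSums(B)
  if (any(release < -tol))
    msgs <- c(msgs, "column sums of B must be <= 0 (release rates >= 0)")
  invertible <- abs(det(B)) > tol * max(1, max(abs(B)))^n
  if (!invertible)
    msgs <- c(msgs, "B is numerically singular")
  list(valid = length(msgs) == 0L, violations = msgs,
       releaseRates = release, invertible = invertible)
}

#' Construct a compartmental system
#'
#' @param u numeric vector of external inputs per pool (PgC/yr).
#' @param B square compartmental matrix (1/yr); columns are source pools.
#' @param poolNames optional pool labels; defaults to `pool_1 ...`.
#' @return A [CompartmentalSystem-class] object.
#' @examples
#' sys <- compartmentalSystem(u = 1, B = matrix(-0.5))
#' steadyState(sys)$x_star   # 2 PgC
#' @export
compartmentalSystem <- function(u, B, poolNames = NULL) {
  if (is.null(dim(B))) B <- matrix(B, length(u), length(u))
  if (is.null(poolNames)) poolNames <- paste0("pool_", seq_len(nrow(B)))
  rep <- validateCompartmental(B)
  if (!rep$valid)
    stop("not a valid compartmental matrix: ",
         paste(rep$violations, collapse = "; "), call. = FALSE)
  new("CompartmentalSystem", u = as.numeric(u), B = B,
      poolNames = as.character(poolNames))
}

#' @describeIn compartmentalSystem number of pools
#' @param sys a \code{CompartmentalSystem}.
#' @export
nPools <- function(sys) length(sys@u)

#' Accessors for compartmental systems
#'
#' \code{inputVector} returns the external input vector u (PgC/yr),
#' \code{compartmentalMatrix} the matrix B (1/yr), \code{poolNames} the
#' pool labels and \code{releaseRates} the per-pool release rates
#' (negative column sums of B, 1/yr).
#'
#' @param sys a [CompartmentalSystem-class].
#' @return numeric vector or matrix as described.
#' @export
inputVector <- function(sys) sys@u

#' @rdname inputVector
#' @export
compartmentalMatrix <- function(sys) sys@B

#' @rdname inputVector
#' @export
poolNames <- function(sys) sys@poolNames

#' @rdname inputVector
#' @export
releaseRates <- function(sys) -colSums(sys@B)

setMethod("show", "CompartmentalSystem", function(object) {
  cat("CompartmentalSystem with", nPools(object), "pools\n")
  cat("  pools:", paste(object@poolNames, collapse = ", "), "\n")
  cat("  total input:", format(sum(object@u)), "PgC/yr\n")
  ss <- try(steadyState(object), silent = TRUE)
  if (!inherits(ss, "try-error"))
    cat("  steady-state stock:", format(ss$total_stock), "PgC\n")
  invisible(object)
})

#' Steady state of an autonomous compartmental system
#'
#' Solves \eqn{x^* = -B^{-1} u}, the unique equilibrium of
#' \eqn{\dot x = u + Bx}.
#'
#' @param sys a [CompartmentalSystem-class].
#' @param tol relative tolerance on the residual \eqn{\|Bx^*+u\|}.
#' @return A list of class \code{"SteadyState"} with \code{x_star}
#'   (stocks, PgC), \code{X_star} (diagonal matrix of stocks),
#'   \code{total_stock} (PgC) and \code{total_input} (PgC/yr).
#' @examples
#' steadyState(emanuelModel())$x_star  # 37 452 69 81 1121
#' @export
steadyState <- function(sys, tol = 1e-10) {
  B <- sys@B; u <- sys@u
  xs <- tryCatch(solve(-B, u), error = function(e)
    stop("compartmental matrix is singular; no steady state exists",
         call. = FALSE))
  resid <- max(abs(B %*% xs + u)) / max(1, max(abs(u)))
  if (resid > tol)
    stop("steady-state residual ", format(resid), " exceeds tolerance",
         call. = FALSE)
  if (any(xs < -tol * max(abs(xs))))
    stop("steady state has negative stocks", call. = FALSE)
  xs <- pmax(xs, 0)
  names(xs) <- sys@poolNames
  structure(list(x_star = xs, X_star = diag(xs, nrow = length(xs)),
                 total_stock = sum(xs), total_input = sum(u),
                 residual = resid),
            class = "SteadyState")
}

#' The five-pool global terrestrial carbon model of Emanuel et al.
#'
#' Pre-industrial global carbon cycle with pools for non-woody tree
#' parts, woody tree parts, ground vegetation, detritus/decomposers and
#' active soil carbon.  Gross primary production is 113 PgC/yr, entering
#' the non-woody tree and ground-vegetation pools; equilibrium stocks
#' total 1760 PgC.
#'
#' @return A [CompartmentalSystem-class] with 5 pools.
#' @examples
#' sys <- emanuelModel()
#' sum(steadyState(sys)$x_star)  # 1760 PgC
#' @export
emanuelModel <- function() {
  B <- matrix(c(
    -77/37,      0,      0,      0,        0,
     31/37, -31/452,     0,      0,        0,
         0,      0, -36/69,      0,        0,
     21/37, 15/452,  12/69, -48/81,        0,
         0,  2/452,   6/69,   3/81, -11/1121),
    nrow = 5, ncol = 5, byrow = TRUE)
  nm <- c("nonwoody_tree", "woody_tree", "ground_vegetation",
          "detritus", "active_soil")
  dimnames(B) <- list(nm, nm)
  compartmentalSystem(u = c(77, 0, 36, 0, 0), B = B, poolNames = nm)
}
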