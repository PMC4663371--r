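#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never perturb the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dice overlap coefficient between two binary masks
#'
#' Computes `2|A n B| / (|A| + |B|)` between two logical (or 0/1) arrays of
#' identical shape. Used to quantify how well a thresholded discriminative
#' map recovers a known ground-truth effect region.
#'
#' @param a,b Logical or 0/1 arrays of identical dimensions.
#' @return A number in `[0, 1]`; `NaN` if both masks are empty.
#' @export
#' @examples
#' m1 <- array(c(1, 1, 0, 0), c(2, 2))
#' m2 <- array(c(1, 0, 1, 0), c(2, 2))
#' dice_overlap(m1, m2)
dice_overlap <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks have different dimensions")
  a <- as.logical(a)
  b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}
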