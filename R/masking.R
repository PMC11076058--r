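#' Mask one contiguous block of timesteps in a clip
#'
#' The self-supervised pretext task: a single contiguous block of timesteps
#' is selected uniformly at random and every feature in those rows is
#' replaced with an out-of-range sentinel. The pair (masked input, original
#' clip) is the pretraining example; input and target have the same
#' dimensions.
#'
#' For clips with at least `mask_len` timesteps the block is exactly
#' `mask_len` rows (30 by default, roughly 10 percent of a typical clip). Shorter
#' clips fall back to masking `floor(0.10 * T)` rows, with a minimum of one
#' row.
#'
#' @param x Numeric matrix (`T` x 74), standardized.
#' @param mask_len Block length in timesteps for clips long enough to hold
#'   it; default 30.
#' @param sentinel Value written into the masked cells; default -30, far
#'   outside any standardized feature range.
#' @return A list of class `ser_masked` with elements `input` (masked
#'   matrix), `target` (the untouched original), `mask_start` (1-based first
#'   masked row) and `mask_len` (rows actually masked).
#' @export
#' @examples
#' x <- matrix(rnorm(60 * 74), 60, 74)
#' set.seed(1)
#' mp <- mask_clip(x)
#' mp$mask_len
mask_clip <- function(x, mask_len = 30L, sentinel = MASK_SENTINEL) {
  stopifnot(is.matrix(x), nrow(x) >= 1L)
  T_len <- nrow(x)
  L <- if (T_len < mask_len) max(1L, as.integer(floor(0.10 * T_len))) else
    as.integer(mask_len)
  start <- sample.int(T_len - L + 1L, 1L)
  input <- x
  input[start:(start + L - 1L), ] <- sentinel
  structure(
    list(input = input, target = x, mask_start = start, mask_len = L),
    class = "ser_masked"
  )
}

#' @export
print.ser_masked <- function(x, ...) {
  cat("<ser_masked> ", nrow(x$target), " x ", ncol(x$target),
      " clip, rows ", x$mask_start, "-", x$mask_start + x$mask_len - 1L,
      " masked\n", sep = "")
  invisible(x)
}
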