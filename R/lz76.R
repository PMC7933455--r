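#' Lempel-Ziv 1976 complexity counter
#'
#' Counts the components of the exhaustive production history of a
#' binary sequence, scanning left to right and incrementing the counter
#' at every component that cannot be copied from the already-seen text
#' (self-overlapping copies allowed). The final component is counted
#' whether or not it is novel, the standard convention under which a
#' constant string has c = 2 (one initial symbol plus one long copied
#' run).
#'
#' @param bits A `binary_sequence`, or a plain integer/logical vector
#'   over \{0, 1\}.
#' @return Integer component count `c`, with `1 <= c <= n`.
#' @examples
#' lz76_count(c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))  # 3
#' @export
lz76_count <- function(bits) {
  if (inherits(bits, "binary_sequence")) bits <- bits$bits
  if (is.character(bits) && length(bits) == 1L) {
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  bits <- as.integer(bits)
  if (length(bits) == 0L) stop("lz76_count: empty sequence")
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("lz76_count: sequence must be binary (0/1)")
  }
  lz76_count_cpp(bits)
}

#' Length-normalized Lempel-Ziv complexity score
#'
#' For a random binary source the LZ'76 counter grows like
#' b(n) = n / log2(n); dividing by b(n) yields a score CS(n) = c(n)/b(n)
#' that is approximately length-independent and tends to 1 for an
#' i.i.d. fair-coin sequence.
#'
#' @param c LZ'76 component count (>= 1).
#' @param n Sequence length (>= 2; the normalization is undefined at
#'   n = 1 where log2(n) = 0).
#' @return The normalized score `c * log2(n) / n` (dimensionless,
#'   per-symbol).
#' @export
normalized_cs <- function(c, n) {
  stopifnot(length(c) == length(n) || length(c) == 1L || length(n) == 1L)
  if (any(n < 2)) stop("normalized_cs: n must be >= 2")
  if (any(c < 1)) stop("normalized_cs: c must be >= 1")
  c * log2(n) / n
}

#' Complexity score of one ECG strip
#'
#' Composition of symbolization and LZ'76 counting: binarize the strip
#' by the requested method ([tc_binarize()] or [bd_binarize()]), count
#' components, normalize by b(n) = n / log2(n).
#'
#' @param strip An [ecg_strip()].
#' @param method `"TC"` (threshold crossing) or `"BD"` (beat detection).
#' @param params [bd_params()] used when `method = "BD"`.
#' @return An object of class `complexity_score`: list with `method`,
#'   `c` (counter), `n` (length), `cs` (normalized score), `source`.
#' @export
strip_cs <- function(strip, method = c("TC", "BD"), params = bd_params()) {
  method <- match.arg(method)
  bs <- switch(method,
               TC = tc_binarize(strip),
               BD = bd_binarize(strip, params))
  cc <- lz76_count(bs)
  structure(list(method = method, c = cc, n = bs$n,
                 cs = normalized_cs(cc, bs$n), source = bs$source),
            class = "complexity_score")
}

#' @export
print.complexity_score <- function(x, ...) {
  cat(sprintf("LZ'76 complexity (%s): c = %d, n = %d, CS = %.4f\n",
              x$method, x$c, x$n, x$cs))
  invisible(x)
}
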