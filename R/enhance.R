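#' Depth-by-depth volumetric enhancement
#'
#' The trained 2D generator is applied independently to every C-scan slice
#' of a flow volume and the enhanced slices are restacked, so slice z of
#' the output depends on slice z of the input only. Slices whose size does
#' not satisfy the generator's divisibility contract are reflect-padded to
#' the next multiple and cropped back exactly.
#'
#' @name volumetric_enhance
NULL

#' Reflect-pad a slice to the next multiple of a size contract
#'
#' @param slice en face matrix
#' @param multiple required divisor of both sides (\code{2^n_levels})
#' @return list with \code{padded} and \code{crop} (\code{c(h, w)}, the
#'   original size; cropping \code{padded[1:h, 1:w]} inverts the padding
#'   exactly)
#' @export
pad_or_tile <- function(slice, multiple) {
  h <- nrow(slice); w <- ncol(slice)
  ph <- multiple * ceiling(h / multiple)
  pw <- multiple * ceiling(w / multiple)
  if (ph == h && pw == w) {
    return(list(padded = slice, crop = c(h = h, w = w)))
  }
  pad_axis <- function(n, target) {
    if (n >= target) return(seq_len(target))
    # reflect indices 1..n out to target (period 2n-2, degenerate n=1 -> 1)
    if (n == 1) return(rep(1L, target))
    base <- c(seq_len(n), seq(n - 1, 2))
    rep(base, length.out = target + n)[seq_len(target)]
  }
  list(padded = slice[pad_axis(h, ph), pad_axis(w, pw), drop = FALSE],
       crop = c(h = h, w = w))
}

#' Enhance a flow volume depth-by-depth
#'
#' @param volume flow volume (z, y, x) in \code{[0,1]}
#' @param generator an \code{octa_generator}, or any function mapping an en
#'   face matrix to a same-shape matrix
#' @return enhanced volume, same shape, values clamped to \code{[0,1]}
#' @export
enhance_volume <- function(volume, generator) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  fwd <- if (is.function(generator)) {
    generator
  } else {
    mult <- 2^generator$n_levels
    function(slice) {
      pt <- pad_or_tile(slice, mult)
      out <- generator_forward(generator, pt$padded, train = FALSE)
      out[seq_len(pt$crop["h"]), seq_len(pt$crop["w"]), drop = FALSE]
    }
  }
  out <- volume
  for (z in seq_len(dim(volume)[1])) {
    y <- fwd(volume[z, , ])
    if (!identical(dim(y), dim(volume[z, , ]))) {
      stop("generator changed the slice shape", call. = FALSE)
    }
    out[z, , ] <- y
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
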