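# Minimal GIF89a encoder (variable-width LZW, 12-bit dictionary, 255-byte
# sub-block framing). The image-complexity predictor is defined as the byte
# ratio of a GIF-encoded rendering to its raw pixel buffer, so the encoder
# must be pinned and deterministic; images here are tiny (a few kB).

lzw_compress <- function(indices, min_code_size) {
  clear <- bitwShiftL(1L, min_code_size)
  eoi <- clear + 1L
  out <- integer(0) # bytes
  buf <- 0
  nbits <- 0
  width <- min_code_size + 1L
  emit <- function(code) {
    buf <<- buf + code * 2^nbits
    nbits <<- nbits + width
    while (nbits >= 8) {
      out[[length(out) + 1L]] <<- buf %% 256
      buf <<- buf %/% 256
      nbits <<- nbits - 8
    }
  }
  dict <- new.env(parent = emptyenv())
  next_code <- eoi + 1L
  reset <- function() {
    dict <<- new.env(parent = emptyenv())
    next_code <<- eoi + 1L
    width <<- min_code_size + 1L
  }
  emit(clear)
  cur <- indices[1]
  if (length(indices) > 1) {
    for (p in indices[-1]) {
      key <- paste0(cur, "_", p)
      ext <- dict[[key]]
      if (!is.null(ext)) {
        cur <- ext
      } else {
        emit(cur)
        dict[[key]] <- next_code
        if (next_code == bitwShiftL(1L, width) && width < 12L) width <- width + 1L
        next_code <- next_code + 1L
        if (next_code >= 4096L) {
          emit(clear)
          reset()
        }
        cur <- p
      }
    }
  }
  emit(cur)
  emit(eoi)
  if (nbits > 0) out[[length(out) + 1L]] <- buf %% 256
  as.raw(out)
}

u16 <- function(x) as.raw(c(x %% 256, x %/% 256))

#' Encode a grayscale pixel matrix as GIF89a bytes
#'
#' @param pixels Integer matrix of gray levels (at most 256 distinct).
#' @return Raw vector holding a complete GIF file.
#' @export
gif_encode <- function(pixels) {
  stopifnot(is.matrix(pixels))
  vals <- sort(unique(as.vector(pixels)))
  if (length(vals) > 256) stop("more than 256 gray levels", call. = FALSE)
  k <- max(1L, ceiling(log2(length(vals))))
  n_pal <- bitwShiftL(1L, k)
  idx <- match(as.vector(t(pixels)), vals) - 1L # row-major pixel order
  h <- nrow(pixels)
  w <- ncol(pixels)
  mcs <- max(2L, k)
  data <- lzw_compress(idx, mcs)
  # 255-byte sub-blocks
  blocks <- raw(0)
  pos <- 1L
  while (pos <= length(data)) {
    chunk <- data[pos:min(pos + 254L, length(data))]
    blocks <- c(blocks, as.raw(length(chunk)), chunk)
    pos <- pos + 255L
  }
  pal <- as.raw(rep(c(vals, rep(0L, n_pal - length(vals))), each = 3))
  c(charToRaw("GIF89a"),
    u16(w), u16(h),
    as.raw(bitwOr(0x80L, bitwOr(bitwShiftL(k - 1L, 4L), k - 1L))),
    as.raw(c(0, 0)),
    pal,
    as.raw(0x2C), u16(0), u16(0), u16(w), u16(h), as.raw(0),
    as.raw(mcs),
    blocks,
    as.raw(c(0, 0x3B)))
}

#' Image-complexity index of a rendered letter string
#'
#' Renders the string with the synthetic monospaced glyph face and returns
#' the ratio of the GIF-compressed byte length to the uncompressed pixel
#' buffer size (width x height x 1 byte at 8-bit depth). Visually simple
#' (repetitive) strings compress further and score lower; the index grows
#' with rendered width and glyph variety.
#'
#' @param strings Character vector of lower-case letter strings.
#' @param config A [render_config()].
#' @return Numeric vector of compression ratios (strictly positive).
#' @export
#' @examples
#' gif_index(c("take", "aaaa"))
gif_index <- function(strings, config = render_config()) {
  vapply(strings, function(s) {
    img <- render_string(s, config)
    length(gif_encode(img)) / (nrow(img) * ncol(img) * (config$bit_depth / 8))
  }, numeric(1), USE.NAMES = FALSE)
}
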