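# 5x7 dot-matrix glyphs for a-z (plus blank). A synthetic monospaced face:
# deterministic across platforms, which is what the image-complexity
# predictor needs; typographic fidelity is irrelevant, only that letters
# have distinct, letter-like pixel patterns.
glyph_rows <- function() {
  list(
    a = c(".XXX.", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
    b = c("XXXX.", "X...X", "X...X", "XXXX.", "X...X", "X...X", "XXXX."),
    c = c(".XXX.", "X...X", "X....", "X....", "X....", "X...X", ".XXX."),
    d = c("XXXX.", "X...X", "X...X", "X...X", "X...X", "X...X", "XXXX."),
    e = c("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "XXXXX"),
    f = c("XXXXX", "X....", "X....", "XXXX.", "X....", "X....", "X...."),
    g = c(".XXX.", "X...X", "X....", "X.XXX", "X...X", "X...X", ".XXXX"),
    h = c("X...X", "X...X", "X...X", "XXXXX", "X...X", "X...X", "X...X"),
    i = c(".XXX.", "..X..", "..X..", "..X..", "..X..", "..X..", ".XXX."),
    j = c("..XXX", "...X.", "...X.", "...X.", "...X.", "X..X.", ".XX.."),
    k = c("X...X", "X..X.", "X.X..", "XX...", "X.X..", "X..X.", "X...X"),
    l = c("X....", "X....", "X....", "X....", "X....", "X....", "XXXXX"),
    m = c("X...X", "XX.XX", "X.X.X", "X.X.X", "X...X", "X...X", "X...X"),
    n = c("X...X", "XX..X", "X.X.X", "X..XX", "X...X", "X...X", "X...X"),
    o = c(".XXX.", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
    p = c("XXXX.", "X...X", "X...X", "XXXX.", "X....", "X....", "X...."),
    q = c(".XXX.", "X...X", "X...X", "X...X", "X...X", "X..XX", ".XXXX"),
    r = c("XXXX.", "X...X", "X...X", "XXXX.", "X.X..", "X..X.", "X...X"),
    s = c(".XXXX", "X....", "X....", ".XXX.", "....X", "....X", "XXXX."),
    t = c("XXXXX", "..X..", "..X..", "..X..", "..X..", "..X..", "..X.."),
    u = c("X...X", "X...X", "X...X", "X...X", "X...X", "X...X", ".XXX."),
    v = c("X...X", "X...X", "X...X", "X...X", ".X.X.", ".X.X.", "..X.."),
    w = c("X...X", "X...X", "X...X", "X.X.X", "X.X.X", "XX.XX", "X...X"),
    x = c("X...X", ".X.X.", "..X..", "..X..", "..X..", ".X.X.", "X...X"),
    y = c("X...X", ".X.X.", "..X..", "..X..", "..X..", "..X..", "..X.."),
    z = c("XXXXX", "....X", "...X.", "..X..", ".X...", "X....", "XXXXX"),
    ` ` = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
  )
}

#' Rendering configuration for the image-complexity predictor
#'
#' Describes the synthetic monospaced raster used by [gif_index()]: each
#' letter occupies a fixed cell into which a 5x7 dot glyph is drawn.
#'
#' @param cell_width,cell_height Cell size in pixels (must fit the 5x7
#'   glyph; the remainder is inter-letter / vertical padding).
#' @param canvas_cells Width of the canvas in letter cells. Strings are
#'   centered on a fixed-width background — as stimuli are on a screen —
#'   so the uncompressed size is constant and visually denser strings
#'   yield larger compression ratios. `NULL` renders a tight canvas the
#'   width of the string.
#' @param foreground,background Gray levels (0-255), must differ.
#' @param bit_depth Bits per pixel of the uncompressed buffer (8).
#' @return An object of class `render_config`.
#' @export
render_config <- function(cell_width = 6, cell_height = 9, canvas_cells = 16,
                          foreground = 0, background = 192, bit_depth = 8) {
  stopifnot(cell_width >= 5, cell_height >= 7, bit_depth %in% c(8))
  if (foreground == background) stop("gray levels must differ", call. = FALSE)
  structure(list(cell_width = cell_width, cell_height = cell_height,
                 canvas_cells = canvas_cells,
                 foreground = foreground, background = background,
                 bit_depth = bit_depth),
            class = "render_config")
}

#' Render a letter string as a grayscale pixel matrix
#'
#' @param string Lower-case letters (space allowed for a blank cell).
#' @param config A [render_config()].
#' @return Integer matrix (rows = `cell_height`, cols = `cell_width *
#'   nchar(string)`) of gray levels.
#' @export
render_string <- function(string, config = render_config()) {
  stopifnot(inherits(config, "render_config"), nchar(string) >= 1)
  glyphs <- glyph_rows()
  chars <- strsplit(string, "")[[1]]
  bad <- setdiff(chars, names(glyphs))
  if (length(bad) > 0) {
    stop("unrenderable character(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  n_cells <- config$canvas_cells %||% length(chars)
  if (length(chars) > n_cells) {
    stop("string of ", length(chars), " letters exceeds the ", n_cells,
         "-cell canvas", call. = FALSE)
  }
  w <- config$cell_width * n_cells
  img <- matrix(config$background, nrow = config$cell_height, ncol = w)
  row0 <- floor((config$cell_height - 7) / 2)
  cell0 <- floor((n_cells - length(chars)) / 2)
  for (k in seq_along(chars)) {
    pat <- glyphs[[chars[k]]]
    col0 <- (cell0 + k - 1) * config$cell_width
    for (r in 1:7) {
      on <- which(strsplit(pat[r], "")[[1]] == "X")
      if (length(on) > 0) img[row0 + r, col0 + on] <- config$foreground
    }
  }
  img
}
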