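# Minimal 5x7 bitmap font bundled in code so glyph templates and rendered
# fixture pages never depend on external font files. Only the characters the
# report fixtures need are defined.
.FVL_FONT <- list(
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "e" = c(".....", ".....", ".###.", "#...#", "#####", "#....", ".###."),
  "x" = c(".....", ".....", "#...#", ".#.#.", "..#..", ".#.#.", "#...#"),
  "/" = c("....#", "....#", "...#.", "..#..", ".#...", "#....", "#...."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)

#' Render text to a small grayscale raster
#'
#' Rasterizes a string with the package's built-in 5x7 bitmap font (the one
#' the synthetic report renderer uses), with integer upscaling and a
#' background border. Used to build [GlyphTemplate-class] rasters and the
#' fixture pages, so a template always matches its rendered occurrence
#' pixel-for-pixel.
#'
#' @param text string; only characters in the bundled font are allowed.
#' @param scale integer upscaling factor.
#' @param ink,bg intensities (0-255) for set and unset pixels.
#' @param pad background border width in (scaled) pixels.
#' @return numeric intensity matrix.
#' @examples
#' dim(textGlyph("2"))
#' @export
textGlyph <- function(text, scale = 2L, ink = 0, bg = 255, pad = 1L) {
  chars <- strsplit(text, "")[[1]]
  if (length(chars) == 0L) .fvlStop("fvlInvalidInput", "empty text")
  miss <- setdiff(chars, names(.FVL_FONT))
  if (length(miss))
    .fvlStop("fvlInvalidInput",
             paste0("characters not in the bundled font: ",
                    paste(unique(miss), collapse = "")))
  cells <- lapply(chars, function(ch) {
    rows <- .FVL_FONT[[ch]]
    m <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]] == "#"))
    m
  })
  spacer <- matrix(FALSE, 7L, 1L)
  bits <- cells[[1]]
  for (i in seq_along(cells)[-1]) bits <- cbind(bits, spacer, cells[[i]])
  scale <- as.integer(scale)
  bits <- bits[rep(seq_len(nrow(bits)), each = scale),
               rep(seq_len(ncol(bits)), each = scale), drop = FALSE]
  out <- matrix(bg, nrow(bits) + 2L * pad, ncol(bits) + 2L * pad)
  out[pad + seq_len(nrow(bits)), pad + seq_len(ncol(bits))] <-
    ifelse(bits, ink, bg)
  out
}
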