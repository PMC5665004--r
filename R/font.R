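## Minimal 5x7 bitmap font for rendering label text into image matrices.
## Glyph shapes only need to look like typed label text to a human; nothing
## in the pipeline reads them back (transcription is deliberately
## human/CSV-driven). Text is rendered uppercase. Each glyph is 7 rows of
## 5-bit integers, top row first.

.labelFont <- local({
  g <- list(
    "A" = c(0x0E,0x11,0x11,0x1F,0x11,0x11,0x11),
    "B" = c(0x1E,0x11,0x11,0x1E,0x11,0x11,0x1E),
    "C" = c(0x0E,0x11,0x10,0x10,0x10,0x11,0x0E),
    "D" = c(0x1E,0x11,0x11,0x11,0x11,0x11,0x1E),
    "E" = c(0x1F,0x10,0x10,0x1E,0x10,0x10,0x1F),
    "F" = c(0x1F,0x10,0x10,0x1E,0x10,0x10,0x10),
    "G" = c(0x0E,0x11,0x10,0x17,0x11,0x11,0x0F),
    "H" = c(0x11,0x11,0x11,0x1F,0x11,0x11,0x11),
    "I" = c(0x0E,0x04,0x04,0x04,0x04,0x04,0x0E),
    "J" = c(0x07,0x02,0x02,0x02,0x02,0x12,0x0C),
    "K" = c(0x11,0x12,0x14,0x18,0x14,0x12,0x11),
    "L" = c(0x10,0x10,0x10,0x10,0x10,0x10,0x1F),
    "M" = c(0x11,0x1B,0x15,0x15,0x11,0x11,0x11),
    "N" = c(0x11,0x19,0x15,0x13,0x11,0x11,0x11),
    "O" = c(0x0E,0x11,0x11,0x11,0x11,0x11,0x0E),
    "P" = c(0x1E,0x11,0x11,0x1E,0x10,0x10,0x10),
    "Q" = c(0x0E,0x11,0x11,0x11,0x15,0x12,0x0D),
    "R" = c(0x1E,0x11,0x11,0x1E,0x14,0x12,0x11),
    "S" = c(0x0F,0x10,0x10,0x0E,0x01,0x01,0x1E),
    "T" = c(0x1F,0x04,0x04,0x04,0x04,0x04,0x04),
    "U" = c(0x11,0x11,0x11,0x11,0x11,0x11,0x0E),
    "V" = c(0x11,0x11,0x11,0x11,0x0A,0x0A,0x04),
    "W" = c(0x11,0x11,0x11,0x15,0x15,0x1B,0x11),
    "X" = c(0x11,0x11,0x0A,0x04,0x0A,0x11,0x11),
    "Y" = c(0x11,0x11,0x0A,0x04,0x04,0x04,0x04),
    "Z" = c(0x1F,0x01,0x02,0x04,0x08,0x10,0x1F),
    "0" = c(0x0E,0x11,0x13,0x15,0x19,0x11,0x0E),
    "1" = c(0x04,0x0C,0x04,0x04,0x04,0x04,0x0E),
    "2" = c(0x0E,0x11,0x01,0x02,0x04,0x08,0x1F),
    "3" = c(0x1F,0x02,0x04,0x02,0x01,0x11,0x0E),
    "4" = c(0x02,0x06,0x0A,0x12,0x1F,0x02,0x02),
    "5" = c(0x1F,0x10,0x1E,0x01,0x01,0x11,0x0E),
    "6" = c(0x06,0x08,0x10,0x1E,0x11,0x11,0x0E),
    "7" = c(0x1F,0x01,0x02,0x04,0x08,0x08,0x08),
    "8" = c(0x0E,0x11,0x11,0x0E,0x11,0x11,0x0E),
    "9" = c(0x0E,0x11,0x11,0x0F,0x01,0x02,0x0C),
    " " = c(0,0,0,0,0,0,0),
    "." = c(0,0,0,0,0,0x06,0x06),
    "," = c(0,0,0,0,0x06,0x04,0x08),
    "-" = c(0,0,0,0x0E,0,0,0),
    "/" = c(0x01,0x02,0x02,0x04,0x08,0x08,0x10),
    ":" = c(0,0x06,0x06,0,0x06,0x06,0),
    "'" = c(0x04,0x04,0x08,0,0,0,0),
    "(" = c(0x02,0x04,0x08,0x08,0x08,0x04,0x02),
    ")" = c(0x08,0x04,0x02,0x02,0x02,0x04,0x08),
    "?" = c(0x0E,0x11,0x01,0x02,0x04,0,0x04),
    "&" = c(0x0C,0x12,0x14,0x08,0x15,0x12,0x0D)
  )
  lapply(g, function(rows) {
    m <- matrix(0L, 7L, 5L)
    for (r in 1:7) m[r, ] <- as.integer(bitwAnd(bitwShiftR(rows[r], 4:0), 1L))
    m
  })
})

# build a logical pixel mask (EBImage [x, y] orientation) for a block of
# text lines; unknown glyphs render as spaces
.textMask <- function(lines, scale = 2L, lineGap = 3L) {
  lh <- (7L + lineGap) * scale
  w <- max(1L, max(nchar(lines)) * 6L * scale)
  h <- length(lines) * lh
  mask <- matrix(FALSE, w, h)
  one <- matrix(1L, scale, scale)
  for (li in seq_along(lines)) {
    chars <- strsplit(toupper(lines[li]), "")[[1L]]
    cx <- 1L
    y <- (li - 1L) * lh + 1L
    for (ch in chars) {
      glyph <- .labelFont[[ch]]
      if (!is.null(glyph) && any(glyph == 1L)) {
        g <- kronecker(t(glyph), one) == 1L
        mask[cx:(cx + nrow(g) - 1L), y:(y + ncol(g) - 1L)] <-
          mask[cx:(cx + nrow(g) - 1L), y:(y + ncol(g) - 1L)] | g
      }
      cx <- cx + 6L * scale
    }
  }
  mask
}

# draw text lines into canvas with one blit; (x, y) is the top-left corner
.drawText <- function(canvas, x, y, lines, scale = 2L, value = 0.08, lineGap = 3L) {
  lines <- lines[!is.na(lines) & nzchar(lines)]
  if (!length(lines)) return(canvas)
  mask <- .textMask(lines, scale = scale, lineGap = lineGap)
  xs <- x:(x + nrow(mask) - 1L)
  ys <- y:(y + ncol(mask) - 1L)
  okx <- xs >= 1L & xs <= nrow(canvas); oky <- ys >= 1L & ys <= ncol(canvas)
  if (!any(okx) || !any(oky)) return(canvas)
  sub <- canvas[xs[okx], ys[oky], drop = FALSE]
  sub[mask[okx, oky, drop = FALSE]] <- value
  canvas[xs[okx], ys[oky]] <- sub
  canvas
}
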