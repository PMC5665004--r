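## ECC200 DataMatrix encoder/decoder (square symbols 10x10 .. 26x26).
##
## Specimen barcodes are short ASCII payloads ("NHMUK" + zero-padded digits),
## which fit comfortably in a single-region square symbol, so only that part
## of the symbology is implemented: ASCII encodation (with digit-pair
## compaction), Reed-Solomon error correction over GF(256) with the
## DataMatrix field polynomial, and the standard utah/corner bit placement.

# GF(256) log/antilog tables, field polynomial x^8+x^5+x^3+x^2+1 (0x12D)
.dmGF <- local({
  exps <- integer(510L)
  logs <- integer(256L)
  x <- 1L
  for (i in 0:254) {
    exps[i + 1L] <- x
    logs[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 301L)
  }
  exps[256:510] <- exps[1:255]
  list(exp = exps, log = logs)
})

.gfMul <- function(a, b) {
  out <- integer(length(a) * 0L + max(length(a), length(b)))
  a <- rep_len(as.integer(a), length(out))
  b <- rep_len(as.integer(b), length(out))
  nz <- a != 0L & b != 0L
  out[nz] <- .dmGF$exp[((.dmGF$log[a[nz] + 1L] + .dmGF$log[b[nz] + 1L]) %% 255L) + 1L]
  out
}

.gfInv <- function(a) {
  stopifnot(a != 0L)
  .dmGF$exp[(255L - .dmGF$log[a + 1L]) %% 255L + 1L]
}

# polynomial coefficients highest degree first
.gfPolyEval <- function(p, x) {
  y <- 0L
  for (coef in p) y <- bitwXor(.gfMul(y, x), as.integer(coef))
  y
}

.gfPolyMul <- function(p, q) {
  out <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    out[i:(i + length(q) - 1L)] <- bitwXor(out[i:(i + length(q) - 1L)], .gfMul(p[i], q))
  }
  out
}

# generator polynomial with roots alpha^1 .. alpha^necc (DataMatrix fcr = 1)
.rsGenerator <- function(necc) {
  g <- 1L
  for (i in seq_len(necc)) g <- .gfPolyMul(g, c(1L, .dmGF$exp[i + 1L]))
  g
}

.rsEncode <- function(data, necc) {
  gen <- .rsGenerator(necc)
  buf <- c(as.integer(data), integer(necc))
  for (i in seq_along(data)) {
    coef <- buf[i]
    if (coef != 0L) {
      idx <- i + seq_along(gen) - 1L
      buf[idx] <- bitwXor(buf[idx], .gfMul(gen, coef))
    }
  }
  c(as.integer(data), buf[(length(data) + 1L):length(buf)])
}

# Berlekamp-Massey + Chien + Forney; returns corrected message or NULL
.rsDecode <- function(msg, necc) {
  msg <- as.integer(msg)
  n <- length(msg)
  synd <- vapply(seq_len(necc), function(j) .gfPolyEval(msg, .dmGF$exp[j + 1L]), integer(1L))
  if (all(synd == 0L)) return(msg)

  # error locator via Berlekamp-Massey
  errLoc <- 1L; oldLoc <- 1L
  for (i in seq_len(necc)) {
    delta <- synd[i]
    if (length(errLoc) > 1L) {
      for (j in 2:length(errLoc)) {
        delta <- bitwXor(delta, .gfMul(errLoc[length(errLoc) - j + 1L], synd[i - j + 1L]))
      }
    }
    oldLoc <- c(oldLoc, 0L)
    if (delta != 0L) {
      if (length(oldLoc) > length(errLoc)) {
        newLoc <- .gfMul(oldLoc, delta)
        oldLoc <- .gfMul(errLoc, .gfInv(delta))
        errLoc <- newLoc
      }
      pad <- length(errLoc) - length(oldLoc)
      errLoc <- bitwXor(errLoc, c(integer(pad), .gfMul(oldLoc, delta)))
    }
  }
  while (length(errLoc) > 1L && errLoc[1L] == 0L) errLoc <- errLoc[-1L]
  nerr <- length(errLoc) - 1L
  if (nerr == 0L || 2L * nerr > necc) return(NULL)

  # Chien search: positions counted from the right of msg
  pos <- integer(0L)
  for (p in 0:(n - 1L)) {
    xinv <- .dmGF$exp[(255L - p) %% 255L + 1L]
    if (.gfPolyEval(errLoc, xinv) == 0L) pos <- c(pos, p)
  }
  if (length(pos) != nerr) return(NULL)

  # Forney (fcr = 1): omega = synd * errLoc mod x^necc
  syndPoly <- rev(synd)                       # highest degree first
  omega <- .gfPolyMul(syndPoly, errLoc)
  omega <- omega[(length(omega) - necc + 1L):length(omega)]
  for (p in pos) {
    xinv <- .dmGF$exp[(255L - p) %% 255L + 1L]
    # Lambda'(xinv): derivative keeps odd-degree coefficients
    deg <- length(errLoc) - 1L
    dval <- 0L
    for (k in seq_len(deg)) {             # coefficient of x^k is errLoc[deg - k + 1]
      if (k %% 2L == 1L) {
        coef <- errLoc[deg - k + 1L]
        xpow <- if (k == 1L) 1L else .gfPolyEval(c(1L, integer(k - 1L)), xinv)
        dval <- bitwXor(dval, .gfMul(coef, xpow))
      }
    }
    if (dval == 0L) return(NULL)
    oval <- .gfPolyEval(omega, xinv)
    mag <- .gfMul(oval, .gfInv(dval))
    idx <- n - p
    msg[idx] <- bitwXor(msg[idx], mag)
  }
  synd2 <- vapply(seq_len(necc), function(j) .gfPolyEval(msg, .dmGF$exp[j + 1L]), integer(1L))
  if (any(synd2 != 0L)) return(NULL)
  msg
}

# symbol size -> (data codewords, ecc codewords)
.dmSizes <- data.frame(
  size = c(10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L, 26L),
  ncw  = c(3L, 5L, 8L, 12L, 18L, 22L, 30L, 36L, 44L),
  necc = c(5L, 7L, 10L, 12L, 14L, 18L, 20L, 24L, 28L)
)

# ASCII encodation with digit-pair compaction
.dmEncodeAscii <- function(text) {
  bytes <- utf8ToInt(text)
  if (any(bytes > 127L)) stop("DataMatrix payload must be ASCII")
  out <- integer(0L)
  i <- 1L
  while (i <= length(bytes)) {
    if (i < length(bytes) &&
        bytes[i] >= 48L && bytes[i] <= 57L &&
        bytes[i + 1L] >= 48L && bytes[i + 1L] <= 57L) {
      out <- c(out, 130L + (bytes[i] - 48L) * 10L + (bytes[i + 1L] - 48L))
      i <- i + 2L
    } else {
      out <- c(out, bytes[i] + 1L)
      i <- i + 1L
    }
  }
  out
}

.dmDecodeAscii <- function(cw) {
  out <- character(0L)
  for (v in cw) {
    if (v == 129L) break                      # pad
    if (v >= 1L && v <= 128L) out <- c(out, intToUtf8(v - 1L))
    else if (v >= 130L && v <= 229L) out <- c(out, sprintf("%02d", v - 130L))
    else return(NULL)                          # unsupported encodation switch
  }
  paste(out, collapse = "")
}

# 253-state randomised padding after the first explicit pad codeword
.dmPad <- function(cw, ncw) {
  if (length(cw) > ncw) stop("payload too long for symbol")
  if (length(cw) == ncw) return(cw)
  cw <- c(cw, 129L)
  while (length(cw) < ncw) {
    p <- length(cw) + 1L
    v <- 129L + ((149L * p) %% 253L) + 1L
    if (v > 254L) v <- v - 254L
    cw <- c(cw, v)
  }
  cw
}

# ISO 16022 annex F placement of codeword bits in the data region.
# Returns an nrow x ncol matrix; entry chr*10+bit marks bit `bit` of
# codeword `chr`; -1/-2 are the fixed dark/light corner modules.
.dmPlacement <- function(nrow, ncol) {
  arr <- matrix(0L, nrow, ncol)
  module <- function(r, c, chr, bit) {
    if (r < 0L) { r <- r + nrow; c <- c + 4L - ((nrow + 4L) %% 8L) }
    if (c < 0L) { c <- c + ncol; r <- r + 4L - ((ncol + 4L) %% 8L) }
    arr[r + 1L, c + 1L] <<- chr * 10L + bit
  }
  utah <- function(r, c, chr) {
    module(r - 2L, c - 2L, chr, 1L); module(r - 2L, c - 1L, chr, 2L)
    module(r - 1L, c - 2L, chr, 3L); module(r - 1L, c - 1L, chr, 4L)
    module(r - 1L, c, chr, 5L); module(r, c - 2L, chr, 6L)
    module(r, c - 1L, chr, 7L); module(r, c, chr, 8L)
  }
  corner1 <- function(chr) {
    module(nrow - 1L, 0L, chr, 1L); module(nrow - 1L, 1L, chr, 2L)
    module(nrow - 1L, 2L, chr, 3L); module(0L, ncol - 2L, chr, 4L)
    module(0L, ncol - 1L, chr, 5L); module(1L, ncol - 1L, chr, 6L)
    module(2L, ncol - 1L, chr, 7L); module(3L, ncol - 1L, chr, 8L)
  }
  corner2 <- function(chr) {
    module(nrow - 3L, 0L, chr, 1L); module(nrow - 2L, 0L, chr, 2L)
    module(nrow - 1L, 0L, chr, 3L); module(0L, ncol - 4L, chr, 4L)
    module(0L, ncol - 3L, chr, 5L); module(0L, ncol - 2L, chr, 6L)
    module(0L, ncol - 1L, chr, 7L); module(1L, ncol - 1L, chr, 8L)
  }
  corner3 <- function(chr) {
    module(nrow - 3L, 0L, chr, 1L); module(nrow - 2L, 0L, chr, 2L)
    module(nrow - 1L, 0L, chr, 3L); module(0L, ncol - 2L, chr, 4L)
    module(0L, ncol - 1L, chr, 5L); module(1L, ncol - 1L, chr, 6L)
    module(2L, ncol - 1L, chr, 7L); module(3L, ncol - 1L, chr, 8L)
  }
  corner4 <- function(chr) {
    module(nrow - 1L, 0L, chr, 1L); module(nrow - 1L, ncol - 1L, chr, 2L)
    module(0L, ncol - 3L, chr, 3L); module(0L, ncol - 2L, chr, 4L)
    module(0L, ncol - 1L, chr, 5L); module(1L, ncol - 3L, chr, 6L)
    module(1L, ncol - 2L, chr, 7L); module(1L, ncol - 1L, chr, 8L)
  }
  chr <- 1L; r <- 4L; cc <- 0L
  repeat {
    if (r == nrow && cc == 0L) { corner1(chr); chr <- chr + 1L }
    if (r == nrow - 2L && cc == 0L && (ncol %% 4L) != 0L) { corner2(chr); chr <- chr + 1L }
    if (r == nrow - 2L && cc == 0L && (ncol %% 8L) == 4L) { corner3(chr); chr <- chr + 1L }
    if (r == nrow + 4L && cc == 2L && (ncol %% 8L) == 0L) { corner4(chr); chr <- chr + 1L }
    repeat {
      if (r < nrow && cc >= 0L && arr[r + 1L, cc + 1L] == 0L) { utah(r, cc, chr); chr <- chr + 1L }
      r <- r - 2L; cc <- cc + 2L
      if (!(r >= 0L && cc < ncol)) break
    }
    r <- r + 1L; cc <- cc + 3L
    repeat {
      if (r >= 0L && cc < ncol && arr[r + 1L, cc + 1L] == 0L) { utah(r, cc, chr); chr <- chr + 1L }
      r <- r + 2L; cc <- cc - 2L
      if (!(r < nrow && cc >= 0L)) break
    }
    r <- r + 3L; cc <- cc + 1L
    if (!(r < nrow || cc < ncol)) break
  }
  if (arr[nrow, ncol] == 0L) {
    arr[nrow, ncol] <- -1L; arr[nrow - 1L, ncol - 1L] <- -1L
    arr[nrow - 1L, ncol] <- -2L; arr[nrow, ncol - 1L] <- -2L
  }
  arr
}

.dmPlacementCache <- new.env(parent = emptyenv())

.dmPlacementFor <- function(n) {
  key <- as.character(n)
  if (is.null(.dmPlacementCache[[key]])) .dmPlacementCache[[key]] <- .dmPlacement(n, n)
  .dmPlacementCache[[key]]
}

#' Encode an ASCII payload as a DataMatrix module matrix
#'
#' Produces the module pattern (1 = dark) of a square ECC200 DataMatrix
#' symbol, including the L-shaped finder and the alternating timing tracks.
#' The smallest symbol size (10x10 to 26x26 modules) that holds the payload
#' is chosen automatically.
#'
#' @param text ASCII payload, at most ~30 characters depending on digit
#'   content.
#' @return Integer matrix of 0/1 modules, dark = 1.
#' @examples
#' m <- encodeDataMatrix("NHMUK010000001")
#' dim(m)
#' @export
encodeDataMatrix <- function(text) {
  cw <- .dmEncodeAscii(text)
  row <- .dmSizes[.dmSizes$ncw >= length(cw), , drop = FALSE]
  if (nrow(row) == 0L) stop("payload too long for supported symbol sizes")
  row <- row[1L, ]
  full <- .rsEncode(.dmPad(cw, row$ncw), row$necc)
  n <- row$size
  map <- .dmPlacementFor(n - 2L)
  region <- matrix(0L, n - 2L, n - 2L)
  for (k in seq_along(full)) {
    v <- full[k]
    for (b in 1:8) {
      bit <- bitwAnd(bitwShiftR(v, 8L - b), 1L)
      region[map == k * 10L + b] <- bit
    }
  }
  region[map == -1L] <- 1L
  region[map == -2L] <- 0L
  sym <- matrix(0L, n, n)
  sym[2:(n - 1L), 2:(n - 1L)] <- region
  sym[, 1L] <- 1L                                   # solid left edge
  sym[n, ] <- 1L                                    # solid bottom edge
  sym[1L, ] <- as.integer(seq_len(n) %% 2L == 1L)   # timing, top
  sym[, n] <- as.integer(seq_len(n) %% 2L == 0L)    # timing, right
  sym
}

# decode a 0/1 module matrix back to its payload, correcting codeword errors
.dmDecodeModules <- function(sym) {
  n <- nrow(sym)
  if (n != ncol(sym)) return(NULL)
  row <- .dmSizes[.dmSizes$size == n, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  map <- .dmPlacementFor(n - 2L)
  region <- sym[2:(n - 1L), 2:(n - 1L)]
  ncwTot <- row$ncw + row$necc
  cw <- integer(ncwTot)
  for (k in seq_len(ncwTot)) {
    v <- 0L
    for (b in 1:8) {
      idx <- which(map == k * 10L + b)
      if (length(idx) != 1L) return(NULL)
      v <- bitwOr(bitwShiftL(v, 1L), as.integer(region[idx]))
    }
    cw[k] <- v
  }
  corrected <- .rsDecode(cw, row$necc)
  if (is.null(corrected)) return(NULL)
  .dmDecodeAscii(corrected[seq_len(row$ncw)])
}

# verify finder + timing pattern of a sampled module grid; exact match required
.dmFinderOk <- function(sym) {
  n <- nrow(sym)
  all(sym[, 1L] == 1L) && all(sym[n, ] == 1L) &&
    all(sym[1L, ] == as.integer(seq_len(n) %% 2L == 1L)) &&
    all(sym[, n] == as.integer(seq_len(n) %% 2L == 0L))
}

# sample a candidate bounding box of a binarised image at every supported
# symbol size; return the decoded payload of the first verifying grid
.dmTryBox <- function(dark, x0, x1, y0, y1) {
  w <- x1 - x0 + 1L
  h <- y1 - y0 + 1L
  for (n in .dmSizes$size) {
    px <- w / n
    py <- h / n
    if (px < 2 || py < 2) next
    xs <- round(x0 + (seq_len(n) - 0.5) * px)
    ys <- round(y0 + (seq_len(n) - 0.5) * py)
    sym <- t(dark[xs, ys, drop = FALSE]) * 1L     # rows = image y, cols = x
    if (!.dmFinderOk(sym)) next
    payload <- .dmDecodeModules(sym)
    if (!is.null(payload) && nzchar(payload)) return(payload)
  }
  NULL
}

#' Decode DataMatrix symbols from a greyscale image
#'
#' Binarises the image, locates candidate symbols as large connected dark
#' components whose bounding box carries the L-shaped finder pattern, samples
#' the module grid (independent horizontal and vertical pitch, so symbols
#' survive anisotropic resizing) and decodes with Reed-Solomon error
#' correction. Rotation is not handled: symbols are expected upright, as
#' produced by a flatbed-style imaging rig.
#'
#' @param img An \code{EBImage::Image}, or a numeric matrix in [0,1] indexed
#'   [x, y] (EBImage convention).
#' @param maxCandidates Number of large dark components to probe.
#' @return A list with \code{ok} (logical), \code{payload} (character or NA),
#'   \code{nSymbols} (number of decodable symbols found) and \code{reason}.
#' @examples
#' sym <- encodeDataMatrix("NHMUK010000001")
#' img <- 1 - t(sym)[rep(seq_len(ncol(sym)), each = 6), rep(seq_len(nrow(sym)), each = 6)]
#' pad <- matrix(1, nrow(img) + 24, ncol(img) + 24)
#' pad[12 + seq_len(nrow(img)), 12 + seq_len(ncol(img))] <- img
#' decodeDataMatrix(pad)$payload
#' @export
decodeDataMatrix <- function(img, maxCandidates = 8L) {
  m <- if (methods::is(img, "Image")) EBImage::imageData(EBImage::channel(img, "gray")) else img
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  dark <- m < 0.5

  if (!any(dark)) return(list(ok = FALSE, payload = NA_character_, nSymbols = 0L, reason = "no dark pixels"))
  lab <- EBImage::bwlabel(EBImage::Image(dark * 1, dim = dim(dark)))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab == 0L) return(list(ok = FALSE, payload = NA_character_, nSymbols = 0L, reason = "no components"))

  # bounding boxes per component
  idx <- which(labm > 0)
  comp <- labm[idx]
  xs <- (idx - 1L) %% nrow(m) + 1L
  ys <- (idx - 1L) %/% nrow(m) + 1L
  x0 <- tapply(xs, comp, min); x1 <- tapply(xs, comp, max)
  y0 <- tapply(ys, comp, min); y1 <- tapply(ys, comp, max)
  bw <- x1 - x0 + 1L; bh <- y1 - y0 + 1L
  ord <- order(bw * bh, decreasing = TRUE)
  ord <- ord[bw[ord] >= 20 & bh[ord] >= 20]
  ord <- utils::head(ord, maxCandidates)

  payloads <- character(0L)
  for (k in ord) {
    p <- .dmTryBox(dark, x0[[k]], x1[[k]], y0[[k]], y1[[k]])
    if (!is.null(p)) payloads <- c(payloads, p)
  }
  payloads <- unique(payloads)
  if (length(payloads) == 0L) {
    list(ok = FALSE, payload = NA_character_, nSymbols = 0L, reason = "no symbol decoded")
  } else if (length(payloads) > 1L) {
    list(ok = FALSE, payload = payloads[1L], nSymbols = length(payloads), reason = "two barcodes")
  } else {
    list(ok = TRUE, payload = payloads, nSymbols = 1L, reason = "")
  }
}

#' Render a DataMatrix module matrix into an image patch
#'
#' @param sym Module matrix from \code{\link{encodeDataMatrix}}.
#' @param modulePx Pixels per module.
#' @param quiet Quiet-zone width in modules.
#' @return Numeric matrix in EBImage [x, y] orientation, dark modules = 0.
#' @export
renderDataMatrix <- function(sym, modulePx = 20L, quiet = 2L) {
  n <- nrow(sym)
  big <- sym[rep(seq_len(n), each = modulePx), rep(seq_len(n), each = modulePx)]
  q <- quiet * modulePx
  out <- matrix(1, nrow(big) + 2L * q, ncol(big) + 2L * q)
  out[q + seq_len(nrow(big)), q + seq_len(ncol(big))] <- 1 - big
  t(out)   # EBImage convention: [x, y]
}
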