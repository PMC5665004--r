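## Synthetic collection generator: a ground-truthed fake drawer tree of
## specimen photographs with rendered labels and DataMatrix barcodes, plus a
## manifest of what was generated. Emulates the statistical structure of a
## pinned-insect collection: a folder per drawer and taxon, a right-hand
## label panel on each photograph, site strings drawn from a variant pool
## with controlled duplication ("Reading" / "Reading, Berks" / "Redding"),
## configurable barcode corruption and missing-barcode rates, and a fraction
## of double-sided labels photographed from both sides.

#' Default site variant pool
#'
#' A small pool of British collecting localities in which several verbatim
#' spellings map to one ground-truth master site, with heavy-tailed sampling
#' weights so a few sites dominate, as in real collections.
#'
#' @return data.frame with columns master, variant, weight.
#' @export
defaultSitePool <- function() {
  pool <- list(
    c("Reading, Berkshire, UK, Europe", "Reading", 8),
    c("Reading, Berkshire, UK, Europe", "Reading, Berks", 5),
    c("Reading, Berkshire, UK, Europe", "Redding", 1),
    c("New Forest, Hampshire, UK, Europe", "New Forest", 7),
    c("New Forest, Hampshire, UK, Europe", "New Forest, Hants", 3),
    c("Dover, Kent, UK, Europe", "Dover", 5),
    c("Dover, Kent, UK, Europe", "Dover Cliffs", 1),
    c("Wicken Fen, Cambridgeshire, UK, Europe", "Wicken Fen", 4),
    c("Wicken Fen, Cambridgeshire, UK, Europe", "Wicken", 2),
    c("Bath, Somerset, UK, Europe", "Bath", 3),
    c("Neath, Glamorgan, UK, Europe", "Neath", 2),
    c("Tring, Hertfordshire, UK, Europe", "Tring", 2),
    c("Tring, Hertfordshire, UK, Europe", "Tring, Herts", 1),
    c("Folkestone, Kent, UK, Europe", "Folkestone", 1)
  )
  data.frame(master = vapply(pool, `[`, "", 1L),
             variant = vapply(pool, `[`, "", 2L),
             weight = as.numeric(vapply(pool, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Build a generator configuration
#'
#' Defaults describe a desk-scale collection: a few drawers of British
#' butterflies, the default site pool, Victorian-to-postwar collecting dates
#' and clean barcodes. Image geometry defaults to 2400x1600, large enough
#' that the 25\% label crop carries a comfortably decodable symbol.
#'
#' @param nDrawers Number of drawers.
#' @param taxa Taxon names; drawers cycle through them.
#' @param specimensPerDrawer Specimens in each drawer.
#' @param sitePool data.frame (master, variant, weight); see
#'   \code{\link{defaultSitePool}}.
#' @param collectorPool Collector name strings.
#' @param dateRange First and last collecting year.
#' @param misreadRate Fraction of specimens whose printed symbol is damaged
#'   beyond decoding.
#' @param missingBarcodeRate Fraction of specimens with no symbol at all.
#' @param doubleSidedFraction Fraction of specimens whose labels are
#'   photographed from both sides, giving a second image file.
#' @param seed Random seed; the same seed gives a byte-identical manifest.
#' @param imageWidth,imageHeight Pixel size of generated photographs.
#' @param barcodePrefix,barcodeStart Barcode payload format.
#' @return A \code{\linkS4class{GenerationConfig}}.
#' @export
collectionConfig <- function(nDrawers = 4L,
                             taxa = c("Hesperia comma", "Polyommatus icarus",
                                      "Aglais urticae", "Pieris brassicae"),
                             specimensPerDrawer = 12L,
                             sitePool = defaultSitePool(),
                             collectorPool = c("N.C. Rothschild", "E.A. Cockayne",
                                               "H.B.D. Kettlewell", "G. Martin",
                                               "F. Toloni"),
                             dateRange = c(1890L, 1960L),
                             misreadRate = 0, missingBarcodeRate = 0,
                             doubleSidedFraction = 0.1,
                             seed = 42L,
                             imageWidth = 2400L, imageHeight = 1600L,
                             barcodePrefix = "NHMUK", barcodeStart = 10000001L) {
  new("GenerationConfig", nDrawers = as.integer(nDrawers), taxa = taxa,
      specimensPerDrawer = as.integer(specimensPerDrawer), sitePool = sitePool,
      collectorPool = collectorPool, dateRange = as.integer(dateRange),
      misreadRate = misreadRate, missingBarcodeRate = missingBarcodeRate,
      doubleSidedFraction = doubleSidedFraction, seed = as.integer(seed),
      imageWidth = as.integer(imageWidth), imageHeight = as.integer(imageHeight),
      barcodePrefix = barcodePrefix, barcodeStart = as.integer(barcodeStart))
}

# verbatim date rendering conventions found on pinned-insect labels
.romanMonths <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii", "ix", "x", "xi", "xii")

.renderVerbatimDate <- function(y, m, d, form) {
  switch(form,
         day_roman = sprintf("%d.%s.%d", d, .romanMonths[m], y),
         day_arabic = sprintf("%d.%d.%d", d, m, y),
         month_roman = sprintf("%s.%d", .romanMonths[m], y),
         year = sprintf("%d", y))
}

.daysInMonth <- function(y, m) {
  as.integer(format(as.Date(sprintf("%d-%02d-01", y + (m == 12L), ifelse(m == 12L, 1L, m + 1L))) - 1, "%d"))
}

# one specimen photograph: neutral grey background, mock specimen silhouette
# on the left 75%, label panel card on the right 25% with text lines and
# (unless suppressed) a DataMatrix symbol
.renderSpecimenImage <- function(cfg, taxon, site, dateVerbatim, collector,
                                 barcode, corrupted, missing, back = FALSE) {
  W <- cfg@imageWidth; H <- cfg@imageHeight
  img <- matrix(0.6, W, H)
  panelX0 <- floor(0.75 * W) + 1L

  if (!back) {
    # butterfly-ish silhouette: body plus four wing ellipses, computed only
    # inside its bounding window
    cx <- 0.375 * W; cy <- 0.5 * H
    r <- 0.15 * min(W, H)
    wx <- max(1L, floor(cx - 2 * r)):min(W, ceiling(cx + 2 * r))
    wy <- max(1L, floor(cy - 2 * r)):min(H, ceiling(cy + 2 * r))
    xg <- matrix(wx, length(wx), length(wy))
    yg <- matrix(wy, length(wx), length(wy), byrow = TRUE)
    sil <- ((xg - cx) / (0.12 * r))^2 + ((yg - cy) / r)^2 <= 1
    for (sx in c(-1, 1)) {
      sil <- sil | (((xg - cx + sx * 0.9 * r) / (0.9 * r))^2 +
                      ((yg - cy + 0.7 * r) / (0.8 * r))^2 <= 1) |
        (((xg - cx + sx * 0.8 * r) / (0.8 * r))^2 +
           ((yg - cy - 0.8 * r) / (0.7 * r))^2 <= 1)
    }
    sub <- img[wx, wy]
    sub[sil] <- 0.22
    img[wx, wy] <- sub
    # scale bar
    img[round(0.05 * W):round(0.15 * W), round(0.93 * H):round(0.945 * H)] <- 0.1
  }

  # label card
  m <- 24L
  img[(panelX0 + m):(W - m), (1L + m):(H - m)] <- 0.93

  scale <- max(2L, round(W / 600))
  lines <- if (back) {
    c("EX COLL.", collector, "B.M. 1947-162", "VERSO")
  } else {
    c(taxon, site, dateVerbatim, collector, barcode)
  }
  img <- .drawText(img, panelX0 + m + 16L, m + 40L, lines, scale = scale)

  if (!back && !missing) {
    modulePx <- max(10L, round(W / 120))
    patch <- renderDataMatrix(encodeDataMatrix(barcode), modulePx = modulePx, quiet = 2L)
    pw <- nrow(patch); ph <- ncol(patch)
    px <- panelX0 + ((W - panelX0) - pw) %/% 2L
    py <- H - m - ph - round(0.08 * H)
    img[px + seq_len(pw) - 1L, py + seq_len(ph) - 1L] <- patch
    if (corrupted) {
      # blot out a random 30%-area rectangle of the symbol with background
      rw <- round(sqrt(0.3) * pw); rh <- round(sqrt(0.3) * ph)
      rx <- px + sample.int(pw - rw, 1L) - 1L
      ry <- py + sample.int(ph - rh, 1L) - 1L
      img[rx + seq_len(rw) - 1L, ry + seq_len(rh) - 1L] <- 0.6
    }
  }
  img
}

#' Generate a synthetic specimen collection
#'
#' Writes a folder tree \code{Drawer##/Taxon name/IMG_####.jpg} of rendered
#' specimen photographs plus \code{manifest.csv} recording the ground truth
#' for every specimen: barcode, drawer, taxon, site master and the verbatim
#' variant printed on the label, collector, collecting date (verbatim and as
#' a calendar range), and the corruption/double-sided flags. Every variant
#' in the site pool is used at least once when the specimen count allows, so
#' the number of distinct verbatim site strings in a generated collection
#' equals the pool size.
#'
#' @param config A \code{\linkS4class{GenerationConfig}}.
#' @param outDir Output directory (created; must be writable).
#' @return Invisibly, a list with \code{dir} and the manifest data.frame.
#' @export
generateCollection <- function(config, outDir) {
  validObject(config)
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)

  n <- config@nDrawers * config@specimensPerDrawer
  manifest <- .withSeed(config@seed, {
    pool <- config@sitePool
    # every variant used once (when n allows), remainder weighted
    sitesIdx <- integer(n)
    nv <- nrow(pool)
    base <- seq_len(min(nv, n))
    sitesIdx[base] <- base
    if (n > nv)
      sitesIdx[(nv + 1L):n] <- sample.int(nv, n - nv, replace = TRUE, prob = pool$weight)
    sitesIdx <- sample(sitesIdx)   # shuffle across drawers

    years <- sample(seq(config@dateRange[1L], config@dateRange[2L]), n, replace = TRUE)
    months <- sample.int(12L, n, replace = TRUE)
    days <- vapply(seq_len(n), function(i) sample.int(.daysInMonth(years[i], months[i]), 1L), 1L)
    forms <- sample(c("day_roman", "day_arabic", "month_roman", "year"), n,
                    replace = TRUE, prob = c(0.55, 0.2, 0.15, 0.1))
    collectors <- sample(config@collectorPool, n, replace = TRUE)
    u <- stats::runif(n)
    missing <- u < config@missingBarcodeRate
    corrupted <- !missing & stats::runif(n) < config@misreadRate
    doubleSided <- stats::runif(n) < config@doubleSidedFraction

    drawerIdx <- rep(seq_len(config@nDrawers), each = config@specimensPerDrawer)
    drawers <- sprintf("Drawer%02d", drawerIdx)
    taxa <- config@taxa[(drawerIdx - 1L) %% length(config@taxa) + 1L]
    codes <- sprintf(paste0("%s%09d"), config@barcodePrefix,
                     config@barcodeStart + seq_len(n) - 1L)

    dateStart <- dateEnd <- character(n)
    dateVerb <- character(n)
    for (i in seq_len(n)) {
      dateVerb[i] <- .renderVerbatimDate(years[i], months[i], days[i], forms[i])
      rng <- switch(forms[i],
        day_roman = , day_arabic = rep(sprintf("%04d-%02d-%02d", years[i], months[i], days[i]), 2L),
        month_roman = c(sprintf("%04d-%02d-01", years[i], months[i]),
                        sprintf("%04d-%02d-%02d", years[i], months[i], .daysInMonth(years[i], months[i]))),
        year = c(sprintf("%04d-01-01", years[i]), sprintf("%04d-12-31", years[i])))
      dateStart[i] <- rng[1L]; dateEnd[i] <- rng[2L]
    }

    man <- data.frame(
      file = character(n), file_back = NA_character_, drawer = drawers,
      taxon = taxa, barcode = codes,
      site_master = pool$master[sitesIdx], site_variant = pool$variant[sitesIdx],
      collector = collectors, date_verbatim = dateVerb,
      date_start = dateStart, date_end = dateEnd,
      corrupted_barcode = corrupted, missing_barcode = missing,
      double_sided = doubleSided, stringsAsFactors = FALSE)

    for (i in seq_len(n)) {
      dir <- file.path(outDir, man$drawer[i], man$taxon[i])
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      stem <- sprintf("IMG_%04d", i)
      img <- .renderSpecimenImage(config, man$taxon[i], man$site_variant[i],
                                  man$date_verbatim[i], man$collector[i],
                                  man$barcode[i], corrupted[i], missing[i])
      f <- file.path(dir, paste0(stem, ".jpg"))
      EBImage::writeImage(EBImage::Image(img), f, quality = 92L)
      man$file[i] <- f
      if (doubleSided[i]) {
        back <- .renderSpecimenImage(config, man$taxon[i], man$site_variant[i],
                                     man$date_verbatim[i], man$collector[i],
                                     man$barcode[i], FALSE, TRUE, back = TRUE)
        fb <- file.path(dir, paste0(stem, "_b.jpg"))
        EBImage::writeImage(EBImage::Image(back), fb, quality = 92L)
        man$file_back[i] <- fb
      }
    }
    man
  })
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(list(dir = outDir, manifest = manifest))
}

#' Build a site pool with a prescribed deduplication profile
#'
#' Returns a site pool whose generated collection yields exactly
#' \code{nVariants} distinct verbatim strings mapping to exactly
#' \code{nMasters} ground-truth master sites, so downstream normalisation
#' reports reproduce a chosen variant-to-master reduction. Variant counts
#' are spread as evenly as possible over masters and weights follow a
#' Zipf-like decay so specimen counts per site are realistically skewed.
#'
#' @param nVariants Total verbatim strings; \code{nMasters <= nVariants <=
#'   nSpecimens} must hold.
#' @param nMasters Ground-truth master sites.
#' @param nSpecimens Specimens the pool is intended to label.
#' @param seed Seed for the weight draw.
#' @return data.frame with columns master, variant, weight.
#' @export
emulateDedupProfile <- function(nVariants, nMasters, nSpecimens, seed = 1L) {
  if (!(nMasters <= nVariants && nVariants <= nSpecimens))
    stop("need nMasters <= nVariants <= nSpecimens")
  perMaster <- rep(nVariants %/% nMasters, nMasters)
  extra <- nVariants %% nMasters
  if (extra > 0L) perMaster[seq_len(extra)] <- perMaster[seq_len(extra)] + 1L
  counties <- c("Berks", "Hants", "Kent", "Surrey", "Sussex", "Devon", "Dorset",
                "Essex", "Norfolk", "Suffolk")
  .withSeed(seed, {
    rows <- vector("list", nMasters)
    for (i in seq_len(nMasters)) {
      master <- sprintf("Site %03d, %s, UK, Europe", i, counties[(i - 1L) %% length(counties) + 1L])
      k <- perMaster[i]
      variants <- sprintf("Site %03d", i)
      if (k > 1L)
        variants <- c(variants, sprintf("Site %03d, %s", i,
                                        c(counties[(i - 1L) %% length(counties) + 1L],
                                          "UK", "England", "Britain",
                                          paste0("var", seq_len(max(0L, k - 5L))))[seq_len(k - 1L)]))
      w <- (1 / i) * stats::runif(k, 0.5, 1.5)   # Zipf-ish across masters
      rows[[i]] <- data.frame(master = master, variant = variants, weight = w,
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
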