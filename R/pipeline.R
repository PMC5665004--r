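## Batch image processing: traverse the drawer/taxon folder tree, crop and
## resize the label panel, decode the DataMatrix barcode, rename files to the
## barcode, and auto-create specimen and image records. Re-running over the
## same tree is a no-op: processed files are tracked by content hash, which
## survives the renaming.

.LABEL_W <- 800L
.LABEL_H <- 1219L

#' Extract drawer and taxon from an image path
#'
#' The folder convention is \code{<root>/Drawer##/Taxonomic name/<file>.jpg}:
#' the first directory component under the root is the drawer, the second
#' the taxon determination. Deeper levels are ignored with a warning; paths
#' with fewer than two directory levels are failures.
#'
#' @param path Image file path.
#' @param root Tree root the path lies under.
#' @return list(ok, drawer, taxon, reason).
#' @export
parseFolderPath <- function(path, root) {
  np <- normalizePath(path, mustWork = FALSE)
  nr <- normalizePath(root, mustWork = FALSE)
  rel <- if (startsWith(np, nr)) substring(np, nchar(nr) + 1L) else path
  rel <- sub("^/+", "", rel)
  parts <- strsplit(rel, "/", fixed = TRUE)[[1L]]
  if (length(parts) < 3L)
    return(list(ok = FALSE, drawer = NA_character_, taxon = NA_character_,
                reason = "path has fewer than two directory levels under root"))
  if (length(parts) > 3L)
    warning("ignoring directory levels below taxon: ", rel)
  list(ok = TRUE, drawer = parts[1L], taxon = parts[2L], reason = "")
}

#' Crop and resize the label panel of a specimen photograph
#'
#' Takes the rightmost 25\% of the image width at full height and resamples
#' it (bilinear) to exactly 800 x 1219 pixels, the standard label-crop
#' geometry. The aspect ratio is not preserved; no padding is applied.
#'
#' @param img An \code{EBImage::Image}.
#' @return An 800 x 1219 \code{EBImage::Image}.
#' @export
cropLabelRegion <- function(img) {
  w <- dim(img)[1L]
  if (w < 4L) stop("image too narrow to crop")
  x0 <- floor(0.75 * w) + 1L
  crop <- img[x0:w, , drop = FALSE]
  EBImage::resize(crop, w = .LABEL_W, h = .LABEL_H)
}

# second decode attempt: sharpen, then half-scale, as barcode readers do on
# noisy captures
.decodeWithRetry <- function(labelImg) {
  r <- decodeDataMatrix(labelImg)
  if (r$ok || r$nSymbols > 1L) return(r)
  sharp <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3L, 3L)
  retry <- tryCatch({
    s <- EBImage::filter2(labelImg, sharp)
    s <- EBImage::resize(s, w = round(dim(s)[1L] / 2))
    decodeDataMatrix(s)
  }, error = function(e) NULL)
  if (!is.null(retry) && retry$ok) retry else r
}

.fileHash <- function(path) unname(tools::md5sum(path))

.isProcessed <- function(store, hash) hash %in% store@tables$processed$hash

.markProcessed <- function(store, hash, path) {
  t <- store@tables
  t$processed <- rbind(t$processed, data.frame(hash = hash, path = path,
                                               stringsAsFactors = FALSE))
}

.addImageRecord <- function(store, path, role, dims, specimenId) {
  t <- store@tables
  id <- .nextId(store, "images")
  t$images <- rbind(t$images, data.frame(
    id = id, path = path, role = role, width = as.integer(dims[1L]),
    height = as.integer(dims[2L]), specimen_id = specimenId,
    cms_irn = NA_integer_, stringsAsFactors = FALSE))
  id
}

.addSpecimenRecord <- function(store, barcode, drawer, taxon) {
  t <- store@tables
  tv <- .getOrCreate(store, "taxon_variants", taxon)
  id <- .nextId(store, "specimens")
  row <- .storeSchemas()$specimens[0, ]
  row[1L, "id"] <- id
  row$barcode <- barcode
  row$drawer <- drawer
  row$taxon_variant_id <- tv$id
  row$status <- "imaged"
  row$flags <- ""
  row$pre_databased <- FALSE
  t$specimens <- rbind(t$specimens, row)
  id
}

#' Process a folder tree of specimen photographs
#'
#' For each unprocessed image: parses drawer and taxon from the path, writes
#' the 800x1219 label crop, decodes the barcode (retrying on a sharpened
#' half-scale copy), renames the specimen image to \code{<barcode>.jpg} and
#' the crop to \code{<barcode>_label.jpg}, and creates the specimen and
#' image records. On decode failure the original file name is retained and
#' the record is flagged \code{barcode_unread}. A second label photograph
#' named \code{<stem>_b.jpg} in the source tree is attached as the back-side
#' label image (\code{<barcode>_label_back.jpg}). A barcode decoded twice in
#' one tree is a collision: both specimens are flagged for scrutiny and no
#' file is overwritten. Re-running over the same tree creates nothing new.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param root Folder tree root.
#' @param dryRun If TRUE, only counts what would be done; the store and disk
#'   are untouched.
#' @return A \code{\linkS4class{BatchReport}}.
#' @export
processBatch <- function(store, root, dryRun = FALSE) {
  if (!dir.exists(root)) stop("no such folder: ", root)
  .requireWritable(store)
  files <- sort(list.files(root, pattern = "\\.jpe?g$", ignore.case = TRUE,
                           recursive = TRUE, full.names = TRUE))
  stems <- sub("\\.jpe?g$", "", basename(files), ignore.case = TRUE)
  isCrop <- grepl("_label(_back)?$", stems)
  isBack <- grepl("_b$", stems)
  primaries <- files[!isCrop & !isBack]

  seen <- 0L; created <- 0L; crops <- 0L; bfail <- 0L; skipped <- 0L
  failures <- data.frame(path = character(), reason = character(), stringsAsFactors = FALSE)
  fail <- function(path, reason) {
    failures <<- rbind(failures, data.frame(path = path, reason = reason,
                                            stringsAsFactors = FALSE))
  }

  for (f in primaries) {
    seen <- seen + 1L
    hash <- .fileHash(f)
    if (.isProcessed(store, hash)) { skipped <- skipped + 1L; next }
    if (dryRun) { created <- created + 1L; next }

    meta <- withCallingHandlers(parseFolderPath(f, root),
                                warning = function(w) invokeRestart("muffleWarning"))
    if (!meta$ok) {
      fail(f, meta$reason)
      .markProcessed(store, hash, f)
      next
    }
    img <- tryCatch(EBImage::readImage(f), error = function(e) NULL)
    if (is.null(img)) {
      fail(f, "unreadable image")
      .markProcessed(store, hash, f)
      next
    }
    label <- cropLabelRegion(img)
    dec <- .decodeWithRetry(label)

    dir <- dirname(f)
    stem <- sub("\\.jpe?g$", "", basename(f), ignore.case = TRUE)
    backSrc <- file.path(dir, paste0(stem, "_b.jpg"))
    hasBack <- file.exists(backSrc)

    collision <- FALSE
    if (dec$ok) {
      code <- dec$payload
      if (identical(.barcodeState(store, code), "attached")) {
        collision <- TRUE
        other <- store@tables$specimens$id[which(store@tables$specimens$barcode == code)]
        for (oid in other) .addFlag(store, oid, "for_scrutiny")
        fail(f, paste("barcode collision:", code))
      } else {
        .attachBarcode(store, code)
      }
    }

    if (dec$ok && !collision) {
      fullPath <- file.path(dir, paste0(code, ".jpg"))
      file.rename(f, fullPath)
      labelPath <- file.path(dir, paste0(code, "_label.jpg"))
      backPath <- file.path(dir, paste0(code, "_label_back.jpg"))
      barcode <- code
    } else {
      fullPath <- f
      labelPath <- file.path(dir, paste0(stem, "_label.jpg"))
      backPath <- file.path(dir, paste0(stem, "_label_back.jpg"))
      barcode <- NA_character_
      bfail <- bfail + 1L
    }

    EBImage::writeImage(label, labelPath, quality = 92L)
    crops <- crops + 1L
    if (hasBack) file.rename(backSrc, backPath)

    sid <- .addSpecimenRecord(store, barcode, meta$drawer, meta$taxon)
    if (!dec$ok) {
      .addFlag(store, sid, "barcode_unread")
      if (dec$nSymbols > 1L) .addFlag(store, sid, "two_barcodes")
      fail(f, dec$reason)
    }
    if (collision) .addFlag(store, sid, "for_scrutiny")
    .addImageRecord(store, fullPath, "full", dim(img)[1:2], sid)
    .addImageRecord(store, labelPath, "label", c(.LABEL_W, .LABEL_H), sid)
    if (hasBack) .addImageRecord(store, backPath, "label_back", dim(img)[1:2], sid)

    .markProcessed(store, .fileHash(fullPath), fullPath)
    .markProcessed(store, .fileHash(labelPath), labelPath)
    if (hasBack) .markProcessed(store, .fileHash(backPath), backPath)
    created <- created + 1L
  }
  if (!dryRun) .audit(store, "system", "process_batch",
                      sprintf("root=%s created=%d failures=%d skipped=%d",
                              root, created, nrow(failures), skipped))
  new("BatchReport", nImagesSeen = seen, nSpecimensCreated = created,
      nLabelCrops = crops, nBarcodeFailures = bfail,
      nSkippedExisting = skipped, failures = failures)
}

#' Correct a misread barcode
#'
#' Replaces a specimen's barcode (typically after a transcriber spots a
#' misread), renames all linked image files so the filename/barcode
#' correspondence is restored, and discards the old code so it can never be
#' re-issued. Correcting to the specimen's current code is a no-op;
#' correcting to a code attached to another specimen is refused.
#'
#' @param store A \code{\linkS4class{DigiStore}}.
#' @param user Caller; requires the transcriber or data_manager role.
#' @param specimenId Specimen id.
#' @param correctedCode The true barcode payload.
#' @return The updated specimen row, invisibly.
#' @export
renameForBarcode <- function(store, user, specimenId, correctedCode) {
  .requireWritable(store)
  if (!any(c("transcriber", "data_manager") %in% userRoles(store, user)))
    stop(sprintf("user '%s' lacks required role 'transcriber'", user))
  t <- store@tables
  i <- match(specimenId, t$specimens$id)
  if (is.na(i)) stop("unknown specimen: ", specimenId)
  old <- t$specimens$barcode[i]
  if (identical(old, correctedCode)) return(invisible(t$specimens[i, ]))
  st <- .barcodeState(store, correctedCode)
  if (identical(st, "attached")) stop("barcode already attached to another specimen: ", correctedCode)
  if (identical(st, "discarded")) stop("barcode was discarded: ", correctedCode)
  .attachBarcode(store, correctedCode)

  imgIdx <- which(t$images$specimen_id == specimenId)
  for (k in imgIdx) {
    oldPath <- t$images$path[k]
    suffix <- switch(t$images$role[k], full = "", label = "_label", label_back = "_label_back")
    newPath <- file.path(dirname(oldPath), paste0(correctedCode, suffix, ".jpg"))
    if (file.exists(oldPath) && oldPath != newPath) file.rename(oldPath, newPath)
    t$images$path[k] <- newPath
  }
  t$specimens$barcode[i] <- correctedCode
  if (!is.na(old)) {
    j <- match(old, t$barcodes$code)
    if (!is.na(j)) t$barcodes$state[j] <- "discarded"
  }
  t$specimens$flags[i] <- .joinMulti(setdiff(.splitMulti(t$specimens$flags[i]),
                                             c("barcode_unread"))) %||% ""
  if (is.na(t$specimens$flags[i])) t$specimens$flags[i] <- ""
  .audit(store, user, "rename_for_barcode",
         sprintf("specimen %d: %s -> %s", specimenId, old %||% "NA", correctedCode))
  invisible(t$specimens[i, ])
}
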