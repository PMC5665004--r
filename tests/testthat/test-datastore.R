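test_that("allocated barcodes are unique, increasing, and never revive discards", {
  store <- makeStore()
  a <- allocateBarcodes(store, "dm", 3)
  b <- allocateBarcodes(store, "dm", 3)
  expect_length(unique(c(a, b)), 6L)
  nums <- as.integer(sub("^NHMUK", "", c(a, b)))
  expect_true(all(diff(nums) > 0))

  # allocate 10, discard 4, allocate 10: 20 issued, 16 attachable, 0 reused
  store2 <- makeStore()
  first <- allocateBarcodes(store2, "dm", 10)
  expect_identical(discardBarcodes(store2, "dm", first[3:6]), 4L)
  second <- allocateBarcodes(store2, "dm", 10)
  expect_length(intersect(second, first), 0L)
  issued <- store2@tables$barcodes
  expect_identical(nrow(issued), 20L)
  expect_identical(sum(issued$state == "allocated"), 16L)
  expect_identical(discardBarcodes(store2, "dm", character(0)), 0L)
})

test_that("barcode uniqueness holds over random allocate/discard interleavings", {
  set.seed(202)
  store <- makeStore()
  issued <- character(0)
  live <- character(0)
  for (step in 1:40) {
    if (runif(1) < 0.6 || length(live) == 0L) {
      got <- allocateBarcodes(store, "dm", sample(1:5, 1))
      expect_length(intersect(got, issued), 0L)
      issued <- c(issued, got)
      live <- c(live, got)
    } else {
      drop <- sample(live, min(length(live), sample(1:3, 1)))
      discardBarcodes(store, "dm", drop)
      live <- setdiff(live, drop)
    }
  }
  expect_false(anyDuplicated(issued) > 0)
})

test_that("attached barcodes cannot be discarded", {
  store <- makeStore()
  codes <- allocateBarcodes(store, "dm", 2)
  colldigi:::.attachBarcode(store, codes[1])
  expect_error(discardBarcodes(store, "dm", codes), "conflict")
  expect_identical(colldigi:::.barcodeState(store, codes[2]), "allocated")
})

test_that("status transitions are monotone with skipped stages audited", {
  statuses <- c("imaged", "transcribed", "normalized", "georeferenced", "exported")
  for (from in seq_along(statuses)) {
    for (to in seq_along(statuses)) {
      store <- makeStore()
      sid <- colldigi:::.addSpecimenRecord(store, "X1", "Drawer01", "Aus bus")
      store@tables$specimens$status[1] <- statuses[from]
      if (to < from) {
        expect_error(setSpecimenStatus(store, sid, statuses[to]), "backward")
      } else {
        setSpecimenStatus(store, sid, statuses[to])
        expect_identical(store@tables$specimens$status[1], statuses[to])
        if (to > from + 1L) {
          last <- tail(store@tables$audit, 1L)
          expect_match(last$detail, "skipped:")
        }
      }
    }
  }
})

test_that("role-restricted operations refuse users lacking the role", {
  store <- makeStore()
  sid <- colldigi:::.addSpecimenRecord(store, "X1", "Drawer01", "Aus bus")
  colldigi:::.getOrCreate(store, "site_variants", "Reading")
  colldigi:::.getOrCreate(store, "site_masters", "Reading, Berkshire, UK, Europe")

  ops <- list(
    data_manager = function(u) allocateBarcodes(store, u, 1),
    transcriber = function(u) transcribe(store, u, sid, transcriptionInput(siteVerbatim = "Reading")),
    georeferencer = function(u) assignVariant(store, u, "site", "Reading", "Reading, Berkshire, UK, Europe"),
    scrutineer = function(u) unmarkUngeoreferenceable(store, u, "Reading, Berkshire, UK, Europe")
  )
  holders <- c(data_manager = "dm", transcriber = "tr",
               georeferencer = "geo", scrutineer = "scr")
  for (role in names(ops)) {
    for (other in setdiff(unname(holders), holders[[role]])) {
      expect_error(ops[[role]](other), "lacks required role")
    }
  }
})

test_that("referenced rows cannot be deleted; unreferenced rows can", {
  store <- makeStore()
  sid <- colldigi:::.addSpecimenRecord(store, "X1", "Drawer01", "Aus bus")
  colldigi:::.addImageRecord(store, "/tmp/x.jpg", "full", c(10L, 10L), sid)
  expect_error(deleteRow(store, "specimens", sid), "referenced by")
  expect_error(deleteRow(store, "taxon_variants",
                         store@tables$taxon_variants$id[1]), "referenced by")
  imgId <- store@tables$images$id[1]
  expect_true(deleteRow(store, "images", imgId))
  expect_identical(nrow(store@tables$images), 0L)
})

test_that("a store survives a save/load round trip", {
  store <- makeStore()
  allocateBarcodes(store, "dm", 3)
  sid <- colldigi:::.addSpecimenRecord(store, "NHMUK010000001", "Drawer01", "Aus bus")
  transcribeOk <- allocateRecords(store, "dm", "tr", sid)
  transcribe(store, "tr", sid,
             transcriptionInput(siteVerbatim = "Reading", dateVerbatim = "14.vi.1921"))
  dir <- withr::local_tempdir()
  saveStore(store, dir)
  back <- loadStore(dir)
  for (nm in names(colldigi:::.storeSchemas())) {
    expect_identical(back@tables[[nm]], store@tables[[nm]], label = nm)
  }
  # counters continue, not restart
  more <- allocateBarcodes(back, "dm", 1)
  expect_false(more %in% store@tables$barcodes$code[1:3])
})
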