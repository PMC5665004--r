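# shared fixtures, built in code at test time

# a store with one user per role
makeStore <- function() {
  store <- createStore("test")
  addUser(store, "dm", "data_manager")
  addUser(store, "tr", "transcriber")
  addUser(store, "geo", "georeferencer")
  addUser(store, "scr", "scrutineer")
  store
}

# small-image generator config: unit tests use reduced geometry for speed;
# the package defaults are exercised in the acceptance suite
smallConfig <- function(...) {
  collectionConfig(imageWidth = 1200L, imageHeight = 800L, ...)
}

# lazily generated small collection shared across test files
.fixtureCache <- new.env()

sharedCollection <- function() {
  if (is.null(.fixtureCache$gen)) {
    dir <- file.path(tempdir(), "colldigi-shared-collection")
    cfg <- smallConfig(nDrawers = 2L, specimensPerDrawer = 5L, seed = 11L,
                       doubleSidedFraction = 0.2)
    .fixtureCache$gen <- generateCollection(cfg, dir)
    .fixtureCache$cfg <- cfg
  }
  .fixtureCache$gen
}

# a processed store over a private copy of the shared collection tree
processedStore <- function() {
  gen <- sharedCollection()
  dir <- file.path(tempdir(), paste0("tree-", paste(sample(letters, 8), collapse = "")))
  dir.create(dir)
  file.copy(list.files(gen$dir, full.names = TRUE), dir, recursive = TRUE)
  unlink(file.path(dir, "manifest.csv"))
  store <- makeStore()
  report <- processBatch(store, dir)
  list(store = store, report = report, manifest = gen$manifest, dir = dir)
}

# run the full transcription from a manifest (allocate + batch CSV)
transcribeFromManifest <- function(store, manifest) {
  allocateRecords(store, "dm", "tr", store@tables$specimens$id)
  rows <- data.frame(barcode = manifest$barcode,
                     site_verbatim = manifest$site_variant,
                     date_verbatim = manifest$date_verbatim,
                     collectors = manifest$collector,
                     stringsAsFactors = FALSE)
  transcribeBatch(store, "tr", rows)
}

# assign all variants to their ground-truth masters
normalizeFromManifest <- function(store, manifest) {
  for (v in unique(manifest$site_variant)) {
    assignVariant(store, "geo", "site",
                  v, manifest$site_master[match(v, manifest$site_variant)])
  }
  for (tx in unique(manifest$taxon)) assignVariant(store, "scr", "taxon", tx, tx)
}

# deep copy of a store (tables environment is reference-semantic)
cloneStore <- function(store) {
  copy <- createStore(store@config$project, store@config$barcodePrefix,
                      store@config$barcodeDigits)
  for (nm in ls(store@tables, all.names = TRUE)) {
    copy@tables[[nm]] <- store@tables[[nm]]
  }
  copy
}

# full CMS round trip in the canonical order; returns the mock CMS
roundTripExport <- function(store, cms = createMockCms()) {
  for (tp in c("multimedia", "parties", "taxonomy", "sites", "locations",
               "collection_events", "catalogue")) {
    rep <- exportNewEntities(store, tp)
    if (tp == "locations") cmsSeed(cms, "locations", rep$name)
    importIrns(store, tp, cmsIngest(cms, tp, rep))
  }
  cms
}
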