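# a small fully transcribed, normalised, georeferenced store ready to export
exportReadyStore <- function() {
  store <- makeStore()
  man <- data.frame(
    barcode = sprintf("NHMUK0100000%02d", 1:6),
    drawer = rep(c("Drawer01", "Drawer02"), each = 3L),
    taxon = rep(c("Aus bus", "Cus dus"), 3L),
    site_variant = c("Reading", "Reading, Berks", "Dover", "Dover", "Bath", "Bath"),
    site_master = c("Reading, Berkshire, UK, Europe", "Reading, Berkshire, UK, Europe",
                    "Dover, Kent, UK, Europe", "Dover, Kent, UK, Europe",
                    "Bath, Somerset, UK, Europe", "Bath, Somerset, UK, Europe"),
    date_verbatim = c("14.vi.1921", "vi.1921", "1895", "3.ix.1991", "1.i.1995", "2.ii.1960"),
    collector = c("A. Smith", "A. Smith", "B. Jones", "B. Jones", "A. Smith", "C. Brown"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(man))) {
    sid <- colldigi:::.addSpecimenRecord(store, man$barcode[i], man$drawer[i], man$taxon[i])
    colldigi:::.addImageRecord(store, sprintf("/img/%s.jpg", man$barcode[i]), "full",
                               c(100L, 100L), sid)
  }
  allocateRecords(store, "dm", "tr", store@tables$specimens$id)
  transcribeBatch(store, "tr", data.frame(
    barcode = man$barcode, site_verbatim = man$site_variant,
    date_verbatim = man$date_verbatim, collectors = man$collector,
    stringsAsFactors = FALSE))
  normalizeFromManifest(store, man)
  for (m in unique(man$site_master))
    setGeoreference(store, "geo", m, 51 + nchar(m) / 100, -1, 3000)
  list(store = store, manifest = man)
}

test_that("export is refused until every referenced type has its IRNs", {
  st <- exportReadyStore()$store
  err <- tryCatch(exportNewEntities(st, "catalogue"), error = function(e) conditionMessage(e))
  expect_match(err, "sites")
  expect_match(err, "taxonomy")
  err2 <- tryCatch(exportNewEntities(st, "collection_events"),
                   error = function(e) conditionMessage(e))
  expect_match(err2, "parties")
})

test_that("random export orders succeed exactly when topologically consistent", {
  types <- c("multimedia", "parties", "taxonomy", "sites", "locations",
             "collection_events", "catalogue")
  base <- exportReadyStore()$store
  set.seed(404)
  orders <- c(list(types), lapply(1:12, function(i) sample(types)))
  for (ord in orders) {
    store <- cloneStore(base)
    cms <- createMockCms()
    cmsSeed(cms, "locations", unique(store@tables$specimens$drawer))
    succeeded <- tryCatch({
      for (tp in ord) {
        rep <- exportNewEntities(store, tp)
        importIrns(store, tp, cmsIngest(cms, tp, rep))
      }
      TRUE
    }, error = function(e) FALSE)
    expect_identical(succeeded, exportOrderOk(ord),
                     label = paste(ord, collapse = ">"))
  }
})

test_that("IRN import accounts for unknown ids, duplicates, and is idempotent", {
  st <- exportReadyStore()$store
  rep <- exportNewEntities(st, "parties")
  expect_identical(nrow(rep), 3L)   # distinct collectors
  irns <- data.frame(local_id = c(rep$local_id, 999L), irn = c(11L, 12L, 13L, 14L))
  expect_identical(importIrns(st, "parties", irns), 3L)
  expect_identical(importIrns(st, "parties", irns), 0L)   # idempotent
  # duplicate irn refused
  st2 <- exportReadyStore()$store
  rep2 <- exportNewEntities(st2, "parties")
  dup <- data.frame(local_id = rep2$local_id, irn = c(5L, 5L, 6L))
  expect_identical(importIrns(st2, "parties", dup), 2L)
  a <- st2@tables$audit
  expect_true(any(grepl("duplicate irn", a$detail)))
})

test_that("match-or-create reuses pre-matched taxa; match-existing never creates locations", {
  st <- exportReadyStore()$store
  cms <- createMockCms()
  preIrns <- cmsSeed(cms, "taxonomy", "Aus bus")
  rep <- exportNewEntities(st, "taxonomy")
  out <- cmsIngest(cms, "taxonomy", rep)
  expect_identical(out$irn[rep$name == "Aus bus"], preIrns)
  expect_identical(nrow(cms@tables$taxonomy), 2L)   # one matched, one created

  locRep <- exportNewEntities(st, "locations")
  locOut <- cmsIngest(cms, "locations", locRep)     # nothing seeded: no matches
  expect_true(all(is.na(locOut$irn)))
  expect_identical(nrow(cms@tables$locations), 0L)
})

test_that("pre-existing CMS specimen records are deleted before replacement", {
  st <- exportReadyStore()$store
  cms <- createMockCms()
  regs <- sprintf("1896.%d", 1:5)
  cmsSeed(cms, "catalogue", regs)
  expect_identical(replaceExistingSpecimens(cms, st, "dm", regs[1:3]), 3L)
  expect_identical(nrow(cms@tables$catalogue), 2L)
  expect_warning(replaceExistingSpecimens(cms, st, "dm", "no-such"), "no pre-existing")
  expect_error(replaceExistingSpecimens(cms, st, "tr", regs), "lacks required role")
})

test_that("publication applies embargo rules soundly and keeps verbatim strings", {
  es <- exportReadyStore()
  store <- es$store
  roundTripExport(store)
  all6 <- publishOccurrences(store)
  expect_identical(nrow(all6), 6L)
  expect_setequal(all6$verbatimLocality, es$manifest$site_variant)
  expect_setequal(all6$occurrenceID, es$manifest$barcode)
  expect_true(all(!is.na(all6$decimalLatitude)))

  # two specimens collected >= 1990 are withheld
  pub <- publishOccurrences(store, list(embargoYearFrom(1990)))
  expect_identical(nrow(pub), 4L)
  withheldIds <- setdiff(all6$occurrenceID, pub$occurrenceID)
  expect_setequal(withheldIds, es$manifest$barcode[c(4, 5)])
  # withheld records remain in the store
  expect_true(all(withheldIds %in% store@tables$specimens$barcode))
  # published + withheld = exported, disjoint by construction
  expect_length(intersect(pub$occurrenceID, withheldIds), 0L)
  expect_setequal(c(pub$occurrenceID, withheldIds), all6$occurrenceID)

  # taxon embargo
  pubT <- publishOccurrences(store, list(embargoTaxa("Cus dus")))
  expect_identical(nrow(pubT), sum(es$manifest$taxon == "Aus bus"))
})

test_that("archiving requires full export, bundles the store, and freezes it", {
  es <- exportReadyStore()
  store <- es$store
  expect_error(archiveProject(store, withr::local_tempdir()), "6 specimen")
  roundTripExport(store)
  dir <- withr::local_tempdir()
  archiveProject(store, dir, copyImages = FALSE)
  expect_error(allocateBarcodes(store, "dm", 1), "read-only")
  # bundle re-opens losslessly
  back <- loadStore(file.path(dir, "store"))
  for (nm in names(colldigi:::.storeSchemas()))
    expect_identical(back@tables[[nm]], store@tables[[nm]], label = nm)
  expect_error(allocateBarcodes(back, "dm", 1), "read-only")
})
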