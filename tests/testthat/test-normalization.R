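test_that("variants resolve to masters and reassignment replaces the link", {
  store <- makeStore()
  for (i in 1:2) colldigi:::.addSpecimenRecord(store, sprintf("X%d", i), "Drawer01",
                                               c("Aus bus", "A. bus")[i])
  assignVariant(store, "scr", "taxon", "Aus bus", "Aus bus (Linnaeus 1758)")
  assignVariant(store, "scr", "taxon", "A. bus", "Aus bus (Linnaeus 1758)")
  t <- store@tables
  expect_identical(nrow(t$taxon_masters), 1L)
  expect_identical(unique(t$taxon_variants$master_id), t$taxon_masters$id)

  # site example with a reassignment
  ids <- vapply(1:3, function(i)
    colldigi:::.addSpecimenRecord(store, sprintf("Y%d", i), "Drawer01", "Aus bus"), 1L)
  allocateRecords(store, "dm", "tr", ids)
  for (k in seq_along(ids))
    transcribe(store, "tr", ids[k], transcriptionInput(
      siteVerbatim = c("Reading", "Reading, Berks", "Redding, Berks")[k]))
  for (v in c("Reading", "Reading, Berks", "Redding, Berks"))
    assignVariant(store, "geo", "site", v, "Reading, Berkshire, UK, Europe")
  expect_identical(nrow(store@tables$site_masters), 1L)

  assignVariant(store, "geo", "site", "Redding, Berks", "Redding, California, USA, N. America")
  sv <- store@tables$site_variants
  expect_identical(sum(sv$name == "Redding, Berks"), 1L)   # replaced, not duplicated
  expect_identical(sv$master_id[sv$name == "Redding, Berks"],
                   store@tables$site_masters$id[2])
  expect_error(assignVariant(store, "geo", "site", "No such place", "X"), "no site variant")
})

test_that("dedup reports reproduce printed reduction statistics and closed forms", {
  expect_identical(dedupReport(9591, nMasters = 4835)@pctReduction, 50)
  expect_identical(dedupReport(10353, nMasters = 5429)@pctReduction, 48)
  # closed forms: all distinct -> 0%; all to one -> round(100 (n-1)/n)
  for (n in c(3, 7, 40)) {
    expect_identical(dedupReport(n, nMasters = n)@pctReduction, 0)
    expect_identical(dedupReport(n, nMasters = 1)@pctReduction,
                     colldigi:::roundHalfUp(100 * (n - 1) / n, 0))
  }
  expect_error(dedupReport(5, nMasters = 7), "masters cannot exceed variants")
})

test_that("specimen conservation holds under normalisation", {
  ps <- processedStore()
  store <- ps$store
  transcribeFromManifest(store, ps$manifest)
  normalizeFromManifest(store, ps$manifest)
  rep <- dedupReport(store, "site")
  perMaster <- colldigi:::.specimensPerMaster(store, "site")
  withSite <- sum(!is.na(store@tables$specimens$site_variant_id))
  expect_identical(length(perMaster), withSite)           # none lost or doubled
  expect_identical(sum(rep@topKCoverage$specimens[rep@topKCoverage$k == max(rep@topKCoverage$k)]),
                   as.integer(withSite))
  # specimens sharing a verbatim string share a master
  s <- store@tables$specimens
  v <- store@tables$site_variants
  m <- v$master_id[match(s$site_variant_id, v$id)]
  for (vid in unique(s$site_variant_id)) {
    expect_length(unique(m[s$site_variant_id == vid]), 1L)
  }
})

test_that("partial reports are refused unless requested, and merging masters is monotone", {
  store <- makeStore()
  ids <- vapply(1:4, function(i)
    colldigi:::.addSpecimenRecord(store, sprintf("X%d", i), "Drawer01", "Aus bus"), 1L)
  allocateRecords(store, "dm", "tr", ids)
  for (k in 1:4) transcribe(store, "tr", ids[k],
                            transcriptionInput(siteVerbatim = paste("Site", k)))
  assignVariant(store, "geo", "site", "Site 1", "Master A")
  expect_error(dedupReport(store, "site"), "unassigned")
  partial <- dedupReport(store, "site", partial = TRUE)
  expect_identical(partial@nVariants, 4L)
  expect_identical(partial@nAssigned, 1L)

  for (k in 2:4) assignVariant(store, "geo", "site", paste("Site", k), paste("Master", k))
  before <- dedupReport(store, "site")
  # merge Master 4 into Master A
  assignVariant(store, "geo", "site", "Site 4", "Master A")
  after <- dedupReport(store, "site")
  expect_lte(after@nMasters, before@nMasters)
  expect_gte(after@pctReduction, before@pctReduction)
})

test_that("taxon master seeding is idempotent and deduplicates the checklist", {
  store <- makeStore()
  checklist <- data.frame(name = c("Hesperia comma", "Polyommatus icarus",
                                   "Aglais urticae"), stringsAsFactors = FALSE)
  expect_identical(seedTaxonMasters(store, checklist), 3L)
  expect_warning(n2 <- seedTaxonMasters(store, checklist), "skipped")
  expect_identical(n2, 0L)
  dup <- rbind(checklist, checklist[1, ])
  store2 <- makeStore()
  expect_warning(n3 <- seedTaxonMasters(store2, dup), "skipped")
  expect_identical(n3, 3L)
  # CSV path form with a pre-matched CMS identifier
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(name = "Vanessa atalanta", irn = 42L), f, row.names = FALSE)
  store3 <- makeStore()
  expect_identical(seedTaxonMasters(store3, f), 1L)
  expect_identical(store3@tables$taxon_masters$cms_irn, 42L)
})
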