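test_that("verbatim label dates parse into the expected calendar ranges", {
  cases <- list(
    list(s = "14.vi.1921", start = "1921-06-14", end = "1921-06-14"),
    list(s = "14.6.1921", start = "1921-06-14", end = "1921-06-14"),
    list(s = "1.i.1900", start = "1900-01-01", end = "1900-01-01"),
    list(s = "29.ii.1904", start = "1904-02-29", end = "1904-02-29"),
    list(s = "vi.1921", start = "1921-06-01", end = "1921-06-30"),
    list(s = "ii.1900", start = "1900-02-01", end = "1900-02-28"),
    list(s = "12.1955", start = "1955-12-01", end = "1955-12-31"),
    list(s = "1921", start = "1921-01-01", end = "1921-12-31"),
    list(s = "12-14.vi.1921", start = "1921-06-12", end = "1921-06-14"),
    list(s = "28.vi-2.vii.1921", start = "1921-06-28", end = "1921-07-02"),
    list(s = "vi.1921-vii.1921", start = "1921-06-01", end = "1921-07-31"),
    list(s = "1920-1922", start = "1920-01-01", end = "1922-12-31"),
    list(s = "14.VI.1921", start = "1921-06-14", end = "1921-06-14"),
    list(s = "14/6/1921", start = "1921-06-14", end = "1921-06-14")
  )
  for (cs in cases) {
    r <- parseVerbatimDate(cs$s)
    expect_true(r$ok, label = cs$s)
    expect_identical(format(r$start), cs$start, label = cs$s)
    expect_identical(format(r$end), cs$end, label = cs$s)
  }
  bad <- c("14.vi.21", "21", "vi.21", "29.ii.1903", "32.i.1921", "14.xiii.1921",
           "", "no date", "14.vi.1921-13.vi.1921")
  for (s in bad) expect_false(parseVerbatimDate(s)$ok, label = s)
})

test_that("allocation controls visibility and reallocation is latest-wins", {
  store <- makeStore()
  addUser(store, "tr2", "transcriber")
  ids <- vapply(1:10, function(i)
    colldigi:::.addSpecimenRecord(store, sprintf("X%02d", i), "Drawer01", "Aus bus"), 1L)
  allocateRecords(store, "dm", "tr", ids)
  expect_setequal(recordsFor(store, "tr"), ids)
  expect_length(recordsFor(store, "tr2"), 0L)

  allocateRecords(store, "dm", "tr2", ids[1:5])
  expect_setequal(recordsFor(store, "tr"), ids[6:10])
  expect_setequal(recordsFor(store, "tr2"), ids[1:5])
  # both allocations audited
  a <- store@tables$audit
  expect_gte(sum(a$action == "allocate_record" & grepl("was tr", a$detail)), 5L)
  expect_error(allocateRecords(store, "tr", "tr2", ids[1]), "lacks required role")
})

test_that("transcription stores verbatim strings and reuses variants idempotently", {
  store <- makeStore()
  ids <- vapply(1:3, function(i)
    colldigi:::.addSpecimenRecord(store, sprintf("X%02d", i), "Drawer01", "Aus bus"), 1L)
  allocateRecords(store, "dm", "tr", ids)
  transcribe(store, "tr", ids[1], transcriptionInput(siteVerbatim = "Reading, Berks"))
  n1 <- nrow(store@tables$site_variants)
  transcribe(store, "tr", ids[2], transcriptionInput(siteVerbatim = "Reading, Berks"))
  expect_identical(nrow(store@tables$site_variants), n1)      # reused, not rekeyed
  transcribe(store, "tr", ids[3], transcriptionInput(siteVerbatim = "reading, berks"))
  expect_identical(nrow(store@tables$site_variants), n1 + 1L) # case-sensitive match
  expect_identical(store@tables$site_variants$name[1], "Reading, Berks")

  # escalation with no fields: flag set, status unchanged
  store2 <- makeStore()
  sid <- colldigi:::.addSpecimenRecord(store2, "X1", "Drawer01", "Aus bus")
  allocateRecords(store2, "dm", "tr", sid)
  transcribe(store2, "tr", sid, transcriptionInput(escalate = "for_scrutiny"))
  expect_true(colldigi:::.hasFlag(store2, sid, "for_scrutiny"))
  expect_identical(store2@tables$specimens$status[1], "imaged")
  expect_error(transcriptionInput(), "empty")
})

test_that("unallocated users are refused but can revisit their own past records", {
  store <- makeStore()
  addUser(store, "tr2", "transcriber")
  sid <- colldigi:::.addSpecimenRecord(store, "X1", "Drawer01", "Aus bus")
  allocateRecords(store, "dm", "tr", sid)
  expect_error(transcribe(store, "tr2", sid, transcriptionInput(siteVerbatim = "A")),
               "not allocated")
  transcribe(store, "tr", sid, transcriptionInput(siteVerbatim = "Reading"))
  allocateRecords(store, "dm", "tr2", sid)
  # tr lost the allocation but worked on the record before
  transcribe(store, "tr", sid, transcriptionInput(siteVerbatim = "Reading, Berks"))
  expect_identical(store@tables$site_variants$name,
                   c("Reading", "Reading, Berks"))
})

test_that("ambiguous dates flag the record instead of guessing", {
  store <- makeStore()
  sid <- colldigi:::.addSpecimenRecord(store, "X1", "Drawer01", "Aus bus")
  allocateRecords(store, "dm", "tr", sid)
  transcribe(store, "tr", sid, transcriptionInput(dateVerbatim = "14.vi.21"))
  t <- store@tables$specimens
  expect_identical(t$date_verbatim[1], "14.vi.21")   # verbatim always kept
  expect_true(is.na(t$date_start[1]))
  expect_true(colldigi:::.hasFlag(store, sid, "uncertain:date"))
})

test_that("completeness categories partition the records and match a census oracle", {
  # printed project table: counts in category order, total 181,545
  printed <- c(100798, 39869, 16942, 8966, 3968, 771, 688, 9543)
  tab <- completenessCategories(printed)
  expect_identical(sum(tab$count), 181545)
  expect_identical(tab$percent[1:4], c(56, 22, 9, 5))
  expect_identical(tab$percent, c(56, 22, 9, 5, 2, 0, 0, 5))

  # single full record
  expect_identical(completenessCategories(c(1, 0, 0, 0, 0, 0, 0, 0))$percent[1], 100)

  # random fixture vs brute-force triple-loop census
  set.seed(33)
  n <- 1000L
  site <- runif(n) < 0.7; date <- runif(n) < 0.6; coll <- runif(n) < 0.5
  oracle <- integer(8)
  for (i in seq_len(n)) {
    k <- if (site[i] && date[i] && coll[i]) 1L
    else if (site[i] && date[i]) 2L
    else if (site[i] && coll[i]) 3L
    else if (site[i]) 4L
    else if (coll[i] && !date[i]) 5L
    else if (date[i] && !coll[i]) 6L
    else if (date[i] && coll[i]) 7L
    else 8L
    oracle[k] <- oracle[k] + 1L
  }
  got <- colldigi:::.completenessFromFlags(site, date, coll)
  expect_identical(got, oracle)
  expect_identical(sum(got), n)
  # percentages sum to 100 exactly before rounding
  expect_equal(sum(100 * got / n), 100)
})
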