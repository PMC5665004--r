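# build a store whose site masters have prescribed specimen counts
storeWithCounts <- function(counts) {
  store <- makeStore()
  k <- 0L
  for (nm in names(counts)) {
    n <- counts[[nm]]
    ids <- vapply(seq_len(n), function(i) {
      k <<- k + 1L
      colldigi:::.addSpecimenRecord(store, sprintf("X%03d", k), "Drawer01", "Aus bus")
    }, 1L)
    allocateRecords(store, "dm", "tr", ids)
    for (sid in ids) transcribe(store, "tr", sid,
                                transcriptionInput(siteVerbatim = paste0(nm, " verbatim")))
    assignVariant(store, "geo", "site", paste0(nm, " verbatim"), nm)
  }
  store
}

test_that("the triage queue splits at the threshold and partitions A-M/N-Z", {
  store <- storeWithCounts(c(Aberdeen = 8L, Bath = 5L, Neath = 4L, York = 1L))
  q <- buildTriageQueue(store, threshold = 5L)
  e <- q@entries
  expect_setequal(e$name[e$stage == "high_frequency"], c("Aberdeen", "Bath"))
  expect_setequal(e$name[e$stage == "split_pass"], c("Neath", "York"))
  # ordering: by count descending
  expect_identical(e$name[e$stage == "high_frequency"], c("Aberdeen", "Bath"))
  expect_identical(e$partition[e$name == "Bath"], "none")
  expect_identical(e$partition[e$name == "Neath"], "N-Z")
  expect_identical(e$partition[e$name == "York"], "N-Z")
  # every master in exactly one stage
  expect_identical(sort(e$name), sort(store@tables$site_masters$name))
  expect_identical(anyDuplicated(e$name), 0L)
  # coverage fraction: 13 of 18 specimens at high-frequency sites
  expect_equal(q@coverageHighFreq, 13 / 18)
})

test_that("top-k specimen coverage is non-decreasing in k", {
  set.seed(71)
  counts <- setNames(as.list(sample(1:20, 12L, replace = TRUE)),
                     paste0("Site", sprintf("%02d", 1:12)))
  store <- storeWithCounts(counts)
  q <- buildTriageQueue(store, threshold = 5L)
  ord <- order(-q@entries$n_specimens)
  cum <- cumsum(q@entries$n_specimens[ord])
  expect_true(all(diff(cum) >= 0))
  expect_identical(cum[length(cum)], sum(unlist(counts)))
})

test_that("georeferences validate coordinates and cascade to specimens", {
  store <- storeWithCounts(c(`Reading, Berkshire, UK, Europe` = 3L))
  expect_error(setGeoreference(store, "geo", "Reading, Berkshire, UK, Europe", 91, 0, 100),
               "latitude")
  expect_error(setGeoreference(store, "geo", "Reading, Berkshire, UK, Europe", 51, -181, 100),
               "longitude")
  expect_error(setGeoreference(store, "geo", "Reading, Berkshire, UK, Europe", 51, 0, 0),
               "extent")
  setGeoreference(store, "geo", "Reading, Berkshire, UK, Europe", 51.4543, -0.9781, 5000)
  expect_true(all(store@tables$specimens$status == "georeferenced"))
  # re-georeferencing keeps the previous value in the audit history
  setGeoreference(store, "geo", "Reading, Berkshire, UK, Europe", 51.46, -0.98, 4000)
  a <- store@tables$audit
  expect_identical(sum(a$action == "georeference_superseded"), 1L)
  expect_match(a$detail[a$action == "georeference_superseded"], "51.4543")
})

test_that("un-georeferenceable marking gates the queue and needs scrutineer to undo", {
  store <- storeWithCounts(c(Lostville = 2L, Bath = 6L))
  markUngeoreferenceable(store, "geo", "Lostville", "no such place found")
  q <- buildTriageQueue(store, threshold = 5L)
  expect_false("Lostville" %in% q@entries$name)
  expect_error(markUngeoreferenceable(store, "tr", "Bath"), "lacks required role")
  setGeoreference(store, "geo", "Bath", 51.38, -2.36, 2000)
  expect_error(markUngeoreferenceable(store, "geo", "Bath"), "already georeferenced")
  expect_error(unmarkUngeoreferenceable(store, "geo", "Lostville"), "lacks required role")
  unmarkUngeoreferenceable(store, "scr", "Lostville")
  expect_true("Lostville" %in% buildTriageQueue(store, 5L)@entries$name)
})

test_that("QA agreement matches a hand-rolled haversine oracle and is symmetric", {
  haversine <- function(lat1, lon1, lat2, lon2) {
    rad <- pi / 180
    dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
    a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
    2 * 6371000 * asin(sqrt(a))
  }
  # 0.0018 deg of latitude is ~200 m; 0.0008 is ~89 m
  a <- data.frame(master = c("P", "Q", "R"), lat = c(51, 52, 53), lon = c(0, 1, -1),
                  extent_m = c(500, 500, 500))
  b <- data.frame(master = c("P", "Q", "R"),
                  lat = c(51, 52 + 0.0008, 53 + 0.0018), lon = c(0, 1, -1),
                  extent_m = c(500, 500, 500))
  for (i in 1:3) {
    expect_equal(geosphere::distHaversine(c(a$lon[i], a$lat[i]), c(b$lon[i], b$lat[i]),
                                          r = 6371000),
                 haversine(a$lat[i], a$lon[i], b$lat[i], b$lon[i]), tolerance = 1e-9)
  }
  r <- qaAgreement(a, b, sampleN = 3L, seed = 5L, thresholdM = 100)
  expect_equal(r$rate, 2 / 3)        # P identical, Q ~100m, R ~200m
  rSwap <- qaAgreement(b, a, sampleN = 3L, seed = 5L, thresholdM = 100)
  expect_identical(r$rate, rSwap$rate)
  # identical result sets agree everywhere
  expect_identical(qaAgreement(a, a, sampleN = 3L, seed = 1L)$rate, 1)
  # sample larger than available: all used, with a warning
  expect_warning(rAll <- qaAgreement(a, b, sampleN = 10L, seed = 1L, thresholdM = 100),
                 "using all")
  expect_identical(rAll$n, 3L)
  # extent overlap requirement: distant extents must both be crossed
  a2 <- data.frame(master = "S", lat = 51, lon = 0, extent_m = 50)
  b2 <- data.frame(master = "S", lat = 51.0018, lon = 0, extent_m = 50)
  expect_identical(qaAgreement(a2, b2, sampleN = 1L, seed = 1L, thresholdM = 10000)$rate, 0)
})
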