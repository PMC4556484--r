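write_sites_fixture <- function(path, rows) {
  header <- "site_id,site_name,lon,lat,phase_start,phase_end,rice_status,evidence,ecology,dated_by"
  writeLines(c(header, rows), path)
}

test_that("median phase age follows the BP convention and normalises order", {
  expect_equal(median_age_bp(-3000, -2000), 4450)
  expect_equal(median_age_bp(300, 500), 1550)
  # swapping start and end leaves the midpoint unchanged
  expect_equal(median_age_bp(-2000, -3000), 4450)
})

test_that("CSV reader parses rows, computes ages and rejects bad records", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_sites_fixture(path, c(
    "A,Site A,110,30,-3000,-2000,cultivated,macro_remains,wet,radiocarbon",
    "B,Site B,112,31,300,500,cultivated,phytolith,dry,radiocarbon",
    "C,Site C,113,not_a_lat,-4000,-3500,wild,other,unknown,cultural_association",
    "D,Site D,114,33,-5000,-4500,cultivated,impression,wet,radiocarbon",
    "E,Site E,115,34,-2500,-1500,wild,macro_remains,unknown,radiocarbon"))
  expect_warning(tab <- read_sites_csv(path), "rejected 1")
  expect_s3_class(tab, "site_table")
  expect_equal(nrow(tab), 4)
  expect_equal(nrow(attr(tab, "diagnostics")), 1)
  expect_equal(attr(tab, "diagnostics")$site_id, "C")
  expect_equal(tab$median_age[tab$site_id == "A"], 4450)
  expect_equal(tab$median_age[tab$site_id == "B"], 1550)
})

test_that("CSV reader applies dialects and reports schema errors by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,longitude,lat,phase_start,phase_end,rice_status",
               "A,110,30,-3000,-2000,cultivated"), path)
  tab <- read_sites_csv(path, dialect = list(site_id = "id", lon = "longitude"))
  expect_equal(tab$lon, 110)
  expect_error(read_sites_csv(path), "site_id")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("site_id,lon,lat,phase_start,phase_end,rice_status", empty)
  expect_error(read_sites_csv(empty), "empty")
})

test_that("phase order is normalised on read (start is the older year)", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_sites_fixture(path,
    "A,Site A,110,30,-2000,-3000,cultivated,macro_remains,wet,radiocarbon")
  tab <- read_sites_csv(path)
  expect_equal(tab$phase_start, -3000)
  expect_equal(tab$phase_end, -2000)
  expect_equal(tab$median_age, 4450)
})

kml_placemark <- function(name, lon, lat, data = list()) {
  fields <- paste(vapply(names(data), function(k) sprintf(
    '<Data name="%s"><value>%s</value></Data>', k, data[[k]]), ""),
    collapse = "")
  sprintf(paste0(
    "<Placemark><name>%s</name><ExtendedData>%s</ExtendedData>",
    "<Point><coordinates>%f,%f,0</coordinates></Point></Placemark>"),
    name, fields, lon, lat)
}

kml_doc <- function(placemarks) {
  paste0('<?xml version="1.0" encoding="UTF-8"?>',
         '<kml xmlns="http://www.opengis.net/kml/2.2"><Document>',
         paste(placemarks, collapse = ""), "</Document></kml>")
}

test_that("KML and KMZ placemarks round-trip to site records", {
  kml <- kml_doc(kml_placemark("Site A", 110.25, 30.5, list(
    site_id = "A", phase_start = "-3000", phase_end = "-2000",
    rice_status = "cultivated")))
  path <- withr::local_tempfile(fileext = ".kml")
  writeLines(kml, path)
  tab <- read_sites_kml(path)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$lon, 110.25)
  expect_equal(tab$lat, 30.5)
  expect_equal(tab$median_age, 4450)

  # KMZ container holding the same document yields the identical table
  kmz <- withr::local_tempfile(fileext = ".kmz")
  write_stored_zip(kmz, "doc.kml", kml)
  tab2 <- read_sites_kml(kmz)
  attr(tab, "provenance") <- attr(tab2, "provenance") <- NULL
  expect_equal(as.data.frame(tab2), as.data.frame(tab))
})

test_that("undated placemarks are kept with NA ages and a warning", {
  kml <- kml_doc(kml_placemark("Site U", 100, 20,
                               list(rice_status = "cultivated")))
  path <- withr::local_tempfile(fileext = ".kml")
  writeLines(kml, path)
  expect_warning(tab <- read_sites_kml(path), "lack date")
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$median_age))

  notkml <- withr::local_tempfile(fileext = ".kml")
  writeLines("just,a,csv", notkml)
  expect_error(read_sites_kml(notkml), "not KML")
})

test_that("analysis-set selection filters status, domain and phase", {
  dom <- helper_domain(matrix(rep(c(TRUE, FALSE), each = 50), 10, 10),
                       cell_size = 30)
  # cells (5, 2) traversable; (5, 9) masked
  ll_in <- cell_to_lonlat(5, 2, dom$spec)
  ll_out <- cell_to_lonlat(5, 9, dom$spec)
  tab <- tibble::tibble(
    site_id = c("w1", "w2", "off", "s1", "s1"),
    site_name = site_id,
    lon = c(ll_in$lon, ll_in$lon, ll_out$lon, ll_in$lon, ll_in$lon),
    lat = c(ll_in$lat, ll_in$lat, ll_out$lat, ll_in$lat, ll_in$lat),
    phase_start = -3000, phase_end = -2000,
    median_age = c(5000, 5000, 5000, 4000, 6000),
    rice_status = c("wild", "wild", "cultivated", "cultivated", "cultivated"),
    evidence = "other", ecology = "unknown", dated_by = "radiocarbon")
  sel <- select_analysis_set(tab, dom)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$site_id, "s1")
  expect_equal(sel$median_age, 6000)      # oldest phase of the site retained
  # idempotent
  sel2 <- select_analysis_set(sel, dom)
  expect_equal(as.data.frame(sel2), as.data.frame(sel))
  # every retained record is on a traversable cell
  expect_true(all(dom$traversable[cbind(sel$row, sel$col)]))

  expect_warning(empty <- select_analysis_set(tab[1:2, ], dom), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("seeded off-domain records are excluded by construction", {
  mask <- matrix(TRUE, 20, 20)
  mask[, 11:20] <- FALSE
  dom <- helper_domain(mask, cell_size = 25)
  set.seed(42)
  n <- 50
  rows <- sample(20, n, replace = TRUE)
  cols <- c(sample(10, 43, replace = TRUE), sample(11:20, 7, replace = TRUE))
  ll <- cell_to_lonlat(rows, cols, dom$spec)
  tab <- tibble::tibble(
    site_id = sprintf("s%02d", 1:n), site_name = site_id,
    lon = ll$lon, lat = ll$lat, phase_start = -3000, phase_end = -2000,
    median_age = 4450 + (1:n), rice_status = "cultivated",
    evidence = "other", ecology = "unknown", dated_by = "radiocarbon")
  sel <- select_analysis_set(tab, dom)
  expect_equal(nrow(sel), 43)
})
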