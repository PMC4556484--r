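#' Site/phase database tools
#'
#' A site table holds one row per dated phase at an archaeological site, with
#' geographic coordinates, a calendar phase interval, the derived median age in
#' years BP, and categorical evidence fields. The calendar convention is
#' signed years with BC negative (astronomical numbering, no year-0
#' adjustment), and `median_age = 1950 - (phase_start + phase_end) / 2`.
#'
#' @name site_table
NULL

.rice_status_levels <- c("wild", "cultivated")
.evidence_levels <- c("macro_remains", "phytolith", "impression", "other")
.ecology_levels <- c("wet", "dry", "unknown")
.dated_by_levels <- c("radiocarbon", "cultural_association")

.site_required_cols <- c("site_id", "lon", "lat", "phase_start", "phase_end",
                         "rice_status")

.new_site_table <- function(df, provenance, diagnostics = tibble()) {
  out <- as_tibble(df)
  class(out) <- c("site_table", class(out))
  attr(out, "provenance") <- provenance
  attr(out, "diagnostics") <- diagnostics
  out
}

# dplyr verbs drop subclasses; restore after filtering
.restore_site_table <- function(out, template) {
  .new_site_table(as_tibble(out), attr(template, "provenance"),
                  attr(template, "diagnostics"))
}

#' Median age of a calendar phase in years BP
#'
#' @param phase_start,phase_end Signed calendar years (BC negative). Order is
#'   normalised, so swapping the two arguments leaves the result unchanged.
#' @return Years before present (BP, 1950 reference).
#' @export
median_age_bp <- function(phase_start, phase_end) {
  lo <- pmin(phase_start, phase_end)
  hi <- pmax(phase_start, phase_end)
  1950 - (lo + hi) / 2
}

#' Read a site/phase database from CSV
#'
#' Expects the canonical columns `site_id, site_name, lon, lat, phase_start,
#' phase_end, median_age (optional), rice_status, evidence, ecology, dated_by`
#' (UTF-8, header required). A `dialect` may rename columns,
#' e.g. `list(lon = "longitude")` reads the file's `longitude` column as
#' `lon`. Rows with unparseable coordinates or dates are rejected and reported
#' in the `diagnostics` attribute (one row each, with the reason); a warning
#' summarises the count. `median_age` is recomputed from the phase interval
#' when absent, and `phase_start`/`phase_end` are normalised so the start is
#' the older (smaller) calendar year.
#'
#' @param path CSV file path.
#' @param dialect Optional named list mapping canonical names to file column
#'   names.
#' @return A `site_table` tibble; attribute `diagnostics` holds rejected rows.
#' @export
read_sites_csv <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) abort(sprintf("empty site table: %s", path))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(raw))
        abort(sprintf("dialect column '%s' (for '%s') not in file",
                      dialect[[canon]], canon))
      names(raw)[names(raw) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.site_required_cols, names(raw))
  if (length(missing_cols) > 0)
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  for (opt in c("site_name", "median_age", "evidence", "ecology", "dated_by"))
    if (!opt %in% names(raw)) raw[[opt]] <- NA_character_

  num <- function(v) suppressWarnings(as.numeric(v))
  parsed <- tibble(
    site_id = raw$site_id,
    site_name = dplyr::coalesce(raw$site_name, raw$site_id),
    lon = num(raw$lon), lat = num(raw$lat),
    phase_start = num(raw$phase_start), phase_end = num(raw$phase_end),
    median_age = num(raw$median_age),
    rice_status = raw$rice_status,
    evidence = dplyr::coalesce(raw$evidence, "other"),
    ecology = dplyr::coalesce(raw$ecology, "unknown"),
    dated_by = dplyr::coalesce(raw$dated_by, "radiocarbon"))

  reason <- rep(NA_character_, nrow(parsed))
  bad_coord <- is.na(parsed$lon) | is.na(parsed$lat) |
    abs(parsed$lon) > 180 | abs(parsed$lat) > 90
  bad_date <- is.na(parsed$phase_start) | is.na(parsed$phase_end)
  bad_status <- !parsed$rice_status %in% .rice_status_levels
  reason[bad_status] <- "unrecognised rice_status"
  reason[bad_date] <- "unparseable phase dates"
  reason[bad_coord] <- "unparseable or out-of-range coordinates"
  bad <- !is.na(reason)
  diagnostics <- tibble(line = which(bad) + 1L, site_id = parsed$site_id[bad],
                        reason = reason[bad])
  if (any(bad))
    warn(sprintf("rejected %d of %d rows (see attr(x, 'diagnostics'))",
                 sum(bad), nrow(parsed)))
  ok <- parsed[!bad, ]
  lo <- pmin(ok$phase_start, ok$phase_end)
  hi <- pmax(ok$phase_start, ok$phase_end)
  ok$phase_start <- lo
  ok$phase_end <- hi
  ok$median_age <- ifelse(is.na(ok$median_age),
                          median_age_bp(ok$phase_start, ok$phase_end),
                          ok$median_age)
  .new_site_table(ok, provenance = path, diagnostics = diagnostics)
}

# default mapping from KML ExtendedData field names to canonical columns
.default_kml_fields <- list(
  site_id = "site_id", phase_start = "phase_start", phase_end = "phase_end",
  median_age = "median_age", rice_status = "rice_status",
  evidence = "evidence", ecology = "ecology", dated_by = "dated_by")

#' Read a site/phase database from KML or KMZ placemarks
#'
#' Placemark coordinates become `lon`/`lat` and the placemark name becomes
#' `site_name`; other fields are looked up in each placemark's
#' `ExtendedData/Data` entries through `field_map` (canonical column ->
#' KML field name). A KMZ file (zipped KML) is unpacked transparently.
#' Placemarks without date fields are kept with `NA` ages and a warning, so
#' partially attributed databases are not silently truncated.
#'
#' @param path KML or KMZ file path.
#' @param field_map Named list mapping canonical columns to KML
#'   `ExtendedData` field names.
#' @return A `site_table` tibble.
#' @export
read_sites_kml <- function(path, field_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  fm <- utils::modifyList(.default_kml_fields, field_map %||% list())
  magic <- readBin(path, "raw", 2)
  if (identical(magic, as.raw(c(0x50, 0x4b)))) {   # "PK": zipped => KMZ
    exdir <- tempfile("kmz")
    files <- unzip(path, exdir = exdir)
    kml <- files[grepl("\\.kml$", files, ignore.case = TRUE)]
    if (length(kml) == 0) abort("KMZ archive contains no .kml document")
    path <- kml[1]
  }
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort("not KML: XML parse failure"))
  ns_def <- xml2::xml_ns(doc)
  has_ns <- any(grepl("kml", ns_def, fixed = TRUE))
  xp <- function(node, what) {
    if (has_ns) xml2::xml_find_all(node, sprintf(".//d1:%s", what), ns_def)
    else xml2::xml_find_all(node, sprintf(".//%s", what))
  }
  pms <- xp(doc, "Placemark")
  if (length(pms) == 0) abort("not KML: no Placemark elements found")

  rows <- purrr::map_dfr(seq_along(pms), function(i) {
    pm <- pms[[i]]
    coords <- xml2::xml_text(xp(pm, "coordinates"))
    if (length(coords) == 0) return(tibble())
    cparts <- as.numeric(strsplit(trimws(coords[1]), ",")[[1]])
    name <- xml2::xml_text(xp(pm, "name"))
    data_nodes <- xp(pm, "Data")
    fields <- setNames(
      xml2::xml_text(xp(pm, "value")),
      xml2::xml_attr(data_nodes, "name"))
    get <- function(canon) {
      key <- fm[[canon]]
      if (!is.null(key) && key %in% names(fields)) fields[[key]] else NA_character_
    }
    num <- function(v) suppressWarnings(as.numeric(v))
    tibble(
      site_id = get("site_id") %|na|% sprintf("pm%03d", i),
      site_name = if (length(name) > 0) name[1] else sprintf("pm%03d", i),
      lon = cparts[1], lat = cparts[2],
      phase_start = num(get("phase_start")),
      phase_end = num(get("phase_end")),
      median_age = num(get("median_age")),
      rice_status = get("rice_status") %|na|% "cultivated",
      evidence = get("evidence") %|na|% "other",
      ecology = get("ecology") %|na|% "unknown",
      dated_by = get("dated_by") %|na|% "radiocarbon")
  })
  lo <- pmin(rows$phase_start, rows$phase_end)
  hi <- pmax(rows$phase_start, rows$phase_end)
  rows$phase_start <- lo
  rows$phase_end <- hi
  rows$median_age <- ifelse(is.na(rows$median_age) & !is.na(lo),
                            median_age_bp(lo, hi), rows$median_age)
  undated <- is.na(rows$median_age)
  if (any(undated))
    warn(sprintf("%d placemark(s) lack date fields; ages set to NA",
                 sum(undated)))
  .new_site_table(rows, provenance = path)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Reduce a site table to the analysis set
#'
#' Applies the record-selection rule for dispersal fitting: keep only
#' cultivated-status records, keep only records that fall on a traversable
#' cell of the modelling domain, then keep the oldest qualifying phase of each
#' site, and require a positive median age. The reduction is idempotent.
#'
#' @param sites A `site_table`.
#' @param domain A [build_domain()] result.
#' @return Filtered `site_table` with `row`/`col` cell indices attached.
#' @export
select_analysis_set <- function(sites, domain) {
  stopifnot(inherits(domain, "domain_grid"))
  out <- dplyr::filter(as_tibble(sites), .data$rice_status == "cultivated",
                       !is.na(.data$median_age), .data$median_age > 0)
  if (nrow(out) > 0) {
    cells <- lonlat_to_cell(out$lon, out$lat, domain$spec, strict = FALSE)
    out$row <- cells$row
    out$col <- cells$col
    inside <- !is.na(out$row)
    trav <- rep(FALSE, nrow(out))
    trav[inside] <- domain$traversable[cbind(out$row[inside], out$col[inside])]
    out <- out[trav, ]
  }
  out <- out |>
    dplyr::group_by(.data$site_id) |>
    dplyr::slice_max(.data$median_age, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site_id)
  if (nrow(out) == 0)
    warn("empty selection: no cultivated records inside the domain")
  .restore_site_table(out, sites)
}
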