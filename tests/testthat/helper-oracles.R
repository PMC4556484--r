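# Shared fixtures and independent oracles.

# Domain whose traversable set is exactly `mask` (land everywhere, desert on
# the masked cells, uniformly warm climate).
helper_domain <- function(mask, cell_size = 1, center_lon = 0, center_lat = 0) {
  spec <- grid_spec(nrow(mask), ncol(mask), cell_size, center_lon, center_lat)
  temps <- lapply(1:12, function(m) matrix(20, nrow(mask), ncol(mask)))
  dd <- compute_degree_days(temps)
  land <- matrix(TRUE, nrow(mask), ncol(mask))
  build_domain(dd, !mask, land, spec)
}

# Grid Dijkstra oracle: shortest paths over 4- or 8-connected moves,
# edge weights h and h*sqrt(2). O(V^2), fine for small grids.
dijkstra_grid <- function(mask, src_row, src_col, h = 1, neighbours = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  dist <- matrix(Inf, nr, nc)
  done <- matrix(FALSE, nr, nc)
  dist[src_row, src_col] <- 0
  moves <- rbind(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1))
  if (neighbours == 8)
    moves <- rbind(moves, c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                   c(1, -1, sqrt(2)), c(1, 1, sqrt(2)))
  for (step in seq_len(nr * nc)) {
    d <- dist
    d[done] <- Inf
    i <- arrayInd(which.min(d), dim(d))
    if (!is.finite(d[i])) break
    done[i] <- TRUE
    for (k in seq_len(nrow(moves))) {
      r2 <- i[1] + moves[k, 1]; c2 <- i[2] + moves[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!mask[r2, c2]) next
      alt <- dist[i] + h * moves[k, 3]
      if (alt < dist[r2, c2]) dist[r2, c2] <- alt
    }
  }
  dist
}

# Exact quantile-line oracle: enumerate all lines through point pairs and
# return the one minimising the summed check loss.
enum_quantile_line <- function(x, y, tau) {
  best <- NULL
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (abs(x[i] - x[j]) < 1e-12) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    loss <- sum(check_loss(y - a - b * x, tau))
    if (is.null(best) || loss < best$loss - 1e-12)
      best <- list(intercept = a, slope = b, loss = loss)
  }
  best
}

# Small, fast toy-world configuration for pipeline tests.
helper_toy_config <- function(seed = 1, ...) {
  toy_world_config(n_rows = 40, n_cols = 60, cell_size_km = 40,
                   n_sites = 120, seed = seed, ...)
}

# Minimal ZIP writer (single stored entry, no compression) so KMZ fixtures
# can be built at test time from plain text.
crc32_r <- function(bytes) {
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L)) bitwXor(bitwShiftR(c, 1), -306674912L)
           else bitwShiftR(c, 1)
    tab[i + 1] <- c
  }
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(bitwShiftR(crc, 8) %% 16777216L,
                   tab[bitwAnd(bitwXor(crc, b), 255L) + 1])
  bitwXor(crc, -1L)
}

write_stored_zip <- function(zip_path, entry_name, text) {
  data <- charToRaw(text)
  name <- charToRaw(entry_name)
  crc <- crc32_r(data)
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  con <- file(zip_path, "wb")
  on.exit(close(con))
  # local file header
  u32(0x04034b50); u16(20); u16(0); u16(0); u16(0); u16(0)
  u32(crc); u32(length(data)); u32(length(data))
  u16(length(name)); u16(0)
  writeBin(name, con); writeBin(data, con)
  cd_start <- 30 + length(name) + length(data)
  # central directory
  u32(0x02014b50); u16(20); u16(20); u16(0); u16(0); u16(0); u16(0)
  u32(crc); u32(length(data)); u32(length(data))
  u16(length(name)); u16(0); u16(0); u16(0); u16(0); u32(0); u32(0)
  writeBin(name, con)
  cd_size <- 46 + length(name)
  # end of central directory
  u32(0x06054b50); u16(0); u16(0); u16(1); u16(1)
  u32(cd_size); u32(cd_start); u16(0)
  invisible(zip_path)
}
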