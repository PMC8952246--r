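# Minimal store-only (method 0) ZIP writer.
#
# The session bundle is a zip archive, but no external `zip` binary can be
# assumed, so the archive is assembled here from its documented on-disk
# structure: one local file header + payload per member, a central directory,
# and the end-of-central-directory record. Entries are stored uncompressed;
# R's unzip() (internal method) and any standard tool read the result.
# Timestamps are fixed so that exports are byte-deterministic.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320
           else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(crc, b[i]), 255L)
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[idx + 1L])
  }
  crc <- bitwXor(crc, -1L)
  v <- as.numeric(crc)
  if (v < 0) v <- v + 2^32
  v
}

# little-endian byte packing of non-negative doubles
le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

ZIP_DOSTIME <- le_bytes(0, 2)                      # 00:00:00
ZIP_DOSDATE <- le_bytes((42 * 512) + (3 * 32) + 11, 2) # fixed date

zip_member <- function(name, payload) {
  crc <- crc32(payload)
  sz <- length(payload)
  nm <- charToRaw(name)
  local_header <- c(
    le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0x0800, 2), # UTF-8 flag
    le_bytes(0, 2), ZIP_DOSTIME, ZIP_DOSDATE,
    le_bytes(crc, 4), le_bytes(sz, 4), le_bytes(sz, 4),
    le_bytes(length(nm), 2), le_bytes(0, 2), nm
  )
  list(name = nm, crc = crc, size = sz, local = c(local_header, payload))
}

write_zip_archive <- function(files, zipfile) {
  # files: named list name -> raw payload
  members <- Map(zip_member, names(files), files)
  offsets <- cumsum(c(0, vapply(members, function(m) length(m$local), 0)))
  central <- list()
  for (i in seq_along(members)) {
    m <- members[[i]]
    central[[i]] <- c(
      le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2), le_bytes(0x0800, 2),
      le_bytes(0, 2), ZIP_DOSTIME, ZIP_DOSDATE,
      le_bytes(m$crc, 4), le_bytes(m$size, 4), le_bytes(m$size, 4),
      le_bytes(length(m$name), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
      le_bytes(offsets[i], 4), m$name
    )
  }
  cd <- do.call(c, central)
  cd_offset <- offsets[length(offsets)]
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(members), 2), le_bytes(length(members), 2),
    le_bytes(length(cd), 4), le_bytes(cd_offset, 4), le_bytes(0, 2)
  )
  con <- file(zipfile, "wb")
  on.exit(close(con))
  writeBin(do.call(c, c(lapply(members, `[[`, "local"), list(cd, eocd))), con)
  invisible(zipfile)
}
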