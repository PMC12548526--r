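# Low-level binary layout shared by every index file.
#
# All integers little-endian. Feature/block numbers and table positions are
# unsigned 32-bit (0-based on disk; the sentinel 0xFFFFFFFF encodes "none").
# Byte offsets, coordinates and element counts are unsigned 64-bit. Strings
# are a u32 byte length followed by the raw bytes; the length sentinel
# 0xFFFFFFFF encodes an absent string. Every file starts with a fixed header:
#
#   magic        4 bytes  "ADXI"
#   version      u32      format version (currently 1)
#   hash_algo    u32      1 = xxHash64 over the full source GFF bytes
#   source_size  u64      size of the source GFF in bytes
#   checksum     8 bytes  xxHash64 digest of the source GFF (big-endian hex
#                         order as printed by digest(), stored raw)
#
# 64-bit values are held as R doubles; exactness is guaranteed below 2^53,
# far beyond any annotation file or genome coordinate in practice.

ADX_MAGIC <- charToRaw("ADXI")
ADX_FORMAT_VERSION <- 1L
ADX_HASH_XXHASH64 <- 1L
U32_SENTINEL <- 4294967295  # 2^32 - 1, "none"

write_u32 <- function(con, x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0) || any(x > U32_SENTINEL)) {
    adx_error("annodex_capacity_error", "value out of unsigned 32-bit range")
  }
  x[x >= 2^31] <- x[x >= 2^31] - 2^32
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

read_u32 <- function(con, n = 1L) {
  x <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(x) < n) adx_data_error("truncated index file (u32)")
  x <- as.numeric(x)
  x[x < 0] <- x[x < 0] + 2^32
  x
}

write_u64 <- function(con, x) {
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0) || any(x >= 2^53)) {
    adx_error("annodex_capacity_error", "value out of exact 64-bit (double) range")
  }
  hi <- floor(x / 2^32)
  lo <- x - hi * 2^32
  both <- as.vector(rbind(lo, hi))  # lo word first (little-endian)
  both[both >= 2^31] <- both[both >= 2^31] - 2^32
  writeBin(as.integer(both), con, size = 4L, endian = "little")
}

read_u64 <- function(con, n = 1L) {
  w <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  if (length(w) < 2L * n) adx_data_error("truncated index file (u64)")
  w <- as.numeric(w)
  w[w < 0] <- w[w < 0] + 2^32
  lo <- w[seq(1L, 2L * n, by = 2L)]
  hi <- w[seq(2L, 2L * n, by = 2L)]
  hi * 2^32 + lo
}

# Strings: u32 length (0xFFFFFFFF = absent/NA) + raw bytes.
write_str <- function(con, x) {
  for (s in x) {
    if (is.na(s)) {
      write_u32(con, U32_SENTINEL)
    } else {
      b <- charToRaw(s)
      write_u32(con, length(b))
      writeBin(b, con)
    }
  }
}

read_str <- function(con, n = 1L) {
  out <- character(n)
  for (i in seq_len(n)) {
    len <- read_u32(con)
    if (len == U32_SENTINEL) {
      out[i] <- NA_character_
    } else if (len == 0) {
      out[i] <- ""
    } else {
      b <- readBin(con, "raw", n = len)
      if (length(b) < len) adx_data_error("truncated index file (string)")
      out[i] <- rawToChar(b)
    }
  }
  out
}

# Feature/block numbers: 1-based in memory, 0-based on disk, NA = sentinel.
write_featno <- function(con, x) {
  x <- as.numeric(x) - 1
  x[is.na(x)] <- U32_SENTINEL
  write_u32(con, x)
}

read_featno <- function(con, n = 1L) {
  x <- read_u32(con, n)
  x[x == U32_SENTINEL] <- NA
  x + 1
}

source_checksum <- function(path) {
  digest::digest(file = path, algo = "xxhash64")
}

write_header <- function(con, source_size, checksum_hex) {
  writeBin(ADX_MAGIC, con)
  write_u32(con, ADX_FORMAT_VERSION)
  write_u32(con, ADX_HASH_XXHASH64)
  write_u64(con, source_size)
  ck <- as.raw(strtoi(substring(checksum_hex,
                                seq(1, 15, by = 2), seq(2, 16, by = 2)),
                      base = 16L))
  writeBin(ck, con)
}

read_header <- function(con, path = "<index>") {
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, ADX_MAGIC)) {
    adx_data_error(sprintf("%s: not an annodex index file (bad magic)", path))
  }
  version <- read_u32(con)
  if (version != ADX_FORMAT_VERSION) {
    adx_data_error(sprintf("%s: unsupported index format version %d", path, version))
  }
  hash_algo <- read_u32(con)
  source_size <- read_u64(con)
  ck <- readBin(con, "raw", n = 8L)
  list(version = version, hash_algo = hash_algo,
       source_size = source_size,
       checksum = paste(sprintf("%02x", as.integer(ck)), collapse = ""))
}

header_nbytes <- function() 28L

check_header_fresh <- function(header, gff_path, index_path) {
  if (header$hash_algo != ADX_HASH_XXHASH64) {
    adx_stale_error(sprintf(
      "%s: index written with unknown hash algorithm %d; re-index",
      index_path, header$hash_algo))
  }
  cur_size <- file.size(gff_path)
  if (!isTRUE(cur_size == header$source_size) ||
      !identical(source_checksum(gff_path), header$checksum)) {
    adx_stale_error(sprintf(
      "%s: stale index (source file %s changed since indexing); re-index",
      index_path, gff_path))
  }
  invisible(TRUE)
}
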