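# Little-endian binary helpers. R has no unsigned 64-bit type, so labels
# and offsets ride in doubles; exact for values < 2^53, which covers every
# chunk/shard offset and every label this package emits.

u8_to_raw <- function(x) as.raw(x)

u16_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, x %/% 256))
}

raw_to_u16 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 2)
  m[1, ] + 256 * m[2, ]
}

u32_to_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256,
               (x %/% 256) %% 256,
               (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}

raw_to_u32 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 4)
  m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
}

u64_to_raw <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x >= 2^53)) {
    stop("64-bit values outside [0, 2^53) are not representable")
  }
  lo <- x %% 2^32
  hi <- x %/% 2^32
  lo_r <- matrix(as.numeric(u32_to_raw(lo)), nrow = 4)
  hi_r <- matrix(as.numeric(u32_to_raw(hi)), nrow = 4)
  as.raw(rbind(lo_r, hi_r))
}

raw_to_u64 <- function(r) {
  m <- matrix(as.numeric(r), nrow = 8)
  lo <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
  hi <- m[5, ] + 256 * m[6, ] + 65536 * m[7, ] + 16777216 * m[8, ]
  lo + 2^32 * hi
}

f32_to_raw <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

raw_to_f32 <- function(r) readBin(r, "numeric", n = length(r) / 4, size = 4,
                                  endian = "little")

# fixed-width unsigned int <-> raw for a voxel payload of the given dtype
values_to_raw <- function(x, data_type) {
  switch(data_type,
         uint8 = u8_to_raw(x),
         uint16 = u16_to_raw(x),
         uint32 = u32_to_raw(x),
         uint64 = u64_to_raw(x))
}

raw_to_values <- function(r, data_type) {
  switch(data_type,
         uint8 = as.numeric(r),
         uint16 = raw_to_u16(r),
         uint32 = raw_to_u32(r),
         uint64 = raw_to_u64(r))
}

# Bit-pack 0-based palette indices at a fixed width (bits per index in
# 0/1/2/4/8/16/32) into a little-endian byte stream; width 0 packs nothing.
pack_indices <- function(idx, bits) {
  n <- length(idx)
  if (bits == 0) return(raw(0))
  if (bits %in% c(1, 2, 4)) {
    per <- 8L %/% bits
    pad <- (per - n %% per) %% per
    m <- matrix(c(idx, rep(0, pad)), nrow = per)
    as.raw(colSums(m * 2^(bits * (seq_len(per) - 1))))
  } else if (bits == 8) {
    as.raw(idx)
  } else if (bits == 16) {
    u16_to_raw(idx)
  } else if (bits == 32) {
    u32_to_raw(idx)
  } else stop("unsupported index width: ", bits)
}

unpack_indices <- function(r, bits, n) {
  if (bits == 0) return(rep(0, n))
  if (bits %in% c(1, 2, 4)) {
    per <- 8L %/% bits
    bytes <- as.numeric(r)
    out <- numeric(length(bytes) * per)
    for (k in seq_len(per)) {
      out[seq(k, by = per, length.out = length(bytes))] <-
        (bytes %/% 2^(bits * (k - 1))) %% 2^bits
    }
    out[seq_len(n)]
  } else if (bits == 8) {
    as.numeric(r)[seq_len(n)]
  } else if (bits == 16) {
    raw_to_u16(r)[seq_len(n)]
  } else if (bits == 32) {
    raw_to_u32(r)[seq_len(n)]
  } else stop("unsupported index width: ", bits)
}
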