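#' Sharding parameters
#'
#' Controls how integer labels are routed into shard files and minishards.
#' A label is preshifted right by `preshift_bits`, hashed, and the low
#' `minishard_bits` of the hash select the minishard while the next
#' `shard_bits` select the shard file.
#'
#' @param preshift_bits,minishard_bits,shard_bits non-negative bit counts;
#'   their sum must not exceed 64.
#' @param hash_kind `"identity"` or `"mixing"` (a splitmix-style 64-bit
#'   finalizer).
#' @param minishard_index_encoding,data_encoding `"raw"` or `"deflate"`.
#' @export
sharding_params <- function(preshift_bits = 0L, minishard_bits = 0L,
                            shard_bits = 0L, hash_kind = "identity",
                            minishard_index_encoding = "raw",
                            data_encoding = "raw") {
  stopifnot(preshift_bits >= 0, minishard_bits >= 0, shard_bits >= 0)
  if (preshift_bits + minishard_bits + shard_bits > 64) {
    stop("preshift_bits + minishard_bits + shard_bits must be <= 64")
  }
  if (!hash_kind %in% c("identity", "mixing")) stop("unknown hash_kind")
  stopifnot(minishard_index_encoding %in% c("raw", "deflate"),
            data_encoding %in% c("raw", "deflate"))
  structure(list(preshift_bits = as.integer(preshift_bits),
                 minishard_bits = as.integer(minishard_bits),
                 shard_bits = as.integer(shard_bits),
                 hash_kind = hash_kind,
                 minishard_index_encoding = minishard_index_encoding,
                 data_encoding = data_encoding),
            class = "sharding_params")
}

# ---- exact 64-bit helpers on doubles (16-bit limb arithmetic) -------------

limbs16 <- function(x) {
  c(x %% 65536, (x %/% 65536) %% 65536,
    (x %/% 2^32) %% 65536, (x %/% 2^48) %% 65536)
}

from_limbs16 <- function(l) l[1] + l[2] * 65536 + l[3] * 2^32 + l[4] * 2^48

xor64 <- function(a, b) {
  la <- limbs16(a); lb <- limbs16(b)
  from_limbs16(vapply(1:4, function(i) {
    bitwXor(as.integer(la[i]), as.integer(lb[i]))
  }, numeric(1)))
}

# (a * b) mod 2^64, exact via schoolbook 16-bit limbs
mul64 <- function(a, b) {
  la <- limbs16(a); lb <- limbs16(b)
  out <- numeric(4)
  for (i in 1:4) {
    for (j in 1:4) {
      if (i + j - 1 > 4) next
      out[i + j - 1] <- out[i + j - 1] + la[i] * lb[j]
    }
  }
  # propagate carries
  for (k in 1:3) {
    out[k + 1] <- out[k + 1] + out[k] %/% 65536
    out[k] <- out[k] %% 65536
  }
  out[4] <- out[4] %% 65536
  from_limbs16(out)
}

shr64 <- function(x, n) x %/% 2^n

# splitmix-style avalanche of a 64-bit value
mix64 <- function(x) {
  x <- xor64(x, shr64(x, 30))
  x <- mul64(x, 13787848793156543929)  # 0xBF58476D1CE4E5B9
  x <- xor64(x, shr64(x, 27))
  x <- mul64(x, 10723151780598845931)  # 0x94D049BB133111EB
  xor64(x, shr64(x, 31))
}

#' Route a label to its shard and minishard
#'
#' `h = hash(label >> preshift_bits)`; the minishard number is
#' `h mod 2^minishard_bits` and the shard number is
#' `(h >> minishard_bits) mod 2^shard_bits`.
#'
#' @param label non-negative integer label (< 2^53).
#' @param params [sharding_params()].
#' @return list with `shard` and `minishard` numbers.
#' @export
shard_location <- function(label, params) {
  h <- shr64(as.numeric(label), params$preshift_bits)
  if (params$hash_kind == "mixing") h <- mix64(h)
  minishard <- h %% 2^params$minishard_bits
  shard <- shr64(h, params$minishard_bits) %% 2^params$shard_bits
  list(shard = shard, minishard = minishard)
}

#' @rdname shard_location
#' @export
shard_filename <- function(shard_number, params) {
  width <- max(1L, ceiling(params$shard_bits / 4))
  sprintf("%0*x.shard", width, as.integer(shard_number))
}

maybe_deflate <- function(bytes, enc) {
  if (enc == "deflate") memCompress(bytes, "gzip") else bytes
}

maybe_inflate <- function(bytes, enc) {
  if (enc == "deflate") memDecompress(bytes, "gzip") else bytes
}

encode_minishard_index <- function(labels, offsets, sizes, enc) {
  # three delta-encoded u64 arrays: label deltas, gaps between consecutive
  # payload spans, sizes
  n <- length(labels)
  ldelta <- diff(c(0, labels))
  odelta <- offsets - c(0, offsets[-n] + sizes[-n])
  maybe_deflate(c(u64_to_raw(ldelta), u64_to_raw(odelta), u64_to_raw(sizes)), enc)
}

decode_minishard_index <- function(bytes, enc) {
  bytes <- maybe_inflate(bytes, enc)
  if (length(bytes) %% 24 != 0) stop("corrupt minishard index")
  n <- length(bytes) %/% 24
  ldelta <- raw_to_u64(bytes[seq_len(8 * n)])
  odelta <- raw_to_u64(bytes[8 * n + seq_len(8 * n)])
  sizes <- raw_to_u64(bytes[16 * n + seq_len(8 * n)])
  labels <- cumsum(ldelta)
  offsets <- numeric(n)
  prev_end <- 0
  for (i in seq_len(n)) {
    offsets[i] <- prev_end + odelta[i]
    prev_end <- offsets[i] + sizes[i]
  }
  list(labels = labels, offsets = offsets, sizes = sizes)
}

#' Build a shard file from label-keyed payloads
#'
#' Layout: a fixed-size shard index of `2^minishard_bits` (start, end)
#' u64 pairs, then the minishard indices, then the payloads. All offsets
#' are relative to the end of the shard index. Shards are write-once:
#' random read, not random write.
#'
#' @param entries named list mapping label (names coercible to numeric) to
#'   raw payloads; all labels must route to the same shard number.
#' @param params [sharding_params()].
#' @return raw vector: the shard file contents.
#' @export
build_shard <- function(entries, params) {
  nms <- as.numeric(names(entries))
  if (length(entries) > 0) {
    locs <- lapply(nms, shard_location, params = params)
    shards <- vapply(locs, `[[`, numeric(1), "shard")
    if (length(unique(shards)) > 1) {
      stop("entries route to multiple shard numbers: ",
           paste(unique(shards), collapse = ", "))
    }
    minis <- vapply(locs, `[[`, numeric(1), "minishard")
  } else {
    minis <- numeric(0)
  }
  n_mini <- 2^params$minishard_bits

  payloads <- lapply(entries, maybe_deflate, enc = params$data_encoding)

  # payloads laid out minishard by minishard, labels ascending
  mini_tables <- vector("list", n_mini)
  payload_blob <- list()
  offset <- 0
  for (m in seq_len(n_mini) - 1) {
    sel <- which(minis == m)
    if (length(sel) == 0) next  # mini_tables entry stays NULL
    sel <- sel[order(nms[sel])]
    labs <- nms[sel]
    if (anyDuplicated(labs)) stop("duplicate labels in shard entries")
    sizes <- vapply(payloads[sel], length, numeric(1))
    offs <- offset + cumsum(c(0, sizes[-length(sizes)]))
    mini_tables[[m + 1]] <- list(labels = labs, offsets = offs, sizes = sizes)
    payload_blob <- c(payload_blob, payloads[sel])
    offset <- offset + sum(sizes)
  }

  # Stored payload offsets are relative to the end of the shard index, so
  # they include the minishard-index region length. With deflated indices
  # that length depends on the offsets themselves; iterate to fixed point
  # (raw indices converge in one step, deflate in practice in two).
  index_len <- 0
  repeat {
    mini_blobs <- lapply(mini_tables, function(t) {
      if (is.null(t)) raw(0)
      else encode_minishard_index(t$labels, t$offsets + index_len, t$sizes,
                                  params$minishard_index_encoding)
    })
    mini_sizes <- vapply(mini_blobs, length, numeric(1))
    if (sum(mini_sizes) <= index_len) break
    index_len <- sum(mini_sizes)
  }
  pad <- raw(index_len - sum(mini_sizes))
  mini_starts <- cumsum(c(0, mini_sizes[-length(mini_sizes)]))

  shard_index <- numeric(2 * n_mini)
  for (m in seq_len(n_mini)) {
    shard_index[2 * m - 1] <- mini_starts[m]
    shard_index[2 * m] <- mini_starts[m] + mini_sizes[m]
  }
  body <- c(do.call(c, c(list(raw(0)), unname(mini_blobs))), pad,
            do.call(c, c(list(raw(0)), unname(payload_blob))))
  unname(c(u64_to_raw(shard_index), body))
}

#' Random-read a label's payload from a shard
#'
#' Performs the three-step lookup: (I) the fixed-size shard index locates
#' the minishard index, (II) the minishard index locates the payload span,
#' (III) the payload bytes are read. `reader` is called once per step with
#' 0-based half-open byte offsets, so a cold lookup issues exactly three
#' range reads.
#'
#' @param reader function(start, end) returning the raw bytes of that
#'   half-open range of the shard file; see [raw_range_reader()].
#' @param label label to look up.
#' @param params [sharding_params()].
#' @return the payload raw vector, or `NULL` when the label is absent.
#' @export
read_shard_entry <- function(reader, label, params) {
  loc <- shard_location(label, params)
  n_mini <- 2^params$minishard_bits
  index_bytes <- 16 * n_mini
  pair <- reader(loc$minishard * 16, loc$minishard * 16 + 16)
  se <- raw_to_u64(pair)
  if (se[2] < se[1]) stop("corrupt shard index")
  if (se[1] == se[2]) return(NULL)  # empty minishard
  mini_raw <- reader(index_bytes + se[1], index_bytes + se[2])
  idx <- decode_minishard_index(mini_raw, params$minishard_index_encoding)
  if (any(diff(idx$labels) <= 0)) stop("corrupt minishard index: labels not increasing")
  at <- match(as.numeric(label), idx$labels)
  if (is.na(at)) return(NULL)
  payload <- reader(index_bytes + idx$offsets[at],
                    index_bytes + idx$offsets[at] + idx$sizes[at])
  if (length(payload) != idx$sizes[at]) {
    stop("corrupt shard: payload span out of file bounds")
  }
  maybe_inflate(payload, params$data_encoding)
}

#' Byte-range readers for shard lookups
#'
#' @param bytes raw vector (whole shard in memory).
#' @return function(start, end) returning that half-open range.
#' @export
raw_range_reader <- function(bytes) {
  force(bytes)
  function(start, end) {
    if (start < 0 || end > length(bytes)) stop("range read out of file bounds")
    if (end == start) return(raw(0))
    bytes[(start + 1):end]
  }
}

#' @rdname raw_range_reader
#' @param path shard file path.
#' @export
file_range_reader <- function(path) {
  force(path)
  size <- file.info(path)$size
  function(start, end) {
    if (start < 0 || end > size) stop("range read out of file bounds")
    if (end == start) return(raw(0))
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, start)
    readBin(con, "raw", n = end - start)
  }
}
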