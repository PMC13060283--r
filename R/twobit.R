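# Minimal 2bit reader: header + sequence index + per-record dna size, which
# is all a translator needs to synthesize genome.txt for an assembly hub.
# Packed bases, N blocks and mask blocks are never decoded on read.  The
# writer exists so the reader (and everything downstream) is testable
# without downloading a real assembly.

TWOBIT_SIGNATURE <- 0x1A412743

# read one unsigned 32-bit integer from raw at 1-based offset `at`
ru32 <- function(data, at, endian) {
  if (at + 3L > length(data)) {
    qh_format_error(sprintf("2bit data truncated at byte %d", at))
  }
  v <- readBin(data[at:(at + 3L)], "integer", size = 4L, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

ru8 <- function(data, at) {
  if (at > length(data)) {
    qh_format_error(sprintf("2bit data truncated at byte %d", at))
  }
  as.integer(data[[at]])
}

#' Read the header and sequence index of a 2bit file
#'
#' Validates the 4-byte signature (`0x1A412743`, either byte order),
#' requires version 0, then reads the sequence index of
#' `(name, record offset)` pairs.  With `fetch_record_sizes`, also reads the
#' 4-byte `dnaSize` field at the head of each sequence record -- never any
#' packed bases or block lists.
#'
#' @param data Raw vector containing at least the header and index (and the
#'   record heads when `fetch_record_sizes`).
#' @param fetch_record_sizes Read per-sequence lengths? (`TRUE` by default;
#'   `FALSE` gives an index with `dna_size = NA`.)
#' @return A `qh_twobit_index`: list with `sequence_count`, `byte_order`
#'   (`"big"` or `"little"`), and `records`, a data frame with columns
#'   `name`, `offset`, `dna_size`.
#' @export
read_twobit_index <- function(data, fetch_record_sizes = TRUE) {
  if (!is.raw(data)) qh_value_error("data must be a raw vector")
  if (length(data) < 16L) {
    qh_format_error("2bit data shorter than the 16-byte header")
  }
  sig_be <- ru32(data, 1L, "big")
  endian <- if (sig_be == TWOBIT_SIGNATURE) {
    "big"
  } else if (ru32(data, 1L, "little") == TWOBIT_SIGNATURE) {
    "little"
  } else {
    qh_format_error(sprintf("bad 2bit signature 0x%08X", sig_be))
  }
  version <- ru32(data, 5L, endian)
  if (version != 0) {
    qh_format_error(sprintf(
      "unsupported 2bit version %d (only version 0, 32-bit offsets)", version))
  }
  count <- ru32(data, 9L, endian)

  nm <- character(count)
  off <- numeric(count)
  pos <- 17L
  for (i in seq_len(count)) {
    nsize <- ru8(data, pos)
    if (pos + nsize + 4L - 1L > length(data)) {
      qh_format_error(sprintf("2bit index truncated at byte %d", pos))
    }
    nm[[i]] <- rawToChar(data[(pos + 1L):(pos + nsize)])
    off[[i]] <- ru32(data, pos + nsize + 1L, endian)
    pos <- pos + 1L + nsize + 4L
  }
  if (anyDuplicated(nm)) qh_format_error("duplicate sequence names in 2bit index")

  sizes <- rep(NA_real_, count)
  if (fetch_record_sizes) {
    for (i in seq_len(count)) sizes[[i]] <- ru32(data, off[[i]] + 1L, endian)
  }

  structure(
    list(sequence_count = as.integer(count), byte_order = endian,
         records = data.frame(name = nm, offset = off, dna_size = sizes)),
    class = "qh_twobit_index"
  )
}

#' @export
print.qh_twobit_index <- function(x, ...) {
  cat(sprintf("<2bit index: %d sequence(s), %s-endian>\n",
              x$sequence_count, x$byte_order))
  if (x$sequence_count) print(utils::head(x$records, 10))
  invisible(x)
}

#' Write a miniature 2bit file
#'
#' Emits a valid version-0 file with a big-endian signature: bases packed 2
#' bits each (T=0, C=1, A=2, G=3, first base in the high bits), N runs
#' recorded as nBlocks (and packed as T), and empty maskBlock lists.
#' `read_twobit_index()` on the output recovers names, order and lengths
#' exactly; standard tools can extract the sequences.
#'
#' @param sequences Named character vector of DNA strings over
#'   `A C G T N` (either case); names are the sequence names.
#' @return Raw vector with the file bytes.
#' @examples
#' idx <- read_twobit_index(write_twobit(c(chr1 = "ACGTACGTAC", chr2 = "NNACG")))
#' idx$records
#' @export
write_twobit <- function(sequences) {
  nm <- names(sequences)
  if (length(sequences) && (is.null(nm) || any(!nzchar(nm)))) {
    qh_value_error("sequences must have non-empty names")
  }
  if (anyDuplicated(nm)) qh_value_error("sequence names must be unique")

  base_code <- c(T = 0L, C = 1L, A = 2L, G = 3L, N = 0L)

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  w32 <- function(x) {
    x <- as.numeric(x)
    if (x >= 2^31) x <- x - 2^32        # reinterpret as signed for writeBin
    writeBin(as.integer(x), con, size = 4L, endian = "big")
  }

  # record payloads and their sizes must be known before offsets are final
  payloads <- lapply(seq_along(sequences), function(i) {
    seq <- toupper(sequences[[i]])
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    codes <- base_code[chars]
    if (anyNA(codes)) {
      qh_value_error(sprintf(
        "sequence '%s' contains characters outside {A,C,G,T,N}", nm[[i]]))
    }
    n <- length(codes)
    is_n <- chars == "N"
    r <- rle(is_n)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths           # 0-based
    n_starts <- starts[r$values]
    n_sizes <- r$lengths[r$values]

    pad <- (4L - n %% 4L) %% 4L
    codes <- c(unname(codes), rep(0L, pad))
    dim(codes) <- c(4L, length(codes) %/% 4L)
    packed <- as.raw(codes[1, ] * 64L + codes[2, ] * 16L +
                     codes[3, ] * 4L + codes[4, ])
    list(dna_size = n, n_starts = n_starts, n_sizes = n_sizes,
         packed = packed)
  })

  header_size <- 16L
  index_size <- sum(vapply(nm, function(x) 1L + nchar(x, "bytes") + 4L,
                           integer(1)), 0L)
  rec_sizes <- vapply(payloads, function(p) {
    4L + 4L + 8L * length(p$n_starts) + 4L + 4L + length(p$packed)
  }, numeric(1))
  offsets <- header_size + index_size + c(0, cumsum(rec_sizes))[seq_along(payloads)]

  w32(TWOBIT_SIGNATURE)
  w32(0)                                 # version
  w32(length(sequences))
  w32(0)                                 # reserved
  for (i in seq_along(sequences)) {
    writeBin(as.integer(nchar(nm[[i]], "bytes")), con, size = 1L)
    writeBin(charToRaw(nm[[i]]), con)
    w32(offsets[[i]])
  }
  for (p in payloads) {
    w32(p$dna_size)
    w32(length(p$n_starts))
    for (s in p$n_starts) w32(s)
    for (s in p$n_sizes) w32(s)
    w32(0)                               # maskBlockCount
    w32(0)                               # reserved
    writeBin(p$packed, con)
  }
  rawConnectionValue(con)
}

#' Chromosome table from a 2bit index
#'
#' @param index A `qh_twobit_index` with `dna_size` populated.
#' @return Data frame with columns `seq_name`, `length` in index order,
#'   ready for [serialize_genome_table()].
#' @export
genome_table_from_twobit <- function(index) {
  if (anyNA(index$records$dna_size)) {
    qh_value_error("index has no record sizes; reread with fetch_record_sizes")
  }
  data.frame(seq_name = index$records$name,
             length = index$records$dna_size)
}

# Read a 2bit index over a ranged transport without downloading the file:
# header, then a bounded index region, then 4 bytes per record head.
# `transport(url, range = c(offset0, length))` with a 0-based offset.
twobit_index_via_transport <- function(url, transport) {
  head <- transport(url, range = c(0, 16))
  if (is.null(head)) {
    qh_stop(sprintf("cannot fetch 2bit header from %s", url),
            "quickhub_upstream_error")
  }
  if (length(head) < 16L) {
    qh_format_error("2bit data shorter than the 16-byte header")
  }
  endian <- if (ru32(head, 1L, "big") == TWOBIT_SIGNATURE) {
    "big"
  } else if (ru32(head, 1L, "little") == TWOBIT_SIGNATURE) {
    "little"
  } else {
    qh_format_error(sprintf("bad 2bit signature 0x%08X", ru32(head, 1L, "big")))
  }
  if (ru32(head, 5L, endian) != 0) {
    qh_format_error("unsupported 2bit version")
  }
  count <- ru32(head, 9L, endian)
  if (count == 0L) {
    return(read_twobit_index(head, fetch_record_sizes = FALSE))
  }
  # names are at most 255 bytes: 16 + count * (1 + 255 + 4) bounds the index
  idx_bytes <- transport(url, range = c(0, 16 + count * 260))
  idx <- read_twobit_index(idx_bytes, fetch_record_sizes = FALSE)
  sizes <- vapply(idx$records$offset, function(off) {
    chunk <- transport(url, range = c(off, 4))
    if (is.null(chunk) || length(chunk) < 4L) {
      qh_format_error(sprintf("cannot fetch 2bit record at offset %.0f", off))
    }
    ru32(chunk, 1L, idx$byte_order)
  }, numeric(1))
  idx$records$dna_size <- sizes
  idx
}
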