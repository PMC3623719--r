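#' Read a Standard Flowgram File (SFF)
#'
#' Parses the binary SFF v1.0 layout (magic ".sff", big-endian integers,
#' flow-values stored as unsigned 16-bit hundredths). Any index section is
#' ignored. Clip points are kept verbatim in the SFF convention: 1-based
#' inclusive, 0 meaning unset.
#'
#' @param path Path to an SFF file.
#' @return A list with `order` (a [flow_order] built from the header flow
#'   characters), `key` (key sequence string), `n_flows`, and `reads`: a list
#'   of per-read records with `name`, `values` (numeric flow-values, exactly
#'   stored hundredths / 100), `bases`, `qualities` (integer Phred),
#'   `flow_of_base` (0-based flow index per base), `clip_qual` and
#'   `clip_adapter` (length-2 integer vectors, SFF convention).
#' @export
read_sff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2,
                               signed = FALSE, endian = "big")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4,
                               endian = "big")
  if (length(raw) < 31L || u32(0) != 0x2E736666L)
    stop("not an SFF file (bad magic): ", path)
  if (u32(4) != 1L) stop("unsupported SFF version in ", path)
  n_reads <- u32(20)                 # magic, version, index offset/length
  header_length <- u16(24)
  key_length <- u16(26)
  n_flows <- u16(28)
  if (as.integer(raw[31]) != 1L) stop("unsupported flowgram format code")
  flow_chars <- rawToChar(raw[31 + seq_len(n_flows)])
  key <- rawToChar(raw[31 + n_flows + seq_len(key_length)])
  off <- header_length  # header is padded to a multiple of 8
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    if (off + 16 > length(raw))
      stop("truncated SFF record at read index ", i)
    rh_len <- u16(off)
    name_len <- u16(off + 2)
    n_bases <- u32(off + 4)
    clips <- c(u16(off + 8), u16(off + 10), u16(off + 12), u16(off + 14))
    name <- rawToChar(raw[off + 16 + seq_len(name_len)])
    doff <- off + rh_len
    data_len <- 2L * n_flows + 3L * n_bases
    if (doff + data_len > length(raw))
      stop("truncated SFF record at read index ", i)
    values <- readBin(raw[doff + seq_len(2L * n_flows)], "integer",
                      n = n_flows, size = 2, signed = FALSE,
                      endian = "big") / 100
    fib <- as.integer(raw[doff + 2L * n_flows + seq_len(n_bases)])
    bases <- rawToChar(raw[doff + 2L * n_flows + n_bases + seq_len(n_bases)])
    quals <- as.integer(raw[doff + 2L * n_flows + 2L * n_bases +
                              seq_len(n_bases)])
    reads[[i]] <- list(name = name, values = values, bases = bases,
                       qualities = quals,
                       flow_of_base = cumsum(fib) - 1L,
                       clip_qual = clips[1:2], clip_adapter = clips[3:4])
    off <- doff + 8L * ((data_len + 7L) %/% 8L)
  }
  list(order = order_from_flow_chars(flow_chars), key = key,
       n_flows = n_flows, reads = reads)
}

# The SFF header stores the full per-flow nucleotide string; the flow
# order's fundamental period (needed for position-in-cycle arithmetic) is
# the smallest p whose repetition reproduces the string.
order_from_flow_chars <- function(flow_chars) {
  chars <- strsplit(flow_chars, "")[[1]]
  n <- length(chars)
  for (p in seq_len(n)) {
    if (identical(chars, rep(chars[seq_len(p)], length.out = n)))
      return(flow_order(chars[seq_len(p)]))
  }
  flow_order(chars)
}

#' Write reads to a Standard Flowgram File (SFF)
#'
#' Inverse of [read_sff()]: values are stored as unsigned 16-bit hundredths
#' (so each value must lie in [0, 655.35] on the hundredth grid), clip points
#' in the SFF 1-based-inclusive/0-unset convention. No index block is
#' written.
#'
#' @param reads List of read records as produced by [read_sff()] (fields
#'   `name`, `values`, `bases`, `qualities`, `flow_of_base`, `clip_qual`,
#'   `clip_adapter`).
#' @param order A [flow_order]; every read must have `length(order
#'   $nucleotides) * cycles` values equal to the common header flow count.
#' @param key Key sequence (4 bases, default "TACG").
#' @param path Output path.
#' @param n_flows Number of flows per read (default: from the first read).
#' @return `path`, invisibly.
#' @export
write_sff <- function(reads, order, key = "TACG", path,
                      n_flows = if (length(reads)) length(reads[[1]]$values)
                                else order$period) {
  flow_chars <- paste(rep(order$nucleotides,
                          length.out = n_flows), collapse = "")
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "big")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  pad8 <- function(n) if (n %% 8L)
    writeBin(raw(8L - n %% 8L), con)
  w32(0x2E736666L); w32(1L)
  writeBin(raw(8), con)              # index offset (none)
  w32(0L)                            # index length
  w32(length(reads))
  hlen_raw <- 31L + n_flows + nchar(key)
  hlen <- 8L * ((hlen_raw + 7L) %/% 8L)
  w16(hlen); w16(nchar(key)); w16(n_flows)
  writeBin(as.raw(1L), con)          # flowgram format code
  writeBin(charToRaw(flow_chars), con)
  writeBin(charToRaw(key), con)
  pad8(hlen_raw)
  for (rd in reads) {
    nb <- nchar(rd$bases)
    stopifnot(length(rd$values) == n_flows,
              length(rd$flow_of_base) == nb,
              length(rd$qualities) == nb)
    hundredths <- as.integer(round(rd$values * 100))
    if (any(hundredths < 0 | hundredths > 65535L))
      stop("flow-value outside the representable range [0, 655.35] in read ",
           rd$name)
    rh_raw <- 16L + nchar(rd$name)
    rh <- 8L * ((rh_raw + 7L) %/% 8L)
    w16(rh); w16(nchar(rd$name)); w32(nb)
    clip_qual <- if (is.null(rd$clip_qual)) c(0L, 0L) else rd$clip_qual
    clip_adapter <- if (is.null(rd$clip_adapter)) c(0L, 0L) else rd$clip_adapter
    w16(clip_qual[1]); w16(clip_qual[2])
    w16(clip_adapter[1]); w16(clip_adapter[2])
    writeBin(charToRaw(rd$name), con)
    pad8(rh_raw)
    w16(hundredths)
    fib <- diff(c(-1L, as.integer(rd$flow_of_base)))
    if (any(fib < 0 | fib > 255L))
      stop("flow_of_base must be non-decreasing with steps <= 255 in read ",
           rd$name)
    writeBin(as.raw(fib), con)
    writeBin(charToRaw(rd$bases), con)
    writeBin(as.raw(rd$qualities), con)
    pad8(2L * n_flows + 3L * nb)
  }
  invisible(path)
}
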