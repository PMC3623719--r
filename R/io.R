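#' Read alignments from a SAM text file
#'
#' Parses the 11 mandatory SAM columns. Secondary/supplementary alignments
#' (flag bits 0x100/0x800) and unmapped records (0x4) are excluded from the
#' returned table but counted, so parsed + unmapped + skipped reconcile to
#' the file total. Records whose CIGAR-implied read length disagrees with
#' the stored sequence are skipped with a count.
#'
#' @param path Path to a SAM file (with or without header lines).
#' @return A list with `records` (a `data.table` with columns qname, flag,
#'   rname, pos, mapq, cigar, seq, qual, strand, ref_width) and counts
#'   `n_total`, `n_unmapped`, `n_skipped`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  n_total <- length(lines)
  if (n_total == 0L)
    return(list(records = empty_sam_table(), n_total = 0L,
                n_unmapped = 0L, n_skipped = 0L))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  dt <- data.table::data.table(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    seq = get(10), qual = get(11))
  unmapped <- bitwAnd(dt$flag, 4L) != 0L | dt$cigar == "*"
  secondary <- bitwAnd(dt$flag, bitwOr(256L, 2048L)) != 0L
  dt <- dt[!unmapped & !secondary]
  ops <- cigar_ops(dt$cigar)
  read_len <- vapply(ops, function(o)
    sum(o$len[o$op %in% c("M", "I", "S", "=", "X")]), integer(1))
  bad <- read_len != nchar(dt$seq)
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(n_skipped, " SAM record(s) skipped: CIGAR/sequence length mismatch")
    dt <- dt[!bad]
    ops <- ops[!bad]
  }
  dt[, strand := ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]
  dt[, ref_width := vapply(ops, function(o)
    sum(o$len[o$op %in% c("M", "D", "N", "=", "X")]), integer(1))]
  list(records = dt, n_total = n_total,
       n_unmapped = sum(unmapped), n_skipped = n_skipped)
}

empty_sam_table <- function() {
  data.table::data.table(qname = character(0), flag = integer(0),
                         rname = character(0), pos = integer(0),
                         mapq = integer(0), cigar = character(0),
                         seq = character(0), qual = character(0),
                         strand = character(0), ref_width = integer(0))
}

#' Split CIGAR strings into operation lists
#' @param cigar Character vector of CIGAR strings.
#' @return A list, one element per input, each a list with integer `len` and
#'   character `op` vectors.
#' @export
cigar_ops <- function(cigar) {
  lapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(m) {
    list(len = as.integer(sub("[A-Z=]$", "", m)),
         op = sub("^\\d+", "", m))
  })
}

#' Write alignments to a SAM text file
#' @param records A data.frame with columns qname, flag, rname, pos, mapq,
#'   cigar, seq, qual.
#' @param ref_names,ref_lengths Reference names and lengths for the header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref_names, ref_lengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_names, ref_lengths))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$mapq, records$cigar, records$seq, records$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a reference genome from FASTA
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences, one per contig.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ (Sanger Phred+33)
#' @param names,seqs Character vectors of read names and sequences.
#' @param quals List (or vector) of integer Phred scores per read.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(names, seqs, quals, path) {
  qstr <- vapply(quals, function(q)
    rawToChar(as.raw(pmin(q, 93L) + 33L)), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Construct a mask set of reference intervals
#'
#' Intervals are half-open `[start, end)` with 1-based starts; overlapping
#' or book-ended intervals are merged per contig.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors (1-based start, half-open end).
#' @return A `mask_set`: `data.table` with columns contig, start, end,
#'   sorted and non-overlapping.
#' @export
mask_set <- function(contig = character(0), start = integer(0),
                     end = integer(0)) {
  dt <- data.table::data.table(contig = as.character(contig),
                               start = as.integer(start),
                               end = as.integer(end))
  dt <- dt[end > start]
  if (nrow(dt)) {
    merged <- dt[, {
      ir <- IRanges::reduce(IRanges::IRanges(start, end - 1L))
      list(start = IRanges::start(ir), end = IRanges::end(ir) + 1L)
    }, by = contig]
    dt <- merged[order(contig, start)]
  }
  structure(dt, class = c("mask_set", class(dt)))
}

#' Positions covered by a mask on one contig
#' @param mask A `mask_set`.
#' @param contig Contig name.
#' @param len Contig length.
#' @return Logical vector of length `len`; TRUE where masked.
#' @export
mask_bits <- function(mask, contig, len) {
  bits <- logical(len)
  m <- mask[mask$contig == contig]
  for (i in seq_len(nrow(m)))
    bits[m$start[i]:(m$end[i] - 1L)] <- TRUE
  bits
}

#' Import / export mask sets as BED
#'
#' BED uses 0-based half-open coordinates; conversion to the internal
#' 1-based half-open convention happens here and only here.
#' @param path BED path.
#' @param mask A `mask_set`.
#' @return `read_bed_mask`: a `mask_set`; `write_bed_mask`: `path`.
#' @export
read_bed_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  mask_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr), GenomicRanges::end(gr) + 1L)
}

#' @rdname read_bed_mask
#' @export
write_bed_mask <- function(mask, path) {
  gr <- GenomicRanges::GRanges(
    mask$contig, IRanges::IRanges(mask$start, mask$end - 1L))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Run metadata for one sequencing run
#'
#' @param run_id Run label.
#' @param chip Chip density, one of "314", "316".
#' @param kit Template kit, one of "OT100" (100 bp OneTouch), "M200"
#'   (200 bp manual), "OT200" (200 bp OneTouch).
#' @param species_label Template species label.
#' @param machine Machine label.
#' @return A `run_metadata` list.
#' @export
run_metadata <- function(run_id, chip = "314", kit = "OT100",
                         species_label = "B.amyloliquefaciens",
                         machine = "a") {
  chip <- match.arg(as.character(chip), c("314", "316"))
  kit <- match.arg(kit, c("OT100", "M200", "OT200"))
  structure(list(run_id = run_id, chip = chip, kit = kit,
                 species_label = species_label, machine = machine),
            class = "run_metadata")
}

#' Nominal read length of a template kit, in bases
#' @param kit Kit label ("OT100", "M200", "OT200").
#' @return Integer nominal length (100 or 200).
#' @export
kit_nominal_length <- function(kit) {
  switch(match.arg(kit, c("OT100", "M200", "OT200")),
         OT100 = 100L, M200 = 200L, OT200 = 200L)
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}
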