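#' Run-length encode a nucleotide sequence
#'
#' Collapses homopolymers to single (base, length) units. Run-length
#' encoding is the natural coordinate system for flowgram data: each RLE run
#' is consumed by exactly one flow.
#'
#' @param seq A single character string over A/C/G/T (case-insensitive).
#' @return An object of class `rle_seq`: list with `bases` (character vector,
#'   no two adjacent equal) and `lengths` (positive integers).
#' @export
rle_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L)
    return(structure(list(bases = character(0), lengths = integer(0)),
                     class = "rle_seq"))
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("sequence contains non-ACGT characters; mask or remove them first")
  r <- rle(chars)
  structure(list(bases = r$values, lengths = as.integer(r$lengths)),
            class = "rle_seq")
}

#' Decode a run-length encoded sequence back to a string
#' @param x An `rle_seq`.
#' @return A character string.
#' @export
rle_decode <- function(x) {
  stopifnot(inherits(x, "rle_seq"))
  paste(rep(x$bases, x$lengths), collapse = "")
}

#' @export
print.rle_seq <- function(x, ...) {
  cat("<rle_seq>", length(x$bases), "runs,", sum(x$lengths), "bases\n")
  invisible(x)
}

#' Base-call a flowgram by rounding flow-values
#'
#' Each flow-value is rounded half-up to the called homopolymer length
#' (a value below 0.50 is a "negative flow" calling zero bases; exactly 0.50
#' calls one base). The called read is the concatenation of
#' `hp_calls[i]` copies of the nucleotide dispensed at flow `i`.
#'
#' @param values Numeric vector of non-negative flow-values (quantised to
#'   hundredths, as stored in SFF).
#' @param order A `flow_order`.
#' @param qualities Optional per-base Phred scores to attach.
#' @return A `called_read`: list with `bases` (string), `hp_calls`
#'   (per-flow called lengths), `flow_of_base` (0-based flow index of each
#'   base), `values`, `order` and optional `qualities`.
#' @export
call_bases <- function(values, order, qualities = NULL) {
  if (any(values < 0)) stop("flow-values must be non-negative")
  # values sit on the hundredth grid, so a small epsilon makes the
  # round-half-up boundary at .50 immune to binary representation error
  hp <- as.integer(floor(values + 0.5 + 1e-6))
  n <- length(values)
  flow_of_base <- rep.int(seq_len(n) - 1L, hp)
  bases <- paste(rep.int(flow_base(seq_len(n) - 1L, order), hp), collapse = "")
  structure(list(bases = bases, hp_calls = hp, flow_of_base = flow_of_base,
                 values = values, order = order, qualities = qualities),
            class = "called_read")
}

#' @export
print.called_read <- function(x, ...) {
  cat("<called_read>", nchar(x$bases), "bases over", length(x$hp_calls),
      "flows\n")
  invisible(x)
}

#' Ideal flowgram of a sequence under a flow order
#'
#' Walks the flows in dispensation order; each flow consumes the current RLE
#' run if and only if the nucleotides match, emitting the run length,
#' otherwise 0. This is the noise-free truth channel: base-calling the
#' returned integer vector reproduces `seq` exactly (when all runs fit in
#' `n_flows`).
#'
#' @param seq Character string over A/C/G/T.
#' @param order A `flow_order`.
#' @param n_flows Number of flows available; if the sequence does not fit,
#'   the flowgram is truncated and the unsynthesised remainder reported.
#' @return Integer vector of per-flow true homopolymer lengths, with
#'   attribute `remainder` (the unsynthesised suffix of `seq`, `""` if none)
#'   and `flow_of_run` (0-based flow index of each consumed RLE run).
#' @export
expected_flowgram <- function(seq, order, n_flows = NULL) {
  r <- rle_encode(seq)
  P <- order$period
  d <- flow_distance_table(order)
  nruns <- length(r$bases)
  flow_of_run <- integer(nruns)
  f <- 0L  # candidate flow for the next run
  for (i in seq_len(nruns)) {
    f <- f + d[(f %% P) + 1L, r$bases[i]]
    flow_of_run[i] <- f
    f <- f + 1L
  }
  needed <- if (nruns) flow_of_run[nruns] + 1L else 0L
  if (is.null(n_flows)) n_flows <- needed
  n_flows <- as.integer(n_flows)
  keep <- flow_of_run < n_flows
  h <- integer(n_flows)
  h[flow_of_run[keep] + 1L] <- r$lengths[keep]
  remainder <- if (all(keep)) "" else
    paste(rep(r$bases[!keep], r$lengths[!keep]), collapse = "")
  attr(h, "remainder") <- remainder
  attr(h, "flow_of_run") <- flow_of_run[keep]
  h
}
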