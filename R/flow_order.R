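#' Flow order: the periodic nucleotide dispensation sequence
#'
#' A flow order describes the fixed, periodic sequence in which nucleotides
#' are flowed over the chip. Each flow dispenses one nucleotide; zero or more
#' template bases incorporate, yielding a flow-value roughly proportional to
#' the homopolymer length. Flow indices and cycles are 0-based throughout;
#' base positions are 1-based.
#'
#' @param nucleotides Character vector of single bases (A/C/G/T), one per
#'   flow position within a cycle. All four bases must occur at least once,
#'   otherwise some sequences could never be synthesised.
#' @return An object of class `flow_order` with elements `nucleotides`
#'   (character vector) and `period` (its length).
#' @export
flow_order <- function(nucleotides) {
  if (length(nucleotides) == 1L && nchar(nucleotides) > 1L)
    nucleotides <- strsplit(nucleotides, "")[[1]]
  nucleotides <- toupper(as.character(nucleotides))
  if (length(nucleotides) < 1L)
    stop("flow order must contain at least one flow")
  if (!all(nucleotides %in% c("A", "C", "G", "T")))
    stop("flow order may only contain A/C/G/T")
  if (!all(c("A", "C", "G", "T") %in% nucleotides))
    stop("flow order must dispense all four nucleotides at least once per period")
  structure(list(nucleotides = nucleotides, period = length(nucleotides)),
            class = "flow_order")
}

#' @export
print.flow_order <- function(x, ...) {
  cat("<flow_order> period", x$period, ":",
      paste(x$nucleotides, collapse = ""), "\n")
  invisible(x)
}

#' The Samba flow order (period 32)
#'
#' The 32-flow dispensation pattern used by the Ion Torrent PGM, which
#' repeats some nucleotides within a period shorter than four to improve
#' synchronicity of clonal templates.
#' @return A `flow_order` of period 32.
#' @export
samba_order <- function() flow_order("TACGTACGTCTGAGCATCGATCGATGTACAGC")

#' The simple 4-flow TACG repeat order
#' @return A `flow_order` of period 4.
#' @export
tacg_order <- function() flow_order("TACG")

#' Position-in-cycle and cycle number of a flow index
#'
#' `pic_of()` returns the position within the dispensation cycle
#' (flow index modulo the period); `cycle_of()` returns the 0-based cycle
#' number (integer division by the period).
#'
#' @param flow_index Non-negative integer flow indices (0-based).
#' @param order A `flow_order`.
#' @return Integer vector of the same length as `flow_index`.
#' @export
pic_of <- function(flow_index, order) {
  flow_index <- check_flow_index(flow_index)
  as.integer(flow_index %% order$period)
}

#' @rdname pic_of
#' @export
cycle_of <- function(flow_index, order) {
  flow_index <- check_flow_index(flow_index)
  as.integer(flow_index %/% order$period)
}

check_flow_index <- function(flow_index) {
  if (any(flow_index < 0)) stop("flow indices are 0-based and non-negative")
  flow_index
}

#' Nucleotide dispensed at given 0-based flow indices
#' @inheritParams pic_of
#' @return Character vector of bases.
#' @export
flow_base <- function(flow_index, order) {
  order$nucleotides[pic_of(flow_index, order) + 1L]
}

# distance table: d[p, b] = smallest k >= 0 such that the flow at
# position-in-cycle (p - 1 + k) %% period dispenses base b.
flow_distance_table <- function(order) {
  P <- order$period
  d <- matrix(NA_integer_, nrow = P, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in seq_len(P)) {
    idx <- ((p - 1L) + 0:(P - 1L)) %% P + 1L
    for (b in c("A", "C", "G", "T"))
      d[p, b] <- which(order$nucleotides[idx] == b)[1] - 1L
  }
  d
}
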