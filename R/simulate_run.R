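#' Simulate a full flowgram sequencing run with ground truth
#'
#' Generates reads from a reference genome under the generative flow-value
#' model: fragment starts uniform over valid positions, strand Bernoulli(0.5),
#' planted HFI sites applied as single-base template edits with their
#' penetrance (respecting strand restriction), per-flow values Gaussian with
#' mean and log-variance from the configured linear predictors (truncated at
#' zero, quantised to hundredths), zero-length homopolymer flows from the
#' truncated-Gaussian zero-flow model, and substitutions injected per aligned
#' base with the 0.51 low-confidence flow-value signature on 1-mer flows.
#' Key flows are synthesised noise-free (the instrument normalises to the
#' key). The returned object carries the reads (SFF-ready records), a truth
#' SAM with correct CIGARs against the reference, and a per-flow truth
#' ledger.
#'
#' @param genome Reference sequence string (single contig).
#' @param hfi_sites Optional planted sites from [plant_hfi_sites()].
#' @param cfg A [sim_config].
#' @param contig_name Reference name used in the SAM.
#' @return An object of class `flow_sim`: list with `sff` (list mirroring
#'   [read_sff()] output), `sam` (alignment `data.table` as written by
#'   [write_sam()]), `ledger` (`data.table`: name, flow, h_true, h_called,
#'   sub, y — one row per alignment-visible flow), `reads_truth`
#'   (`data.table`: name, start, strand, n_edits), `genome`, `hfi_sites`,
#'   `config`, and counts `n_unmapped`, `n_mu_truncated`.
#' @export
simulate_run <- function(genome, hfi_sites = NULL, cfg,
                         contig_name = "sim_contig") {
  stopifnot(inherits(cfg, "sim_config"))
  order <- cfg$flow_order
  P <- order$period
  dtab <- flow_distance_table(order)
  bmap <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n_flows <- cfg$n_flows
  L <- nchar(genome)
  frag_len <- min(L, as.integer(ceiling(cfg$read_len_bases * 1.2)))
  if (L < frag_len) stop("genome shorter than one fragment")
  gchars <- strsplit(toupper(genome), "")[[1]]
  kchars <- strsplit(cfg$key, "")[[1]]
  md <- cfg$metadata
  flow_idx <- 0:(n_flows - 1L)
  pic <- flow_idx %% P
  cycle <- flow_idx %/% P
  fbase <- order$nucleotides[pic + 1L]
  n <- cfg$n_reads

  # substream: fragment placement
  set.seed(substream_seed(cfg$seed, "starts"))
  starts <- sample.int(L - frag_len + 1L, n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  # substream: which planted sites fire in which read
  edits <- vector("list", n)
  if (!is.null(hfi_sites) && nrow(hfi_sites)) {
    set.seed(substream_seed(cfg$seed, "hfi_pen"))
    for (i in seq_len(n)) {
      inr <- hfi_sites[hfi_sites$pos >= starts[i] &
                         hfi_sites$pos < starts[i] + frag_len - 1L, ]
      if (nrow(inr)) {
        ok <- (is.na(inr$strand) | inr$strand == strands[i]) &
          stats::runif(nrow(inr)) < inr$penetrance
        edits[[i]] <- inr[ok, ]
      }
    }
  }

  set.seed(substream_seed(cfg$seed, "flows"))
  names_v <- sprintf("%s_r%06d", md$run_id, seq_len(n))
  sff_reads <- vector("list", n)
  sam_rows <- vector("list", n)
  led_rows <- vector("list", n)
  n_unmapped <- 0L
  n_mu_trunc <- 0L

  for (i in seq_len(n)) {
    w <- gchars[starts[i]:(starts[i] + frag_len - 1L)]
    extra <- integer(frag_len)
    ed <- edits[[i]]
    if (!is.null(ed) && nrow(ed)) {
      for (k in order(-ed$pos)) {       # right-to-left keeps coordinates valid
        j <- ed$pos[k] - starts[i] + 1L
        if (ed$type[k] == "ins") {
          w <- append(w, w[j], after = j)
          extra <- append(extra, -1L, after = j)
        } else {
          b <- w[j]
          w <- w[-j]; extra <- extra[-j]
          tj <- if (j <= length(w) && w[j] == b) j else j - 1L
          extra[tj] <- extra[tj] + 1L
        }
      }
    }
    if (strands[i] == "-") {
      w <- rev(unname(comp[w])); extra <- rev(extra)
    }
    full <- c(kchars, w)
    tags <- c(integer(length(kchars)), extra)
    r <- rle(full)
    nr <- length(r$lengths)
    run_id <- rep.int(seq_len(nr), r$lengths)
    tagsum <- as.integer(rowsum(tags, run_id))
    bi <- bmap[r$values]
    # flow walk: each run consumed by the first matching flow
    flow_of_run <- integer(nr)
    f <- 0L
    kept <- 0L
    for (q in seq_len(nr)) {
      f <- f + dtab[(f %% P) + 1L, bi[q]]
      if (f >= n_flows) break
      flow_of_run[q] <- f
      f <- f + 1L
      kept <- q
    }
    h_t <- integer(n_flows)
    h_r <- integer(n_flows)
    if (kept) {
      h_t[flow_of_run[1:kept] + 1L] <- r$lengths[1:kept]
      h_r[flow_of_run[1:kept] + 1L] <- r$lengths[1:kept] + tagsum[1:kept]
    }
    cum <- cumsum(r$lengths)
    key_run_last <- which(cum >= length(kchars))[1]
    key_flow_max <- flow_of_run[key_run_last]
    # reference bases consumed by the genomic tail of the key-side runs
    skip0_ref <- (cum[key_run_last] - length(kchars)) +
      sum(tagsum[seq_len(key_run_last)])

    # flow-values: key flows exact, the rest from the generative model
    values <- as.numeric(h_t)
    gi <- (key_flow_max + 2L):n_flows      # 1-based indices of genomic flows
    hz <- h_t[gi]
    mu <- ifelse(hz >= 1,
                 eval_predictor(cfg$mean_params, hz, cycle[gi], pic[gi],
                                md$species_label, md$chip, md$kit),
                 cfg$zero_flow[["mean"]])
    sd_ <- ifelse(hz >= 1,
                  sqrt(exp(eval_predictor(cfg$disp_params, hz, cycle[gi],
                                          pic[gi], md$species_label,
                                          md$chip, md$kit))),
                  cfg$zero_flow[["sd"]])
    n_mu_trunc <- n_mu_trunc + sum(mu < 0 & hz >= 1)
    lo <- stats::pnorm(0, mu, sd_)
    y <- stats::qnorm(lo + stats::runif(length(gi)) * (1 - lo), mu, sd_)
    values[gi] <- round(y * 100) / 100
    hc <- as.integer(floor(values + 0.5 + 1e-6))

    # per-flow alignment units over the genomic flows. Indels are
    # left-aligned in reference coordinates (as aligners normalise them),
    # which in physical flow order means indel-before-match on the forward
    # strand and match-before-indel on the reverse strand. The alignment
    # must start (forward) / end (reverse) on an exactly-called flow so the
    # reference-leftmost CIGAR operation is a match.
    gf <- gi - 1L                          # 0-based genomic flow indices
    hr_g <- h_r[gi]; hc_g <- hc[gi]
    has_m <- pmin(hr_g, hc_g) > 0L
    exact <- hr_g == hc_g & hr_g > 0L
    a <- if (strands[i] == "+") which(exact)[1] else which(has_m)[1]
    b <- if (strands[i] == "+") which(has_m)[sum(has_m)]
         else which(exact)[sum(exact)]
    if (!any(exact) || is.na(a) || is.na(b) || a > b) {
      n_unmapped <- n_unmapped + 1L
      sff_reads[[i]] <- make_sff_read(names_v[i], values, hc, fbase,
                                      cfg$quality_map)
      sam_rows[[i]] <- data.table::data.table(
        qname = names_v[i], flag = 4L, rname = "*", pos = 0L, mapq = 0L,
        cigar = "*", seq = sff_reads[[i]]$bases,
        qual = phred_string(sff_reads[[i]]$qualities))
      next
    }
    led <- a:b
    ref_before <- skip0_ref + sum(hr_g[seq_len(a - 1L)])
    r_len <- sum(hr_g[led])
    pos <- if (strands[i] == "+") starts[i] + ref_before
           else starts[i] + frag_len - ref_before - r_len
    s_left <- sum(hc[seq_len(key_flow_max + 1L)]) +
      sum(hc_g[seq_len(a - 1L)])
    s_right <- if (b < length(gf)) sum(hc_g[(b + 1L):length(gf)]) else 0L

    m_f <- pmin(hr_g[led], hc_g[led])
    i_f <- pmax(hc_g[led] - hr_g[led], 0L)
    d_f <- pmax(hr_g[led] - hc_g[led], 0L)
    if (strands[i] == "+") {      # indel first = reference-left of the run
      op_len <- as.vector(rbind(i_f, d_f, m_f))
      op_chr <- rep.int(c("I", "D", "M"), length(led))
    } else {                      # reversal puts the indel reference-left
      op_len <- as.vector(rbind(m_f, i_f, d_f))
      op_chr <- rep.int(c("M", "I", "D"), length(led))
    }
    keep_op <- op_len > 0L
    op_len <- op_len[keep_op]; op_chr <- op_chr[keep_op]
    if (s_left > 0L) { op_len <- c(s_left, op_len); op_chr <- c("S", op_chr) }
    if (s_right > 0L) { op_len <- c(op_len, s_right); op_chr <- c(op_chr, "S") }
    if (strands[i] == "-") { op_len <- rev(op_len); op_chr <- rev(op_chr) }
    brk <- c(TRUE, op_chr[-1] != op_chr[-length(op_chr)])
    grp <- cumsum(brk)
    cigar <- paste0(as.integer(rowsum(op_len, grp)), op_chr[brk],
                    collapse = "")

    # substitutions: each match-column base flips with probability sub_rate;
    # bases sitting in called 1-mer flows take the 0.51 flow-value signature
    sub_flag <- logical(length(led))
    hit <- integer(0)
    mflow <- rep.int(seq_along(led), m_f)     # index into led, per M base
    moff <- sequence(m_f)                     # 1..m within each flow
    if (cfg$sub_rate > 0 && length(mflow)) {
      hit <- which(stats::runif(length(mflow)) < cfg$sub_rate)
      for (s in hit) {
        fi <- mflow[s]
        gflow <- gi[led[fi]]                  # 1-based flow array index
        sub_flag[fi] <- TRUE
        if (hc[gflow] == 1L) values[gflow] <- 0.51
      }
    }

    srec <- make_sff_read(names_v[i], values, hc, fbase, cfg$quality_map)
    if (length(hit)) {                        # flip the substituted letters
      chars <- strsplit(srec$bases, "")[[1]]
      for (s in hit) {
        fi <- mflow[s]
        gflow0 <- gf[led[fi]]
        # physical layout within an over-called flow: inserted bases come
        # first on the forward strand (indel-first CIGAR), last on reverse
        off <- if (strands[i] == "+") i_f[fi] else 0L
        ppos <- which(srec$flow_of_base == gflow0)[off + moff[s]]
        chars[ppos] <- sample(setdiff(c("A", "C", "G", "T"),
                                      chars[ppos]), 1L)
      }
      srec$bases <- paste(chars, collapse = "")
    }
    sff_reads[[i]] <- srec

    seq_sam <- srec$bases
    qual_sam <- phred_string(srec$qualities)
    if (strands[i] == "-") {
      seq_sam <- revcomp(seq_sam)
      qual_sam <- paste(rev(strsplit(qual_sam, "")[[1]]), collapse = "")
    }
    sam_rows[[i]] <- data.table::data.table(
      qname = names_v[i], flag = if (strands[i] == "-") 16L else 0L,
      rname = contig_name, pos = as.integer(pos), mapq = 60L,
      cigar = cigar, seq = seq_sam, qual = qual_sam)
    led_rows[[i]] <- list(flow = gf[led], h_true = hr_g[led],
                          h_called = hc[gi[led]], sub = sub_flag,
                          y = values[gi[led]])
  }

  if (n_mu_trunc > 0L)
    warning("mean model yielded mu < 0 for ", n_mu_trunc,
            " flows with h >= 1 (truncated at zero)")
  led_n <- vapply(led_rows, function(x) if (is.null(x)) 0L
                  else length(x$flow), integer(1))
  ledger <- data.table::data.table(
    name = rep(names_v, led_n),
    flow = unlist(lapply(led_rows, `[[`, "flow")),
    h_true = unlist(lapply(led_rows, `[[`, "h_true")),
    h_called = unlist(lapply(led_rows, `[[`, "h_called")),
    sub = unlist(lapply(led_rows, `[[`, "sub")),
    y = unlist(lapply(led_rows, `[[`, "y")))
  structure(list(
    sff = list(order = order, key = cfg$key, n_flows = n_flows,
               reads = sff_reads),
    sam = data.table::rbindlist(sam_rows),
    ledger = ledger,
    reads_truth = data.table::data.table(
      name = names_v, start = starts, strand = strands,
      n_edits = vapply(edits, function(e) if (is.null(e)) 0L
                       else nrow(e), integer(1))),
    genome = genome, hfi_sites = hfi_sites, config = cfg,
    contig_name = contig_name,
    n_unmapped = n_unmapped, n_mu_truncated = n_mu_trunc),
    class = "flow_sim")
}

make_sff_read <- function(name, values, hc, fbase, quality_map) {
  qual_flow <- quality_map(abs(values - hc))
  list(name = name, values = values,
       bases = paste(rep.int(fbase, hc), collapse = ""),
       qualities = rep.int(qual_flow, hc),
       flow_of_base = rep.int(seq_along(values) - 1L, hc),
       clip_qual = c(0L, 0L), clip_adapter = c(0L, 0L))
}

phred_string <- function(q) rawToChar(as.raw(pmin(q, 93L) + 33L))

#' Write a simulated run to disk
#'
#' Emits the SFF, a FASTQ, the truth SAM, the reference FASTA and the truth
#' ledger (TSV), plus a plain-text manifest echoing the seed.
#' @param sim A `flow_sim` from [simulate_run()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  write_sff(sim$sff$reads, sim$sff$order, sim$sff$key, p(".sff"),
            n_flows = sim$sff$n_flows)
  write_fastq(vapply(sim$sff$reads, `[[`, character(1), "name"),
              vapply(sim$sff$reads, `[[`, character(1), "bases"),
              lapply(sim$sff$reads, `[[`, "qualities"), p(".fastq"))
  genome <- stats::setNames(as.character(sim$genome), sim$contig_name)
  write_sam(sim$sam, sim$contig_name, nchar(sim$genome), p(".sam"))
  write_fasta(genome, p(".fasta"))
  data.table::fwrite(sim$ledger, p("_ledger.tsv"), sep = "\t")
  writeLines(c(paste("seed:", sim$config$seed),
               paste("n_reads:", sim$config$n_reads),
               paste("n_flows:", sim$sff$n_flows),
               paste("outputs:", paste0(prefix,
                                        c(".sff", ".fastq", ".sam", ".fasta",
                                          "_ledger.tsv"), collapse = " "))),
             p("_manifest.txt"))
  invisible(c(sff = p(".sff"), fastq = p(".fastq"), sam = p(".sam"),
              fasta = p(".fasta"), ledger = p("_ledger.tsv"),
              manifest = p("_manifest.txt")))
}

#' Per-read truth error lists from a simulated run
#'
#' Extracts, from the simulator's ledger, every alignment-visible flow where
#' the called homopolymer length disagrees with the reference, plus the
#' substitution-carrying flows. Aggregates match [project_to_flows()] run on
#' the truth SAM.
#' @param sim A `flow_sim`.
#' @return `data.table` with columns name, flow, h_true, h_called, type
#'   ("indel" or "sub").
#' @export
truth_error_table <- function(sim) {
  led <- sim$ledger
  ind <- led[!led$sub & led$h_called != led$h_true,
             c("name", "flow", "h_true", "h_called")]
  ind$type <- if (nrow(ind)) "indel" else character(0)
  sb <- led[led$sub == TRUE, c("name", "flow", "h_true", "h_called")]
  sb$type <- if (nrow(sb)) "sub" else character(0)
  out <- rbind(ind, sb)
  data.table::setorder(out, name, flow)
  out[]
}
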