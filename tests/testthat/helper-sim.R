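# shared fixtures, built in code

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_run <- function(n_reads = 60L, genome_len = 8000L, seed = 5L,
                     sub_rate = 1e-3, hfi = NULL, ...) {
  g <- simulate_reference(genome_len, 0.45, seed = seed)
  cfg <- sim_config(n_reads = n_reads, read_len_bases = 100L,
                    sub_rate = sub_rate, seed = seed + 1L, ...)
  list(genome = g, sim = simulate_run(g, hfi, cfg), cfg = cfg)
}

# a hand-built SFF read record
fake_sff_read <- function(values, order = tacg_order(), name = "r1",
                          qualities = NULL) {
  hc <- as.integer(floor(values + 0.5 + 1e-6))
  bases <- paste(rep.int(order$nucleotides[(seq_along(values) - 1L) %%
                                             order$period + 1L], hc),
                 collapse = "")
  if (is.null(qualities)) qualities <- rep(30L, sum(hc))
  list(name = name, values = values, bases = bases, qualities = qualities,
       flow_of_base = rep.int(seq_along(values) - 1L, hc),
       clip_qual = c(0L, 0L), clip_adapter = c(0L, 0L))
}
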