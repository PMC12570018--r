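# Lightweight simulation configurations shared across tests.

# Small single-motif bundle without the optional extras; fast enough to run
# many replicates.
light_cfg <- function(seed, contig_length_bp = 50000, ...) {
  args <- utils::modifyList(
    list(seed = seed, contig_length_bp = contig_length_bp, prophage = NULL,
         genes = NULL, rm_table_spec = NULL, gc_skew_planting = NULL),
    list(...))
  do.call(sim_config, args)
}

sample_groups <- function(sim) {
  stats::setNames(sim$samples$group, sim$samples$sample_id)
}

truth_instances <- function(sim) {
  sim$truth$instances[, c("contig", "strand", "start", "site_pos", "motif",
                          "meth_offset", "mod_type")]
}

# Random short nucleotide string
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Naive per-window motif scan oracle: checks every window on both strands
# with iupac_match().
naive_scan <- function(seq, m) {
  k <- nchar(m$iupac)
  L <- nchar(seq)
  rows <- list()
  rc <- reverse_complement(m$iupac)
  for (s0 in 0:(L - k)) {
    win <- substr(seq, s0 + 1, s0 + k)
    if (iupac_match(m$iupac, win)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strand = "+", start = s0, site_pos = s0 + m$meth_offset)
    }
    if (iupac_match(rc, win)) {
      rows[[length(rows) + 1L]] <- data.frame(
        strand = "-", start = s0, site_pos = s0 + (k - 1 - m$meth_offset))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(strand = character(), start = integer(), site_pos = integer())
  out[order(out$start, out$strand), , drop = FALSE]
}

# Brute-force two-sample KS statistic: evaluate both ECDFs at all pooled
# points.
ks_d_oracle <- function(xs, ys) {
  grid <- sort(unique(c(xs, ys)))
  fx <- vapply(grid, function(t) mean(xs <= t), numeric(1))
  fy <- vapply(grid, function(t) mean(ys <= t), numeric(1))
  max(abs(fx - fy))
}

# Textbook BH step-up adjustment
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * n / (n:1)))[ro]
}

# Minimal methylation record constructor for hand-built fixtures
mk_records <- function(sample_id, contig, pos, strand, mod_type, valid_cov,
                       n_mod) {
  data.frame(sample_id = sample_id, contig = contig, pos = pos,
             strand = strand, mod_type = mod_type, valid_cov = valid_cov,
             n_mod = n_mod,
             fraction = ifelse(valid_cov > 0, n_mod / valid_cov, NA_real_),
             stringsAsFactors = FALSE)
}
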