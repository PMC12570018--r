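#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: two depth horizons
#' ("top"/"bottom") with three replicate samples each, ~30x modified-base
#' coverage, one planted Dam-like GATC 6mA motif methylated at a mean site
#' fraction of 0.9 against a 0.02 background, a differential subset of 20%
#' of instances shifted by 0.3 (less methylated in the bottom group, so the
#' full magnitude survives the \[0, 1\] clipping from the 0.9 baseline), a
#' motif-depleted
#' prophage (density ratio 0.5), uniformly placed genes, a planted GC-skew
#' replication origin, and an RM gene table with a methyltransferase
#' surplus.
#'
#' @param seed master integer seed; independent per-purpose substreams are
#'   derived from it
#' @param n_contigs number of contigs
#' @param contig_length_bp length of each contig (scalar or vector)
#' @param gc_fraction GC content of the simulated sequence
#' @param planted_motifs list of entries `list(motif =, site_fraction_mean =,
#'   background_fraction_mean =)`
#' @param groups two group labels; the differential shift applies to the
#'   second
#' @param n_samples_per_group replicate samples per group
#' @param coverage_lambda Poisson mean of per-site valid coverage
#' @param beta_concentration concentration of the Beta distribution of true
#'   site fractions (overdispersion comparable to real pileups)
#' @param diff_fraction_of_instances fraction of instances that are truly
#'   differential
#' @param diff_delta methylation-fraction shift added in the second group
#'   (clipped to \[0, 1\])
#' @param prophage NULL or `list(length_bp =, motif_depletion_rho =,
#'   start =)` (start optional) carved from contig 1
#' @param genes `list(n_genes =, mean_length =)`
#' @param rm_table_spec named list per system type: `c(n_mtase =, n_rease =)`
#' @param gc_skew_planting NULL or `list(amplitude =, ori_pos =)` (ori_pos
#'   optional, defaults to 1/4 of contig 1)
#' @param background_site_rate fraction of background sites emitted in the
#'   pileups
#' @param instance_floor optional minimal instance count per planted motif,
#'   reached by targeted insertion
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1,
                       n_contigs = 1,
                       contig_length_bp = 200000,
                       gc_fraction = 0.45,
                       planted_motifs = list(list(motif = motif("GATC", 1, "6mA"),
                                                  site_fraction_mean = 0.9,
                                                  background_fraction_mean = 0.02)),
                       groups = c("top", "bottom"),
                       n_samples_per_group = 3,
                       coverage_lambda = 30,
                       beta_concentration = 50,
                       diff_fraction_of_instances = 0.2,
                       diff_delta = -0.3,
                       prophage = list(length_bp = 20000, motif_depletion_rho = 0.5),
                       genes = list(n_genes = 60, mean_length = 900),
                       rm_table_spec = list(I = c(n_mtase = 4, n_rease = 2),
                                            II = c(n_mtase = 8, n_rease = 2),
                                            III = c(n_mtase = 1, n_rease = 1),
                                            IV = c(n_mtase = 0, n_rease = 1)),
                       gc_skew_planting = list(amplitude = 0.03),
                       background_site_rate = 1,
                       instance_floor = NULL) {
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length_bp = rep_len(as.integer(contig_length_bp), n_contigs),
              gc_fraction = gc_fraction, planted_motifs = planted_motifs,
              groups = groups, n_samples_per_group = as.integer(n_samples_per_group),
              coverage_lambda = coverage_lambda,
              beta_concentration = beta_concentration,
              diff_fraction_of_instances = diff_fraction_of_instances,
              diff_delta = diff_delta, prophage = prophage, genes = genes,
              rm_table_spec = rm_table_spec, gc_skew_planting = gc_skew_planting,
              background_site_rate = background_site_rate,
              instance_floor = instance_floor)
  .validate_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_config <- function(cfg) {
  .assert(length(cfg$groups) == 2L, "exactly two groups are supported")
  .assert(cfg$gc_fraction > 0 && cfg$gc_fraction < 1, "gc_fraction must be in (0, 1)")
  .assert(cfg$diff_fraction_of_instances >= 0 && cfg$diff_fraction_of_instances <= 1,
          "diff_fraction_of_instances must be in [0, 1]")
  .assert(cfg$diff_delta >= -1 && cfg$diff_delta <= 1, "diff_delta must be in [-1, 1]")
  .assert(cfg$background_site_rate >= 0 && cfg$background_site_rate <= 1,
          "background_site_rate must be in [0, 1]")
  for (pm in cfg$planted_motifs) {
    .assert(inherits(pm$motif, "motif"), "planted_motifs entries need a motif")
    .assert(pm$site_fraction_mean >= 0 && pm$site_fraction_mean <= 1 &&
              pm$background_fraction_mean >= 0 && pm$background_fraction_mean <= 1,
            "fraction means must be in [0, 1]")
  }
  if (!is.null(cfg$prophage)) {
    .assert(cfg$prophage$length_bp < cfg$contig_length_bp[1],
            "prophage longer than contig 1")
    rho <- cfg$prophage$motif_depletion_rho
    .assert(rho >= 0 && rho <= 1, "motif_depletion_rho must be in [0, 1]")
  }
  if (!is.null(cfg$rm_table_spec)) {
    iv <- cfg$rm_table_spec[["IV"]]
    .assert(is.null(iv) || iv[["n_mtase"]] == 0,
            "Type IV systems lack methylase activity: n_mtase must be 0")
  }
  invisible(cfg)
}

.rbeta_mean <- function(n, mean, conc) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# Substitute one non-methylated position of a motif window so the window no
# longer matches on either strand. Both strands' methylated positions are
# left untouched. Returns the replacement (position, base) or NULL when the
# pattern is too degenerate to break at any non-methylated position.
.break_instance <- function(chars, start0, k, pat, pat_rc, meth_offset) {
  meth_idx <- c(meth_offset + 1L, k - meth_offset)
  idx <- sample(seq_len(k))
  idx <- idx[!(idx %in% meth_idx)]
  for (j in idx) {
    allowed <- setdiff(c("A", "C", "G", "T"),
                       union(.IUPAC_SETS[[pat[j]]], .IUPAC_SETS[[pat_rc[j]]]))
    allowed <- setdiff(allowed, chars[start0 + j])
    if (length(allowed)) {
      return(list(pos = start0 + j, base = sample(allowed, 1L)))
    }
  }
  NULL
}

#' Simulate a complete methylome input bundle in memory
#'
#' Deterministic given the configuration seed: sequences are drawn i.i.d.
#' at the configured GC content (with an optional planted GC-skew origin on
#' contig 1), planted-motif instances arise naturally by composition, a
#' prophage region is carved from contig 1 with its planted-motif density
#' thinned to `motif_depletion_rho` by single-base substitutions at
#' non-methylated motif positions, true per-instance methylation fractions
#' are Beta-distributed around the configured means (independently per
#' group, with the differential subset shifted in the second group), and
#' observed pileups follow Poisson coverage with Binomial modified counts.
#'
#' @param config a [sim_config()]
#' @return list: sequences, records (all samples), samples, genes, regions,
#'   rm_genes, truth (instances with true fractions, prophage, ori/ter,
#'   expected orphan counts)
#' @export
simulate_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  groups <- cfg$groups
  conc <- cfg$beta_concentration

  ## 1. sequences -----------------------------------------------------------
  set.seed(.substream_seed(cfg$seed, 1L))
  gc <- cfg$gc_fraction
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- vector("list", cfg$n_contigs)
  ori_pos <- ter_pos <- NA_real_
  for (i in seq_len(cfg$n_contigs)) {
    L <- cfg$contig_length_bp[i]
    if (i == 1L && !is.null(cfg$gc_skew_planting)) {
      amp <- cfg$gc_skew_planting$amplitude
      ori <- cfg$gc_skew_planting$ori_pos %||% round(0.25 * L)
      .assert(ori + L / 2 <= L, "planted ori_pos must lie in the first half of contig 1")
      ter <- ori + L / 2
      ori_pos <- ori; ter_pos <- ter
      lead <- c(A = (1 - gc) / 2, C = gc * (1 - amp) / 2,
                G = gc * (1 + amp) / 2, T = (1 - gc) / 2)
      lag <- c(A = (1 - gc) / 2, C = gc * (1 + amp) / 2,
               G = gc * (1 - amp) / 2, T = (1 - gc) / 2)
      seq_chars[[i]] <- c(
        sample(names(lag), ori, TRUE, lag),
        sample(names(lead), ter - ori, TRUE, lead),
        sample(names(lag), L - ter, TRUE, lag))
    } else {
      seq_chars[[i]] <- sample(names(base_prob), L, TRUE, base_prob)
    }
  }
  contig_ids <- sprintf("ctg_%03d", seq_len(cfg$n_contigs))
  names(seq_chars) <- contig_ids

  ## 2. prophage region + 3. motif-depletion ablation -----------------------
  set.seed(.substream_seed(cfg$seed, 3L))
  regions <- NULL
  prophage_iv <- NULL
  n_ablated <- 0L
  if (!is.null(cfg$prophage)) {
    L1 <- cfg$contig_length_bp[1]
    lp <- cfg$prophage$length_bp
    ps <- cfg$prophage$start %||%
      sample(seq.int(floor(0.05 * L1), floor(0.95 * L1) - lp), 1L)
    pe <- ps + lp
    prophage_iv <- c(start = ps, end = pe)
    host_iv <- rbind(c(0L, ps), c(pe, L1))
    host_iv <- host_iv[host_iv[, 1] < host_iv[, 2], , drop = FALSE]
    regions <- rbind(
      data.frame(contig = contig_ids[1], start = ps, end = pe,
                 label = "prophage", stringsAsFactors = FALSE),
      data.frame(contig = contig_ids[1], start = host_iv[, 1],
                 end = host_iv[, 2], label = "host", stringsAsFactors = FALSE))
    rho <- cfg$prophage$motif_depletion_rho
    if (rho < 1) {
      for (pm in cfg$planted_motifs) {
        m <- pm$motif
        k <- nchar(m$iupac)
        pat <- strsplit(m$iupac, "", fixed = TRUE)[[1]]
        pat_rc <- strsplit(reverse_complement(m$iupac), "", fixed = TRUE)[[1]]
        inst <- scan_motif(paste(seq_chars[[1]], collapse = ""), m)
        # one ablation candidate per physical window (+ orientation)
        inst <- inst[inst$strand == "+" & inst$start >= ps & inst$start + k <= pe, ,
                     drop = FALSE]
        drop_idx <- which(stats::runif(nrow(inst)) > rho)
        for (ii in drop_idx) {
          sub <- .break_instance(seq_chars[[1]], inst$start[ii], k, pat, pat_rc,
                                 m$meth_offset)
          if (!is.null(sub)) {
            seq_chars[[1]][sub$pos] <- sub$base
            n_ablated <- n_ablated + 1L
          }
        }
      }
    }
  }

  ## 4. optional up-sampling to an instance floor ---------------------------
  n_inserted <- 0L
  if (!is.null(cfg$instance_floor)) {
    for (pm in cfg$planted_motifs) {
      m <- pm$motif
      k <- nchar(m$iupac)
      cur <- sum(vapply(seq_len(cfg$n_contigs), function(i) {
        nrow(scan_motif(paste(seq_chars[[i]], collapse = ""), m))
      }, numeric(1)))
      tries <- 0L
      while (cur < cfg$instance_floor && tries < 10L * cfg$instance_floor) {
        tries <- tries + 1L
        ci <- 1L
        L <- cfg$contig_length_bp[ci]
        s0 <- sample.int(L - k, 1L)
        concrete <- vapply(strsplit(m$iupac, "", fixed = TRUE)[[1]],
                           function(cc) sample(.IUPAC_SETS[[cc]], 1L), character(1))
        seq_chars[[ci]][s0 + seq_len(k) - 1L] <- concrete
        cur <- cur + 2L  # one + and (at least) one window; recount lazily
        n_inserted <- n_inserted + 1L
      }
    }
  }

  sequences <- vapply(seq_chars, paste, character(1), collapse = "")

  ## 5. truth instances + per-group true fractions --------------------------
  set.seed(.substream_seed(cfg$seed, 4L))
  truth_inst <- list()
  for (mi in seq_along(cfg$planted_motifs)) {
    pm <- cfg$planted_motifs[[mi]]
    for (ci in seq_len(cfg$n_contigs)) {
      inst <- scan_motif(sequences[[ci]], pm$motif, contig = contig_ids[ci])
      if (nrow(inst) == 0L) next
      n <- nrow(inst)
      for (g in groups) {
        inst[[paste0("true_", g)]] <- .rbeta_mean(n, pm$site_fraction_mean, conc)
      }
      inst$is_diff <- FALSE
      n_diff <- round(cfg$diff_fraction_of_instances * n)
      if (n_diff > 0L) {
        idx <- sample.int(n, n_diff)
        inst$is_diff[idx] <- TRUE
        gb <- paste0("true_", groups[2])
        inst[[gb]][idx] <- pmin(1, pmax(0, inst[[gb]][idx] + cfg$diff_delta))
      }
      inst$in_prophage <- FALSE
      if (!is.null(prophage_iv) && ci == 1L) {
        inst$in_prophage <- inst$site_pos >= prophage_iv["start"] &
          inst$site_pos < prophage_iv["end"]
      }
      truth_inst[[length(truth_inst) + 1L]] <- inst
    }
  }
  truth_inst <- if (length(truth_inst)) do.call(rbind, truth_inst) else NULL

  ## background sites per modification type ---------------------------------
  bg_sites <- list()
  mod_types <- unique(vapply(cfg$planted_motifs, function(pm) pm$motif$mod_type,
                             character(1)))
  for (mt in mod_types) {
    base <- if (mt == "6mA") "A" else "C"
    comp <- .IUPAC_COMPLEMENT[[base]]
    bfm <- max(vapply(cfg$planted_motifs,
                      function(pm) if (pm$motif$mod_type == mt)
                        pm$background_fraction_mean else 0, numeric(1)))
    for (ci in seq_len(cfg$n_contigs)) {
      ch <- seq_chars[[ci]]
      plus <- which(ch == base) - 1L
      minus <- which(ch == comp) - 1L
      if (cfg$background_site_rate < 1) {
        plus <- plus[stats::runif(length(plus)) < cfg$background_site_rate]
        minus <- minus[stats::runif(length(minus)) < cfg$background_site_rate]
      }
      if (length(plus) + length(minus) == 0L) next
      df <- data.frame(contig = contig_ids[ci],
                       pos = c(plus, minus),
                       strand = c(rep("+", length(plus)), rep("-", length(minus))),
                       mod_type = mt, stringsAsFactors = FALSE)
      if (!is.null(truth_inst) && nrow(df) > 0L) {
        planted <- truth_inst[truth_inst$mod_type == mt &
                                truth_inst$contig == contig_ids[ci], ]
        key <- paste(planted$site_pos, planted$strand)
        df <- df[!(paste(df$pos, df$strand) %in% key), , drop = FALSE]
      }
      n <- nrow(df)
      for (g in groups) {
        df[[paste0("true_", g)]] <- .rbeta_mean(n, bfm, conc)
      }
      bg_sites[[length(bg_sites) + 1L]] <- df
    }
  }
  bg_sites <- if (length(bg_sites)) do.call(rbind, bg_sites) else NULL

  ## 6. observed pileups per sample -----------------------------------------
  set.seed(.substream_seed(cfg$seed, 5L))
  site_cols <- c("contig", "pos", "strand", "mod_type",
                 paste0("true_", groups))
  sites <- rbind(
    if (!is.null(truth_inst)) {
      s <- truth_inst[, c("contig", "site_pos", "strand", "mod_type",
                          paste0("true_", groups))]
      names(s)[2] <- "pos"
      s
    },
    if (!is.null(bg_sites)) bg_sites[, site_cols]
  )
  .assert(!is.null(sites) && nrow(sites) > 0L,
          "configuration produced no methylation sites")
  samples <- data.frame(
    sample_id = paste0(rep(groups, each = cfg$n_samples_per_group),
                       rep(seq_len(cfg$n_samples_per_group), times = 2L)),
    group = rep(groups, each = cfg$n_samples_per_group),
    stringsAsFactors = FALSE)
  records <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    g <- samples$group[si]
    p_true <- sites[[paste0("true_", g)]]
    cov <- stats::rpois(nrow(sites), cfg$coverage_lambda)
    n_mod <- stats::rbinom(nrow(sites), cov, p_true)
    records[[si]] <- data.table::data.table(
      sample_id = samples$sample_id[si], contig = sites$contig,
      pos = sites$pos, strand = sites$strand, mod_type = sites$mod_type,
      valid_cov = cov, n_mod = n_mod,
      fraction = data.table::fifelse(cov > 0L, n_mod / cov, NA_real_))
  }
  records <- as.data.frame(data.table::rbindlist(records))

  ## 7. gene models ----------------------------------------------------------
  set.seed(.substream_seed(cfg$seed, 2L))
  genes <- NULL
  if (!is.null(cfg$genes) && cfg$genes$n_genes > 0) {
    n <- cfg$genes$n_genes
    ml <- cfg$genes$mean_length
    L1 <- cfg$contig_length_bp[1]
    placed <- matrix(numeric(0), ncol = 2)
    lens <- pmax(90L, round(stats::rnorm(n, ml, ml / 5)))
    starts <- integer(0)
    for (len in lens) {
      for (try in 1:50) {
        s <- sample.int(L1 - len, 1L)
        if (nrow(placed) == 0L ||
            all(s + len <= placed[, 1] | s >= placed[, 2])) {
          placed <- rbind(placed, c(s, s + len))
          break
        }
      }
    }
    ord <- order(placed[, 1])
    placed <- placed[ord, , drop = FALSE]
    genes <- data.frame(contig = contig_ids[1],
                        start = as.integer(placed[, 1]),
                        end = as.integer(placed[, 2]),
                        strand = sample(c("+", "-"), nrow(placed), TRUE),
                        gene_id = sprintf("g_%04d", seq_len(nrow(placed))),
                        annotation = "", stringsAsFactors = FALSE)
  }

  ## 8. RM gene table ---------------------------------------------------------
  set.seed(.substream_seed(cfg$seed, 6L))
  rm_genes <- NULL
  expected_orphans <- NULL
  if (!is.null(cfg$rm_table_spec)) {
    planted_strings <- vapply(cfg$planted_motifs, function(pm) pm$motif$iupac,
                              character(1))
    planted_offsets <- vapply(cfg$planted_motifs, function(pm) pm$motif$meth_offset,
                              integer(1))
    pool <- character(0)  # distinct synthetic recognition motifs
    while (length(pool) < 60L) {
      cand <- paste(sample(c("A", "C", "G", "T"), 6L, TRUE), collapse = "")
      ok <- !any(vapply(c(pool, planted_strings), motif_compatible, logical(1),
                        a = cand))
      if (ok) pool <- c(pool, cand)
    }
    rows <- list()
    expected_orphans <- integer(0)
    gi <- 0L
    pool_i <- 0L
    for (tp in names(cfg$rm_table_spec)) {
      nm <- cfg$rm_table_spec[[tp]][["n_mtase"]]
      nr <- cfg$rm_table_spec[[tp]][["n_rease"]]
      motifs_tp <- character(nm)
      offs_tp <- integer(nm)
      for (j in seq_len(nm)) {
        if (j <= length(planted_strings) && tp == "II") {
          motifs_tp[j] <- planted_strings[j]
          offs_tp[j] <- planted_offsets[j]
        } else {
          pool_i <- pool_i + 1L
          motifs_tp[j] <- pool[pool_i]
          offs_tp[j] <- 1L
        }
      }
      for (j in seq_len(nm)) {
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig_ids[1], gene_id = sprintf("rm_%03d", gi),
          system_type = tp, role = "MTase", recognition_motif = motifs_tp[j],
          methylated_offset = offs_tp[j],
          homolog_identity = round(stats::runif(1, 85, 100), 2),
          genome = "bin_1", start = 2000L * gi, end = 2000L * gi + 900L,
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(nr)) {
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          contig = contig_ids[1], gene_id = sprintf("rm_%03d", gi),
          system_type = tp, role = "REase",
          recognition_motif = if (j <= nm) motifs_tp[j] else NA_character_,
          methylated_offset = NA_integer_,
          homolog_identity = round(stats::runif(1, 85, 100), 2),
          genome = "bin_1", start = 2000L * gi, end = 2000L * gi + 900L,
          stringsAsFactors = FALSE)
      }
      expected_orphans[tp] <- max(0L, nm - nr)
    }
    rm_genes <- do.call(rbind, rows)
  }

  list(sequences = sequences, records = records, samples = samples,
       genes = genes, regions = regions, rm_genes = rm_genes,
       truth = list(instances = truth_inst,
                    prophage = prophage_iv,
                    ori_pos = ori_pos, ter_pos = ter_pos,
                    expected_orphans = expected_orphans,
                    n_ablated = n_ablated, n_inserted = n_inserted))
}

.write_bedmethyl <- function(records, path) {
  r <- records[order(records$contig, records$pos, records$strand), , drop = FALSE]
  code <- c(`5mC` = "m", `6mA` = "a", `4mC` = "21839")
  pct <- ifelse(r$valid_cov > 0, 100 * r$n_mod / r$valid_cov, 0)
  dt <- data.table::data.table(
    r$contig, r$pos, r$pos + 1L, unname(code[r$mod_type]), r$valid_cov,
    r$strand, r$pos, r$pos + 1L, "255,0,0", r$valid_cov,
    sprintf("%.2f", pct), r$n_mod, r$valid_cov - r$n_mod,
    0L, 0L, 0L, 0L, 0L)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes contigs (FASTA), one bedMethyl pileup per sample, a sample/group
#' map, gene models (GFF3), the RM gene table (TSV), region definitions
#' (BED) and truth tables (TSV/JSON) into `out_dir`. Running the same
#' configuration twice produces byte-identical files.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if missing)
#' @return invisibly, the list from [simulate_tables()] with a `paths`
#'   element added
#' @export
generate_bundle <- function(config, out_dir) {
  sim <- simulate_tables(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  ss <- Biostrings::DNAStringSet(sim$sequences)
  paths$fasta <- file.path(out_dir, "contigs.fasta")
  Biostrings::writeXStringSet(ss, paths$fasta)
  paths$bedmethyl <- character(0)
  for (si in seq_len(nrow(sim$samples))) {
    sid <- sim$samples$sample_id[si]
    p <- file.path(out_dir, paste0(sid, ".bedmethyl.tsv"))
    .write_bedmethyl(sim$records[sim$records$sample_id == sid, ], p)
    paths$bedmethyl <- c(paths$bedmethyl, p)
  }
  paths$samples <- file.path(out_dir, "samples.tsv")
  write_report(sim$samples, paths$samples)
  if (!is.null(sim$genes)) {
    paths$gff <- file.path(out_dir, "genes.gff3")
    write_gff(sim$genes, paths$gff)
  }
  if (!is.null(sim$rm_genes)) {
    paths$rm <- file.path(out_dir, "rm_genes.tsv")
    write_report(sim$rm_genes, paths$rm)
  }
  if (!is.null(sim$regions)) {
    paths$regions <- file.path(out_dir, "regions.bed")
    write_regions(sim$regions, paths$regions)
  }
  if (!is.null(sim$truth$instances)) {
    paths$truth_instances <- file.path(out_dir, "truth_instances.tsv")
    write_report(sim$truth$instances, paths$truth_instances)
  }
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(prophage = as.list(sim$truth$prophage),
         ori_pos = sim$truth$ori_pos, ter_pos = sim$truth$ter_pos,
         expected_orphans = as.list(sim$truth$expected_orphans),
         n_ablated = sim$truth$n_ablated, n_inserted = sim$truth$n_inserted),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}
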