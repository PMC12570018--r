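#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test; `d` is the supremum of the absolute
#' difference between the two empirical CDFs. The exact p-value is used when
#' the sample-size product n*m is at most 10000 (falling back to the
#' asymptotic approximation in the presence of ties), asymptotic otherwise.
#'
#' @param xs,ys numeric vectors, each of length >= 2
#' @return list with elements `d` and `p`
#' @export
ks_compare <- function(xs, ys) {
  .assert(length(xs) >= 2L && length(ys) >= 2L,
          "ks_compare needs at least 2 values per sample (got %d and %d)",
          length(xs), length(ys))
  exact <- length(xs) * length(ys) <= 10000
  r <- suppressWarnings(stats::ks.test(xs, ys, exact = exact))
  list(d = unname(r$statistic), p = unname(r$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals p-values in \[0, 1\]
#' @return adjusted p-values (monotone in rank order, capped at 1)
#' @export
bh_adjust <- function(pvals) {
  .assert(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)), "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

.promoter_intervals <- function(genes, window) {
  plus <- genes$strand == "+"
  data.frame(contig = genes$contig,
             gene_id = genes$gene_id,
             pstart = ifelse(plus, genes$start - window, genes$end),
             pend = ifelse(plus, genes$start, genes$end + window),
             stringsAsFactors = FALSE)
}

#' Restrict motif instances to promoter regions
#'
#' Keeps instances whose methylated-base coordinate lies in the window
#' upstream of a gene start codon: `[start - window, start)` for plus-strand
#' genes, `[end, end + window)` for minus-strand genes (0-based half-open).
#' The default 60 bp window matches the transcription-start-site convention
#' used for the MAG analyses; 70 bp is the isolate-analysis variant.
#'
#' @param instances motif instances with contig and site_pos columns
#' @param genes gene models ([read_gff()])
#' @param window promoter width in bp upstream of the start codon
#' @return the subset of instances falling in at least one promoter
#' @export
promoter_subset <- function(instances, genes, window = 60) {
  if (nrow(instances) == 0L || nrow(genes) == 0L) {
    return(instances[integer(0), , drop = FALSE])
  }
  pr <- data.table::as.data.table(.promoter_intervals(genes, window))
  inst <- data.table::as.data.table(instances)
  inst[, .row_idx := .I]
  hit <- pr[inst, on = .(contig, pstart <= site_pos, pend > site_pos),
            nomatch = NULL, allow.cartesian = TRUE]
  keep <- sort(unique(hit$.row_idx))
  out <- instances[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-contig differential methylation between two sample groups
#'
#' For each contig x motif with at least `min_instances` instances having
#' data in both groups, compares the per-instance group statistics between
#' the groups with a two-sample KS test ([ks_compare()]). The statistic is
#' either the coverage-weighted per-instance group mean fraction or the
#' per-instance standard error of the fractions across a group's replicate
#' samples (a population-heterogeneity signal). P-values are BH-adjusted
#' across all tested rows of the run; each row is flagged at the configured
#' alpha and at the 0.05 level used for contig-level significance calls.
#' Contigs below `min_instances` are reported with status
#' "insufficient_data", never silently dropped.
#'
#' @param profiles long-format profiles from [profile_instances()]
#' @param group_a,group_b group labels (by convention "top" and "bottom")
#' @param scope "all_sites" or "promoter_only"
#' @param genes gene models, required for promoter_only scope
#' @param window promoter width (see [promoter_subset()])
#' @param statistic_kind "mean_fraction" or "standard_error"
#' @param min_instances minimal instances with data in both groups
#' @param alpha significance level for the primary flag
#' @return data.frame, one row per contig x motif
#' @export
contig_differential <- function(profiles, group_a = "top", group_b = "bottom",
                                scope = c("all_sites", "promoter_only"),
                                genes = NULL, window = 60,
                                statistic_kind = c("mean_fraction", "standard_error"),
                                min_instances = 10, alpha = 0.01) {
  scope <- match.arg(scope)
  statistic_kind <- match.arg(statistic_kind)
  dt <- data.table::as.data.table(profiles)
  .assert(all(c(group_a, group_b) %in% dt$group),
          "groups '%s' and '%s' must both occur in the profiles", group_a, group_b)
  if (scope == "promoter_only") {
    .assert(!is.null(genes), "promoter_only scope requires gene models")
    inst <- unique(dt[, .(inst_id, contig, site_pos)])
    keep <- promoter_subset(as.data.frame(inst), genes, window = window)$inst_id
    dt <- dt[inst_id %in% keep]
  }
  col <- if (statistic_kind == "mean_fraction") "group_mean" else "group_se"
  wide <- data.table::dcast(dt[group %in% c(group_a, group_b)],
                            contig + motif + mod_type + inst_id ~ group,
                            value.var = col)
  data.table::setnames(wide, c(group_a, group_b), c("va", "vb"))
  wide <- wide[!is.na(va) & !is.na(vb)]
  groups_of <- wide[, .(n = .N), by = .(contig, motif, mod_type)]
  res <- lapply(seq_len(nrow(groups_of)), function(i) {
    key <- groups_of[i]
    sub <- wide[key, on = .(contig, motif, mod_type)]
    row <- data.frame(contig = key$contig, motif = key$motif,
                      mod_type = key$mod_type, scope = scope,
                      statistic_kind = statistic_kind, n_instances = key$n,
                      d = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
    if (key$n >= min_instances) {
      ks <- ks_compare(sub$va, sub$vb)
      row$d <- ks$d
      row$p_raw <- ks$p
      row$status <- "ok"
    } else {
      row$status <- "insufficient_data"
    }
    row
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(contig = character(), motif = character(),
                      mod_type = character(), scope = character(),
                      statistic_kind = character(), n_instances = integer(),
                      d = numeric(), p_raw = numeric(), status = character(),
                      stringsAsFactors = FALSE)
  }
  out$p_adj <- NA_real_
  tested <- out$status == "ok"
  out$p_adj[tested] <- bh_adjust(out$p_raw[tested])
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$significant_05 <- !is.na(out$p_adj) & out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

.two_prop_test <- function(mod_a, cov_a, mod_b, cov_b) {
  m <- matrix(c(mod_a, cov_a - mod_a, mod_b, cov_b - mod_b), nrow = 2L,
              byrow = TRUE)
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5)) {
    stats::fisher.test(m)$p.value
  } else {
    stats::chisq.test(m, correct = FALSE)$p.value
  }
}

.nearest_gene <- function(contig, site_pos, genes) {
  g <- genes[genes$contig == contig, , drop = FALSE]
  if (nrow(g) == 0L) return(list(gene_id = NA_character_, distance = NA_integer_))
  dist <- pmax(g$start - site_pos, site_pos - (g$end - 1L), 0L)
  i <- which.min(dist)
  list(gene_id = g$gene_id[i], distance = as.integer(dist[i]))
}

#' Per-instance differential methylation between two sample groups
#'
#' Pools modified and valid-read counts per group for every instance with
#' data in both groups and tests the two pooled proportions (chi-squared
#' without continuity correction; Fisher's exact test when any expected
#' cell is below 5). The effect `delta` is fraction(group_b) minus
#' fraction(group_a); with the default top/bottom labels, positive deltas
#' mean more methylated in the bottom ice. P-values are BH-adjusted across
#' instances, and every instance is annotated with its nearest flanking
#' gene and a promoter flag.
#'
#' @param profiles long-format profiles from [profile_instances()]
#' @param group_a,group_b group labels; `delta = fraction(b) - fraction(a)`
#' @param genes optional gene models for flanking-gene annotation
#' @param window promoter width for the in_promoter flag
#' @param alpha significance level
#' @return data.frame, one row per instance with data in both groups
#' @export
instance_differential <- function(profiles, group_a = "top", group_b = "bottom",
                                  genes = NULL, window = 60, alpha = 0.01) {
  dt <- data.table::as.data.table(profiles)
  .assert(all(c(group_a, group_b) %in% dt$group),
          "groups '%s' and '%s' must both occur in the profiles", group_a, group_b)
  inst_cols <- intersect(c("inst_id", "contig", "strand", "start", "site_pos",
                           "motif", "meth_offset", "mod_type"), names(dt))
  a <- dt[group == group_a, c(inst_cols, "cov_sum", "mod_sum"), with = FALSE]
  data.table::setnames(a, c("cov_sum", "mod_sum"), c("cov_a", "mod_a"))
  b <- dt[group == group_b, .(inst_id, cov_b = cov_sum, mod_b = mod_sum)]
  m <- b[a, on = "inst_id"]
  skipped <- m[is.na(cov_a) | is.na(cov_b) | cov_a == 0L | cov_b == 0L]
  if (nrow(skipped)) {
    message(sprintf("instance_differential: skipped %d instances with zero pooled coverage in a group",
                    nrow(skipped)))
  }
  m <- m[!is.na(cov_a) & !is.na(cov_b) & cov_a > 0L & cov_b > 0L]
  out <- as.data.frame(m)
  if (nrow(out) == 0L) {
    out$frac_a <- out$frac_b <- out$delta <- out$p_raw <- out$p_adj <- numeric(0)
    out$significant <- logical(0)
    out$flanking_gene <- character(0)
    out$gene_distance <- integer(0)
    out$in_promoter <- logical(0)
    return(out)
  }
  out$frac_a <- out$mod_a / out$cov_a
  out$frac_b <- out$mod_b / out$cov_b
  out$delta <- out$frac_b - out$frac_a
  out$p_raw <- vapply(seq_len(nrow(out)), function(i) {
    .two_prop_test(out$mod_a[i], out$cov_a[i], out$mod_b[i], out$cov_b[i])
  }, numeric(1))
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  if (!is.null(genes) && nrow(genes) > 0L) {
    nearest <- lapply(seq_len(nrow(out)),
                      function(i) .nearest_gene(out$contig[i], out$site_pos[i], genes))
    out$flanking_gene <- vapply(nearest, `[[`, character(1), "gene_id")
    out$gene_distance <- vapply(nearest, `[[`, integer(1), "distance")
    prom_ids <- promoter_subset(out, genes, window = window)$inst_id
    out$in_promoter <- out$inst_id %in% prom_ids
  } else {
    out$flanking_gene <- NA_character_
    out$gene_distance <- NA_integer_
    out$in_promoter <- NA
  }
  rownames(out) <- NULL
  out
}
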