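#' Apply the per-site coverage filter
#'
#' Keeps records with sufficient valid coverage (default >= 5x, boundary
#' inclusive) and reports kept/dropped counts.
#'
#' @param records methylation records ([read_bedmethyl()])
#' @param min_cov minimum valid coverage (>= 1)
#' @return the filtered records
#' @export
filter_records <- function(records, min_cov = 5) {
  .assert(.is_count(min_cov) && min_cov >= 1, "min_cov must be an integer >= 1")
  keep <- records$valid_cov >= min_cov
  message(sprintf("coverage filter (>=%dx): kept %d, dropped %d records",
                  as.integer(min_cov), sum(keep), sum(!keep)))
  records[keep, , drop = FALSE]
}

#' Categorise a methylation fraction
#'
#' Low (< 33%), medium (33%-66%, boundaries inclusive), or high (> 66%);
#' NA maps to "no_data". Boundary assignment is configurable.
#'
#' @param x fractions in \[0, 1\]
#' @param low,high category thresholds
#' @return character vector of categories
#' @export
categorize_fraction <- function(x, low = 0.33, high = 0.66) {
  out <- rep("no_data", length(x))
  out[!is.na(x) & x < low] <- "low"
  out[!is.na(x) & x >= low & x <= high] <- "medium"
  out[!is.na(x) & x > high] <- "high"
  out
}

#' Profile motif instances against per-site methylation calls
#'
#' Joins every motif instance to the record at (contig, site_pos, strand,
#' mod_type) in each sample, then aggregates per sample group. Records are
#' expected to be coverage-filtered already (see [filter_records()]). The
#' group mean is the coverage-weighted pooled fraction (sum of modified
#' reads over sum of valid coverage across the group's samples); the group
#' standard error is the SE of the per-sample fractions (NA below two
#' samples). Each instance receives a methylation category from the
#' reference group's mean (the pool of all samples when no reference group
#' is named); instances with no surviving record in any sample are retained
#' with category "no_data", never dropped.
#'
#' @param instances motif instances ([scan_motif()]), with a contig column
#' @param records coverage-filtered methylation records, possibly several
#'   samples
#' @param groups named character vector mapping sample_id to group label
#' @param reference_group group whose mean drives the headline category;
#'   NULL pools all samples
#' @param low,high category thresholds (see [categorize_fraction()])
#' @return data.frame in long format, one row per instance x group:
#'   instance columns, pooled_cov, pooled_mod, pooled_mean, category,
#'   group, n_samples, cov_sum, mod_sum, group_mean, group_se
#' @export
profile_instances <- function(instances, records, groups,
                              reference_group = NULL, low = 0.33, high = 0.66) {
  .assert(nrow(instances) == 0L || "contig" %in% names(instances),
          "instances must carry a contig column")
  .assert(!is.null(names(groups)) && all(nzchar(names(groups))),
          "groups must be a named vector sample_id -> group")
  if (!is.null(reference_group)) {
    .assert(reference_group %in% groups, "reference_group '%s' not among groups",
            reference_group)
  }
  inst <- data.table::as.data.table(instances)
  inst[, inst_id := .I]
  group_levels <- unique(unname(groups))

  rec <- data.table::as.data.table(records)
  miss <- setdiff(unique(rec$sample_id), names(groups))
  .assert(length(miss) == 0L, "sample(s) without group label: %s",
          paste(miss, collapse = ", "))
  rec[, group := unname(groups[sample_id])]

  joined <- rec[inst, on = c(contig = "contig", pos = "site_pos",
                             strand = "strand", mod_type = "mod_type"),
                allow.cartesian = TRUE, nomatch = NULL]

  # per instance x group aggregates
  agg <- joined[, .(n_samples = data.table::uniqueN(sample_id),
                    cov_sum = sum(valid_cov), mod_sum = sum(n_mod),
                    group_se = if (.N >= 2L) stats::sd(fraction) / sqrt(.N) else NA_real_),
                by = .(inst_id, group)]
  agg[, group_mean := mod_sum / cov_sum]

  # instance-level pooled (all samples) and reference aggregates
  pooled <- joined[, .(pooled_cov = sum(valid_cov), pooled_mod = sum(n_mod)),
                   by = inst_id]
  pooled[, pooled_mean := pooled_mod / pooled_cov]
  if (is.null(reference_group)) {
    ref <- pooled[, .(inst_id, ref_mean = pooled_mean)]
  } else {
    ref <- agg[group == reference_group, .(inst_id, ref_mean = group_mean)]
  }

  full <- data.table::CJ(inst_id = inst$inst_id, group = group_levels)
  full <- agg[full, on = c("inst_id", "group")]
  full[is.na(n_samples), `:=`(n_samples = 0L, cov_sum = 0L, mod_sum = 0L)]
  full <- pooled[full, on = "inst_id"]
  full <- ref[full, on = "inst_id"]
  full[, category := categorize_fraction(ref_mean, low, high)]
  full[, ref_mean := NULL]
  out <- inst[full, on = "inst_id"]
  data.table::setorder(out, inst_id, group)
  cols <- c("inst_id", intersect(c("contig", "strand", "start", "site_pos",
                                   "motif", "meth_offset", "mod_type"), names(out)),
            "pooled_cov", "pooled_mod", "pooled_mean", "category",
            "group", "n_samples", "cov_sum", "mod_sum", "group_mean", "group_se")
  as.data.frame(out[, ..cols])
}

#' Summarise profiles per motif and contig
#'
#' Per motif x contig: number of instances, number and fraction with data,
#' mean and median of the group means, and the low/medium/high category
#' histogram (which sums to the number of instances with data).
#'
#' @param profiles output of [profile_instances()]
#' @return data.frame, one row per motif x contig
#' @export
motif_summary <- function(profiles) {
  empty <- data.frame(motif = character(), mod_type = character(),
                      contig = character(), n_instances = integer(),
                      n_with_data = integer(), fraction_with_data = numeric(),
                      mean_group_mean = numeric(), median_group_mean = numeric(),
                      n_low = integer(), n_medium = integer(), n_high = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(profiles) || nrow(profiles) == 0L) return(empty)
  dt <- data.table::as.data.table(profiles)
  per_inst <- dt[, .(category = category[1L], pooled_mean = pooled_mean[1L],
                     mean_of_group_means = mean(group_mean, na.rm = TRUE)),
                 by = .(motif, mod_type, contig, inst_id)]
  out <- per_inst[, .(
    n_instances = .N,
    n_with_data = sum(category != "no_data"),
    fraction_with_data = sum(category != "no_data") / .N,
    mean_group_mean = mean(pooled_mean, na.rm = TRUE),
    median_group_mean = stats::median(pooled_mean, na.rm = TRUE),
    n_low = sum(category == "low"),
    n_medium = sum(category == "medium"),
    n_high = sum(category == "high")
  ), by = .(motif, mod_type, contig)]
  data.table::setorder(out, motif, contig)
  as.data.frame(out)
}
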