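#' Motif density and spacing within a region
#'
#' Density is occurrences per bp; spacing is bp per occurrence. The display
#' spacing is truncated toward zero (e.g. 24047/23 = 1045.5 prints as 1045),
#' while the exact value is retained.
#'
#' @param count motif occurrence count (>= 0)
#' @param length_bp region length (> 0)
#' @return list: count, length_bp, density_per_bp, spacing_bp (exact, NA at
#'   count 0), spacing_display (truncated)
#' @examples
#' motif_density(97, 63960)$spacing_display  # 659
#' @export
motif_density <- function(count, length_bp) {
  .assert(.is_count(count), "count must be a non-negative integer")
  .assert(is.numeric(length_bp) && length(length_bp) == 1L && length_bp > 0,
          "length_bp must be > 0")
  spacing <- if (count > 0) length_bp / count else NA_real_
  list(count = as.integer(count), length_bp = as.integer(length_bp),
       density_per_bp = count / length_bp, spacing_bp = spacing,
       spacing_display = if (count > 0) trunc(spacing) else NA_real_)
}

#' Compare motif densities between two regions
#'
#' The ratio is the raw density of region 1 over region 2. The p-value
#' treats positions as trials in a two-proportion comparison of the
#' (count, length) pairs; the exact conditional (Fisher) test is the
#' default since for a 2x2 table it is cheap at any region size, with the
#' uncorrected chi-squared approximation available as an option. Swapping
#' the arguments inverts the ratio and leaves the p-value unchanged.
#'
#' @param count1,len1 occurrences and length of region 1
#' @param count2,len2 occurrences and length of region 2
#' @param method "fisher" (exact conditional, default) or "chisq"
#'   (uncorrected approximation; still replaced by the exact test when any
#'   expected cell is below 5)
#' @return list: ratio (density1/density2; NA when both counts are 0),
#'   p_two_sided, density1, density2, method
#' @export
density_compare <- function(count1, len1, count2, len2,
                            method = c("fisher", "chisq")) {
  method <- match.arg(method)
  .assert(len1 > 0 && len2 > 0, "region lengths must be > 0")
  .assert(.is_count(count1) && .is_count(count2), "counts must be non-negative integers")
  .assert(count1 <= len1 && count2 <= len2, "counts cannot exceed region lengths")
  d1 <- count1 / len1
  d2 <- count2 / len2
  if (count1 == 0 && count2 == 0) {
    return(list(ratio = NA_real_, p_two_sided = 1, density1 = d1, density2 = d2,
                method = "degenerate"))
  }
  m <- matrix(c(count1, len1 - count1, count2, len2 - count2), nrow = 2L,
              byrow = TRUE)
  if (method == "chisq") {
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected < 5)) method <- "fisher"
  }
  p <- if (method == "fisher") {
    stats::fisher.test(m)$p.value
  } else {
    stats::chisq.test(m, correct = FALSE)$p.value
  }
  list(ratio = d1 / d2, p_two_sided = p, density1 = d1, density2 = d2,
       method = method)
}

#' Composition-normalised observed/expected motif count
#'
#' Expected occurrence count of an IUPAC motif in a region under the
#' region's own mononucleotide composition (both strands), for reporting
#' density ratios corrected for base-composition differences between
#' regions.
#'
#' @param seq region sequence
#' @param m a [motif()]
#' @return list: observed, expected, obs_exp_ratio
#' @export
motif_obs_exp <- function(seq, m) {
  stopifnot(inherits(m, "motif"))
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  k <- nchar(m$iupac)
  .assert(L >= k, "region shorter than motif")
  freq <- table(factor(chars, levels = c("A", "C", "G", "T")))
  freq <- freq / max(sum(freq), 1L)
  pat <- strsplit(m$iupac, "", fixed = TRUE)[[1]]
  p_fwd <- prod(vapply(pat, function(cc) sum(freq[.IUPAC_SETS[[cc]]]), numeric(1)))
  rc <- strsplit(reverse_complement(m$iupac), "", fixed = TRUE)[[1]]
  p_rev <- prod(vapply(rc, function(cc) sum(freq[.IUPAC_SETS[[cc]]]), numeric(1)))
  expected <- (L - k + 1) * (p_fwd + p_rev)
  observed <- nrow(scan_motif(seq, m))
  list(observed = observed, expected = expected,
       obs_exp_ratio = if (expected > 0) observed / expected else NA_real_)
}

#' Match viral methylation profiles against candidate host recognition sets
#'
#' A phage profile is the set of motifs methylated on the phage contig; a
#' host set is the recognition motifs of the host's RM genes. Two motifs
#' match when either IUPAC pattern subsumes (aligns compatibly within) the
#' other on either strand ([motif_compatible()]). The score is a weighted
#' Jaccard: the summed weight of matched motifs on both sides over the
#' summed weight of all motifs, so identical sets score 1 and disjoint sets
#' score 0. Information weighting uses [motif_information()] bits; uniform
#' weighting counts motifs equally. Ranking ties are broken by host id.
#'
#' @param phage_profiles named list: phage_id -> character vector of IUPAC
#'   motifs
#' @param host_rm_sets named list: host_id -> character vector of IUPAC
#'   motifs
#' @param weight "information" or "uniform"
#' @return data.frame ranked per phage: phage_id, host_id, score, n_shared,
#'   shared_motifs
#' @export
match_hosts <- function(phage_profiles, host_rm_sets,
                        weight = c("information", "uniform")) {
  weight <- match.arg(weight)
  wfun <- if (weight == "information") motif_information else function(x) 1
  out <- list()
  for (pid in names(phage_profiles)) {
    pm <- unique(toupper(phage_profiles[[pid]]))
    if (length(pm) == 0L) {
      message(sprintf("match_hosts: phage '%s' has an empty motif profile", pid))
      next
    }
    for (hid in names(host_rm_sets)) {
      hm <- unique(toupper(host_rm_sets[[hid]]))
      p_matched <- vapply(pm, function(x) any(vapply(hm, motif_compatible, logical(1), a = x)),
                          logical(1))
      h_matched <- vapply(hm, function(x) any(vapply(pm, motif_compatible, logical(1), a = x)),
                          logical(1))
      wp <- vapply(pm, wfun, numeric(1))
      wh <- if (length(hm)) vapply(hm, wfun, numeric(1)) else numeric(0)
      tot <- sum(wp) + sum(wh)
      score <- if (tot > 0) (sum(wp[p_matched]) + sum(wh[h_matched])) / tot else 0
      out[[length(out) + 1L]] <- data.frame(
        phage_id = pid, host_id = hid, score = score,
        n_shared = sum(p_matched),
        shared_motifs = paste(pm[p_matched], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(phage_id = character(), host_id = character(),
                      score = numeric(), n_shared = integer(),
                      shared_motifs = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$phage_id, -res$score, res$host_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motif density across labelled regions of a contig
#'
#' Counts strand-specific instances of a motif within each labelled region
#' (intervals sharing a label are pooled, so the "host remainder" can be
#' split around a prophage) and reports count, density and spacing per
#' label, plus the pairwise density comparison between the first two labels.
#'
#' @param seq contig sequence
#' @param m a [motif()]
#' @param regions region table for that contig ([read_regions()])
#' @return list with elements `density` (data.frame per label) and
#'   `comparison` (output of [density_compare()] between the first two
#'   labels, or NULL with fewer than two)
#' @export
region_motif_density <- function(seq, m, regions) {
  inst <- scan_motif(seq, m)
  labels <- unique(regions$label)
  rows <- lapply(labels, function(lab) {
    iv <- regions[regions$label == lab, , drop = FALSE]
    len <- sum(iv$end - iv$start)
    cnt <- sum(vapply(seq_len(nrow(iv)), function(i) {
      sum(inst$site_pos >= iv$start[i] & inst$site_pos < iv$end[i])
    }, numeric(1)))
    md <- motif_density(cnt, len)
    data.frame(motif = m$iupac, region_label = lab, count = md$count,
               length_bp = md$length_bp, density_per_bp = md$density_per_bp,
               spacing_bp = md$spacing_bp, spacing_display = md$spacing_display,
               stringsAsFactors = FALSE)
  })
  density <- do.call(rbind, rows)
  comparison <- NULL
  if (length(labels) >= 2L) {
    comparison <- density_compare(density$count[1], density$length_bp[1],
                                  density$count[2], density$length_bp[2])
    comparison$label1 <- labels[1]
    comparison$label2 <- labels[2]
  }
  list(density = density, comparison = comparison)
}
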