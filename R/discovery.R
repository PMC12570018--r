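#' Select highly methylated seed sites
#'
#' Pools records per site (contig, pos, strand, mod_type) across samples and
#' keeps sites whose pooled coverage reaches `min_cov` and whose pooled
#' fraction reaches `min_fraction` (the "high" methylation category reused
#' as the seed threshold). One site list per modification type.
#'
#' @param records coverage-filtered methylation records
#' @param min_cov minimum pooled valid coverage
#' @param min_fraction minimum pooled methylated fraction
#' @return data.frame: contig, pos, strand, mod_type, valid_cov, n_mod, fraction
#' @export
select_seed_sites <- function(records, min_cov = 5, min_fraction = 0.66) {
  dt <- data.table::as.data.table(records)
  if (nrow(dt) == 0L) {
    return(data.frame(contig = character(), pos = integer(), strand = character(),
                      mod_type = character(), valid_cov = integer(),
                      n_mod = integer(), fraction = numeric()))
  }
  pooled <- dt[, .(valid_cov = sum(valid_cov), n_mod = sum(n_mod)),
               by = .(contig, pos, strand, mod_type)]
  pooled[, fraction := n_mod / valid_cov]
  out <- pooled[valid_cov >= min_cov & fraction >= min_fraction]
  data.table::setorder(out, contig, pos, strand)
  as.data.frame(out)
}

# Vectorised 2x2 chi-squared (no continuity correction); degenerate margins
# give chi2 = 0, p = 1. Cross-checked against stats::chisq.test in the tests.
.chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

.revcomp_kmers <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Both-strand background count of concrete k-mers from a per-width
# oligonucleotide frequency table.
.bg_count <- function(kmers, freq) {
  f <- freq[kmers]
  f[is.na(f)] <- 0L
  r <- freq[.revcomp_kmers(kmers)]
  r[is.na(r)] <- 0L
  unname(f + r)
}

#' De novo methylation motif discovery
#'
#' Identifies recognition motifs from a contig sequence and its methylation
#' records by k-mer enrichment around highly methylated seed sites:
#'
#' 1. the +/-`flank` context around every seed site is extracted,
#'    reverse-complementing minus-strand contexts so the methylated base sits
#'    at a fixed central index;
#' 2. every sub-window of length k <= `k_max` containing the methylated
#'    position contributes concrete k-mer candidates, counted among contexts
#'    and against their genome-wide (both-strand) background occurrence;
#' 3. each candidate is tested for enrichment with a 2x2 chi-squared
#'    (no continuity correction) and Benjamini-Hochberg adjusted at `alpha`;
#' 4. significant candidates are generalised greedily: sibling k-mers
#'    (Hamming distance 1) whose seed-support rate (seed count over
#'    background count) reaches `support_frac` of the parent's rate are
#'    merged, rewriting the position as the minimal covering IUPAC code;
#' 5. flanking positions that become N are trimmed;
#' 6. generalised motifs are re-tested, ranked by enrichment and reported
#'    greedily; a motif whose seed-site set is covered by an already
#'    reported motif is redundant and dropped.
#'
#' The background model is the empirical k-mer count of the contig itself,
#' robust to composition skew. Ties are broken by seed count, then
#' lexicographic k-mer order, so discovery is deterministic and invariant
#' under reverse-complementing the contig.
#'
#' @param seq contig sequence
#' @param records coverage-filtered methylation records for that contig
#' @param k_max maximal motif window length
#' @param flank context half-width around the methylated base
#' @param alpha BH-adjusted significance threshold
#' @param min_sites minimal number of seed sites per modification type
#' @param min_cov,min_fraction seed-site thresholds (see [select_seed_sites()])
#' @param support_frac sibling merge threshold in step 4
#' @param contig optional contig id recorded in the result
#' @return data.frame of candidate motifs: contig, motif, mod_type,
#'   meth_offset, n_seed_sites, n_meth_sites_matching, n_background_matching,
#'   chi2, p_raw, p_adj
#' @export
discover_motifs <- function(seq, records, k_max = 6, flank = 5, alpha = 0.01,
                            min_sites = 20, min_cov = 5, min_fraction = 0.66,
                            support_frac = 0.5, contig = NULL) {
  .assert(nchar(seq) >= 2 * flank + 1, "sequence shorter than one context window")
  empty <- data.frame(contig = character(), motif = character(),
                      mod_type = character(), meth_offset = integer(),
                      n_seed_sites = integer(), n_meth_sites_matching = integer(),
                      n_background_matching = integer(), chi2 = numeric(),
                      p_raw = numeric(), p_adj = numeric(), stringsAsFactors = FALSE)
  seeds <- select_seed_sites(records, min_cov = min_cov, min_fraction = min_fraction)
  if (nrow(seeds) == 0L) {
    message("motif discovery: no seed sites")
    return(empty)
  }
  out <- list()
  for (mt in sort(unique(seeds$mod_type))) {
    res <- .discover_one(toupper(seq), seeds[seeds$mod_type == mt, , drop = FALSE],
                         mt, k_max, flank, alpha, min_sites, support_frac)
    out[[mt]] <- res
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- cbind(contig = if (is.null(contig)) NA_character_ else contig, out)
  rownames(out) <- NULL
  out
}

.discover_one <- function(seq, sites, mod_type, k_max, flank, alpha,
                          min_sites, support_frac) {
  L <- nchar(seq)
  width <- 2L * flank + 1L
  cidx <- flank + 1L

  # seed contexts, motif-strand oriented, methylated base at the centre
  pos <- sites$pos
  keep <- pos >= flank & pos + flank < L
  pos <- pos[keep]
  strand <- sites$strand[keep]
  ctx <- substring(seq, pos - flank + 1L, pos + flank + 1L)
  minus <- strand == "-"
  if (any(minus)) ctx[minus] <- .revcomp_kmers(ctx[minus])
  ctx <- ctx[!grepl("N", ctx, fixed = TRUE)]
  ctx <- sort(ctx)  # orientation-independent deterministic order
  n_seed <- length(ctx)
  if (n_seed < min_sites) {
    message(sprintf("motif discovery (%s): %d seed contexts < min_sites = %d",
                    mod_type, n_seed, min_sites))
    return(NULL)
  }

  bg_freq <- lapply(seq_len(k_max), function(k) {
    f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
    f
  })

  # (1)-(2) concrete candidate enumeration
  cand <- list()
  tabs <- list()
  for (k in seq_len(k_max)) {
    for (off in max(1L, cidx - k + 1L):min(cidx, width - k + 1L)) {
      kmers <- substr(ctx, off, off + k - 1L)
      tb <- table(kmers)
      key <- paste(k, off, sep = ":")
      tabs[[key]] <- tb
      cand[[key]] <- data.frame(kmer = names(tb), k = k, off = off,
                                meth_offset = cidx - off,
                                a = as.integer(tb), stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  cand$bg <- NA_integer_
  for (k in unique(cand$k)) {
    i <- cand$k == k
    cand$bg[i] <- .bg_count(cand$kmer[i], bg_freq[[k]])
  }
  n_bg_tot <- 2L * (L - cand$k + 1L)

  # (3) enrichment test + BH across candidates
  tst <- .chi2_2x2(cand$a, n_seed - cand$a, cand$bg, n_bg_tot - cand$bg)
  cand$chi2 <- tst$chi2
  cand$p <- tst$p
  cand$enriched <- cand$a / n_seed > cand$bg / n_bg_tot
  cand$p_adj <- bh_adjust(cand$p)
  sig <- cand[cand$enriched & cand$p_adj <= alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(NULL)
  sig <- sig[order(sig$p, -sig$a, sig$kmer), , drop = FALSE]
  if (nrow(sig) > 50L) sig <- sig[seq_len(50L), , drop = FALSE]  # work bound

  # context subject-mask matrix for fast pattern matching
  M <- matrix(unname(.SUBJECT_MASK[unlist(strsplit(ctx, "", fixed = TRUE))]),
              nrow = n_seed, ncol = width, byrow = TRUE)
  smask <- .subject_mask_vec(seq)
  bases <- c("A", "C", "G", "T")

  # (4) greedy generalisation of each significant concrete candidate
  gen <- list()
  for (i in seq_len(nrow(sig))) {
    kmer <- sig$kmer[i]
    k <- sig$k[i]
    off <- sig$off[i]
    tb <- tabs[[paste(k, off, sep = ":")]]
    parent_rate <- sig$a[i] / max(sig$bg[i], 1L)
    chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
    # all Hamming-distance-1 siblings at once
    sibs <- character(0)
    sib_pos <- integer(0)
    sib_base <- character(0)
    for (j in seq_len(k)) {
      for (b in setdiff(bases, chars[j])) {
        s <- chars
        s[j] <- b
        sibs <- c(sibs, paste(s, collapse = ""))
        sib_pos <- c(sib_pos, j)
        sib_base <- c(sib_base, b)
      }
    }
    sib_a <- as.integer(tb[sibs])
    sib_a[is.na(sib_a)] <- 0L
    sib_bg <- .bg_count(sibs, bg_freq[[k]])
    merge_ok <- sib_a > 0L & sib_bg > 0L &
      sib_a / pmax(sib_bg, 1L) >= support_frac * parent_rate
    codes <- character(k)
    for (j in seq_len(k)) {
      mask <- .BASE_BIT[[chars[j]]] +
        sum(.BASE_BIT[sib_base[merge_ok & sib_pos == j]])
      codes[j] <- .MASK_TO_CODE[mask]
    }
    mo <- sig$meth_offset[i]
    # (5) trim flanking N positions
    while (length(codes) > 1L && codes[1L] == "N" && mo > 0L) {
      codes <- codes[-1L]
      mo <- mo - 1L
    }
    while (length(codes) > 1L && codes[length(codes)] == "N" &&
           mo < length(codes) - 1L) {
      codes <- codes[-length(codes)]
    }
    gen[[i]] <- data.frame(iupac = paste(codes, collapse = ""), meth_offset = mo,
                           stringsAsFactors = FALSE)
  }
  gen <- unique(do.call(rbind, gen))

  # (6) re-test generalised motifs, rank, and report non-redundant ones
  res <- list()
  seed_sets <- list()
  stats_list <- list()
  for (i in seq_len(nrow(gen))) {
    pat <- gen$iupac[i]
    mo <- gen$meth_offset[i]
    k2 <- nchar(pat)
    pmask <- .pattern_mask_vec(pat)
    col0 <- cidx - mo
    ok <- rep(TRUE, n_seed)
    for (j in seq_len(k2)) {
      ok <- ok & bitwAnd(M[, col0 + j - 1L], pmask[j]) > 0L
    }
    a2 <- sum(ok)
    bg2 <- length(.match_starts(smask, pmask)) +
      length(.match_starts(smask, .pattern_mask_vec(reverse_complement(pat))))
    nb <- 2L * (L - k2 + 1L)
    t2 <- .chi2_2x2(a2, n_seed - a2, bg2, nb - bg2)
    seed_sets[[i]] <- which(ok)
    stats_list[[i]] <- data.frame(motif = pat, mod_type = mod_type,
                                  meth_offset = mo, n_seed_sites = n_seed,
                                  n_meth_sites_matching = a2,
                                  n_background_matching = bg2,
                                  chi2 = t2$chi2, p_raw = t2$p,
                                  enriched = a2 / n_seed > bg2 / nb,
                                  stringsAsFactors = FALSE)
  }
  stats_df <- do.call(rbind, stats_list)
  stats_df$p_adj <- bh_adjust(stats_df$p_raw)
  keep <- stats_df$enriched & stats_df$p_adj <= alpha
  stats_df <- stats_df[keep, , drop = FALSE]
  seed_sets <- seed_sets[keep]
  if (nrow(stats_df) == 0L) return(NULL)
  ord <- order(-stats_df$chi2, -stats_df$n_meth_sites_matching, stats_df$motif)
  stats_df <- stats_df[ord, , drop = FALSE]
  seed_sets <- seed_sets[ord]

  accepted <- integer(0)
  for (i in seq_len(nrow(stats_df))) {
    redundant <- FALSE
    for (j in accepted) {
      if (all(seed_sets[[i]] %in% seed_sets[[j]])) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) accepted <- c(accepted, i)
  }
  out <- stats_df[accepted, , drop = FALSE]
  out$enriched <- NULL
  rownames(out) <- NULL
  out
}
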