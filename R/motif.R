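# IUPAC degeneracy sets encoded as bitmasks over A=1, C=2, G=4, T=8.
# A literal N in a scanned sequence gets its own bit (16) so that an N in the
# subject matches only the pattern code N (conservative counting: ambiguous
# sequence never supports a concrete motif call).
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.BASE_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.SUBJECT_MASK <- c(.BASE_BIT, N = 16L)
.PATTERN_MASK <- vapply(.IUPAC_SETS, function(s) sum(.BASE_BIT[s]), integer(1))
.PATTERN_MASK["N"] <- .PATTERN_MASK["N"] + 16L  # pattern N also matches subject N

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

# Minimal IUPAC code for a set of concrete bases (bitmask over ACGT).
.MASK_TO_CODE <- local({
  v <- character(15)
  for (code in names(.IUPAC_SETS)) {
    v[sum(.BASE_BIT[.IUPAC_SETS[[code]]])] <- code
  }
  v
})

.check_alphabet <- function(chars, allowed, what) {
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop(sprintf("invalid %s character '%s' at position %d", what,
                 chars[bad[1]], bad[1]), call. = FALSE)
  }
}

#' Reverse complement of a nucleotide or IUPAC string
#'
#' The standard complement extended to the full IUPAC alphabet
#' (R/Y, S/S, W/W, K/M, B/V, D/H, N/N).
#'
#' @param x a single nucleotide or IUPAC-degenerate string
#' @return the reverse-complemented string
#' @examples
#' reverse_complement("GGATG")  # "CATCC"
#' reverse_complement("GANTC")  # palindromic under N self-complement
#' @export
reverse_complement <- function(x) {
  .assert(is.character(x) && length(x) == 1L && !is.na(x), "x must be a single string")
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  .check_alphabet(chars, names(.IUPAC_COMPLEMENT), "IUPAC")
  paste(rev(.IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Match a nucleotide k-mer against an IUPAC pattern
#'
#' Each k-mer base must belong to the degeneracy set of the corresponding
#' pattern code. An N in the k-mer matches only the pattern code N.
#'
#' @param pattern IUPAC string
#' @param kmer nucleotide string (A/C/G/T/N) of the same length
#' @return logical
#' @examples
#' iupac_match("GANTC", "GATTC")  # TRUE
#' iupac_match("CCWGG", "CCCGG")  # FALSE: W is A/T
#' @export
iupac_match <- function(pattern, kmer) {
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  s <- strsplit(toupper(kmer), "", fixed = TRUE)[[1]]
  .assert(length(p) == length(s), "pattern and kmer lengths differ (%d vs %d)",
          length(p), length(s))
  .check_alphabet(p, names(.PATTERN_MASK), "IUPAC")
  .check_alphabet(s, names(.SUBJECT_MASK), "nucleotide")
  all(bitwAnd(.PATTERN_MASK[p], .SUBJECT_MASK[s]) > 0L)
}

#' Construct a methylation motif
#'
#' A motif is an IUPAC recognition sequence together with the 0-based offset
#' of the methylated base within it and the modification type. The base at
#' the methylated offset must be able to carry the modification (a
#' C-compatible code for 5mC/4mC, an A-compatible code for 6mA).
#'
#' @param iupac IUPAC string
#' @param meth_offset 0-based index of the methylated base within `iupac`
#' @param mod_type one of "5mC", "6mA", "4mC"
#' @return an object of class `motif`
#' @examples
#' motif("GANTC", 1, "6mA")
#' @export
motif <- function(iupac, meth_offset, mod_type = c("6mA", "5mC", "4mC")) {
  mod_type <- match.arg(mod_type)
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "", fixed = TRUE)[[1]]
  .check_alphabet(chars, names(.IUPAC_SETS), "IUPAC")
  .assert(.is_count(meth_offset) && meth_offset < length(chars),
          "meth_offset must lie within the motif (0 <= offset < %d)", length(chars))
  need <- if (mod_type == "6mA") "A" else "C"
  .assert(need %in% .IUPAC_SETS[[chars[meth_offset + 1L]]],
          "base '%s' at meth_offset %d cannot carry %s",
          chars[meth_offset + 1L], meth_offset, mod_type)
  structure(list(iupac = iupac, meth_offset = as.integer(meth_offset),
                 mod_type = mod_type),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif>", format_motif(x), "\n")
  invisible(x)
}

#' Report notation for a motif
#'
#' Writes the motif with the methylated base bracketed together with its
#' modification type, e.g. `"G[6mA]NTC"`.
#'
#' @param m a [motif()]
#' @return a single string
#' @export
format_motif <- function(m) {
  stopifnot(inherits(m, "motif"))
  chars <- strsplit(m$iupac, "", fixed = TRUE)[[1]]
  i <- m$meth_offset + 1L
  paste0(paste(chars[seq_len(i - 1L)], collapse = ""),
         "[", m$mod_type, "]",
         paste(chars[seq_len(length(chars) - i) + i], collapse = ""))
}

#' Parse the bracketed report notation back into a motif
#'
#' The bracketed modification code stands in for the methylated base itself
#' (A for 6mA, C for 5mC/4mC), so `"G[6mA]NTC"` parses to GANTC with the A
#' at offset 1.
#'
#' @param x a string such as `"G[6mA]NTC"`
#' @return a [motif()]
#' @export
parse_motif <- function(x) {
  m <- regmatches(x, regexec("^([ACGTRYSWKMBDHVN]*)\\[(5mC|6mA|4mC)\\]([ACGTRYSWKMBDHVN]*)$",
                             toupper(x), ignore.case = TRUE))[[1]]
  .assert(length(m) == 4L, "cannot parse motif notation '%s'", x)
  base <- if (m[3] == "6mA") "A" else "C"
  motif(paste0(m[2], base, m[4]), nchar(m[2]), m[3])
}

.subject_mask_vec <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  .check_alphabet(chars, names(.SUBJECT_MASK), "nucleotide")
  unname(.SUBJECT_MASK[chars])
}

.pattern_mask_vec <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  .check_alphabet(chars, names(.PATTERN_MASK), "IUPAC")
  unname(.PATTERN_MASK[chars])
}

# 1-based start positions where the pattern matches the masked subject.
.match_starts <- function(smask, pmask) {
  L <- length(smask)
  k <- length(pmask)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    ok <- ok & bitwAnd(smask[j:(n + j - 1L)], pmask[j]) > 0L
  }
  which(ok)
}

#' Locate strand-specific motif instances on a contig
#'
#' Scans the forward strand with the motif and with its reverse complement;
#' every match is a separate strand-specific instance, so palindromic motifs
#' yield one `+` and one `-` instance over the same window. All overlapping
#' occurrences are reported. Coordinates are 0-based: `start` is the position
#' of the motif's first base in `+` orientation and `site_pos` the reference
#' coordinate of the methylated base (`start + meth_offset` on `+`,
#' `start + k - 1 - meth_offset` on `-`).
#'
#' @param seq nucleotide string (A/C/G/T/N)
#' @param m a [motif()]
#' @param contig optional contig id recorded in the result
#' @return data.frame with columns contig (if given), strand, start,
#'   site_pos, motif, meth_offset, mod_type, sorted by (start, strand)
#' @examples
#' scan_motif("GGATCC", motif("GATC", 1, "6mA"))
#' @export
scan_motif <- function(seq, m, contig = NULL) {
  stopifnot(inherits(m, "motif"))
  k <- nchar(m$iupac)
  .assert(nchar(seq) >= k, "sequence (%d bp) shorter than motif (%d bp)",
          nchar(seq), k)
  smask <- .subject_mask_vec(seq)
  fwd <- .match_starts(smask, .pattern_mask_vec(m$iupac)) - 1L
  rev <- .match_starts(smask, .pattern_mask_vec(reverse_complement(m$iupac))) - 1L
  n <- length(fwd) + length(rev)
  out <- data.frame(
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    start = c(fwd, rev),
    site_pos = c(fwd + m$meth_offset, rev + (k - 1L - m$meth_offset)),
    motif = rep(m$iupac, n),
    meth_offset = rep(m$meth_offset, n),
    mod_type = rep(m$mod_type, n),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(contig)) out <- cbind(contig = contig, out, stringsAsFactors = FALSE)
  out
}

#' Information content of an IUPAC motif
#'
#' Sum over positions of `2 - log2(|degeneracy set|)` bits; fully degenerate
#' positions (N) contribute nothing, concrete bases 2 bits.
#'
#' @param iupac IUPAC string
#' @return bits (numeric)
#' @export
motif_information <- function(iupac) {
  chars <- strsplit(toupper(iupac), "", fixed = TRUE)[[1]]
  .check_alphabet(chars, names(.IUPAC_SETS), "IUPAC")
  sum(2 - log2(lengths(.IUPAC_SETS[chars])))
}

#' Test whether two IUPAC motifs are compatible
#'
#' Two motifs are compatible when the shorter can be aligned within the
#' longer, on either strand, such that every aligned position has a
#' non-empty intersection of degeneracy sets. Equal-length subsumption
#' (one pattern matching a superset of the other's instances) is a special
#' case; the sliding alignment additionally lets a short recognition core
#' (e.g. ACAY) match a bipartite Type I site written with an explicit N run
#' (e.g. ACAYNNNNNRTT).
#'
#' @param a,b IUPAC strings
#' @return logical
#' @export
motif_compatible <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  pa <- .pattern_mask_vec(a)
  k <- length(pa)
  for (bb in c(b, reverse_complement(b))) {
    pb <- .pattern_mask_vec(bb)
    for (off in 0:(length(pb) - k)) {
      if (all(bitwAnd(pa, pb[off + seq_len(k)]) > 0L)) return(TRUE)
    }
  }
  FALSE
}
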