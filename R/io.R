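# All coordinates are 0-based half-open internally; conversions to and from
# 1-based external dialects (GFF3) happen only inside the parsers/writers.

.MOD_CODE_MAP <- c(m = "5mC", a = "6mA", "21839" = "4mC")

.empty_methyl <- function() {
  data.frame(sample_id = character(), contig = character(), pos = integer(),
             strand = character(), mod_type = character(),
             valid_cov = integer(), n_mod = integer(), fraction = numeric(),
             stringsAsFactors = FALSE)
}

#' Read a bedMethyl modified-base pileup
#'
#' Reads the tab-separated per-site, per-strand pileup emitted by nanopore
#' modified-base callers. Two dialects are accepted, detected by column
#' count: the 18-column layout (9 BED fields plus the 9-column pileup
#' extension, with valid coverage in column 10 and modified-read count in
#' column 12) and a minimal 11-column layout (9 BED fields plus valid
#' coverage and modified count in columns 10-11). Modified-base codes are
#' mapped m -> 5mC, a -> 6mA, 21839 -> 4mC; rows with unknown codes are
#' skipped with a warning giving the skipped count. The upstream read-level
#' confidence filter applied by the caller is not re-applied here.
#'
#' @param path bedMethyl file
#' @param sample_id sample label attached to every record
#' @return data.frame of methylation records: sample_id, contig, pos
#'   (0-based), strand, mod_type, valid_cov, n_mod, fraction
#'   (n_mod/valid_cov; NA when valid_cov is 0)
#' @export
read_bedmethyl <- function(path, sample_id) {
  .assert(file.exists(path), "file not found: %s", path)
  if (file.size(path) == 0L) return(.empty_methyl())
  first <- readLines(path, n = 1L, warn = FALSE)
  nfields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  .assert(nfields %in% c(11L, 18L),
          "unsupported bedMethyl dialect: %d columns (expected 11 or 18)", nfields)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = FALSE, fill = FALSE,
                      colClasses = "character", data.table = TRUE),
    error = function(e) stop("malformed bedMethyl row: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("malformed bedMethyl row: ", conditionMessage(w),
                               call. = FALSE)
  )
  .assert(ncol(dt) == nfields, "inconsistent column count in %s", path)
  cov_col <- 10L
  mod_col <- if (nfields == 18L) 12L else 11L
  int_or_die <- function(x, what, col) {
    bad <- which(!grepl("^[0-9]+$", x))
    if (length(bad)) {
      stop(sprintf("malformed bedMethyl row: non-integer %s '%s' at line %d",
                   what, x[bad[1]], bad[1]), call. = FALSE)
    }
    as.integer(x)
  }
  pos <- int_or_die(dt[[2L]], "start", 2L)
  valid_cov <- int_or_die(dt[[cov_col]], "valid coverage", cov_col)
  n_mod <- int_or_die(dt[[mod_col]], "modified count", mod_col)
  bad <- which(n_mod > valid_cov)
  if (length(bad)) {
    stop(sprintf("malformed bedMethyl row: n_mod (%d) > valid_cov (%d) at line %d",
                 n_mod[bad[1]], valid_cov[bad[1]], bad[1]), call. = FALSE)
  }
  strand <- dt[[6L]]
  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("malformed bedMethyl row: bad strand '%s' at line %d",
                 strand[bad[1]], bad[1]), call. = FALSE)
  }
  mod_type <- unname(.MOD_CODE_MAP[dt[[4L]]])
  unknown <- is.na(mod_type)
  if (any(unknown)) {
    warning(sprintf("skipped %d bedMethyl rows with unknown modified-base codes (%s)",
                    sum(unknown),
                    paste(unique(dt[[4L]][unknown]), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !unknown
  data.frame(sample_id = sample_id, contig = dt[[1L]][keep], pos = pos[keep],
             strand = strand[keep], mod_type = mod_type[keep],
             valid_cov = valid_cov[keep], n_mod = n_mod[keep],
             fraction = ifelse(valid_cov[keep] > 0L,
                               n_mod[keep] / valid_cov[keep], NA_real_),
             stringsAsFactors = FALSE)
}

#' Read contig sequences from FASTA
#'
#' Ids are the first whitespace-delimited token of each header; sequences are
#' uppercased and restricted to A/C/G/T/N.
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0L, "duplicate contig id '%s' in %s", dup[1], path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    off <- regexpr("[^ACGTN]", seqs[[i]])
    .assert(off < 0L, "non-nucleotide character '%s' in contig '%s' at offset %d",
            substr(seqs[[i]], off, off), ids[i], off - 1L)
  }
  seqs
}

#' Read gene models from GFF3
#'
#' Only rows of the configured feature types are ingested. The 1-based
#' inclusive GFF coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file
#' @param types feature types to keep (default CDS and gene)
#' @return data.frame: contig, start, end (0-based half-open), strand,
#'   gene_id, annotation
#' @export
read_gff <- function(path, types = c("CDS", "gene")) {
  .assert(file.exists(path), "file not found: %s", path)
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      annotation = character(), stringsAsFactors = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(empty)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[g$type %in% types, , drop = FALSE]
  if (nrow(g) == 0L) return(empty)
  .assert(all(g$start <= g$end), "GFF record with start > end in %s", path)
  strand <- as.character(g$strand)
  .assert(all(strand %in% c("+", "-")), "GFF gene with undefined strand in %s", path)
  pick <- function(cols) {
    out <- rep(NA_character_, nrow(g))
    for (cc in cols) {
      if (cc %in% names(g)) {
        v <- as.character(g[[cc]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  gene_id <- pick(c("ID", "locus_tag", "Name", "gene"))
  gene_id[is.na(gene_id)] <- paste0("gene_", which(is.na(gene_id)))
  annotation <- pick(c("product", "Note", "description"))
  annotation[is.na(annotation)] <- ""
  data.frame(contig = as.character(g$seqid), start = as.integer(g$start) - 1L,
             end = as.integer(g$end), strand = strand, gene_id = gene_id,
             annotation = annotation, stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GFF convention; reading the file back with [read_gff()] is the
#' identity.
#'
#' @param genes data.frame as returned by [read_gff()]
#' @param path output file
#' @param type feature type to write
#' @export
write_gff <- function(genes, path, type = "gene") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- type
  if (type == "CDS") gr$phase <- 0L
  gr$ID <- genes$gene_id
  if (!is.null(genes$annotation)) gr$product <- genes$annotation
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

.VALID_SYSTEM_TYPES <- c("I", "II", "III", "IV")
.VALID_ROLES <- c("MTase", "REase", "S", "combined")

#' Read a restriction-modification gene table
#'
#' Tab-separated with header. Required columns: contig, gene_id,
#' system_type (I-IV), role (MTase/REase/S/combined). Optional columns:
#' recognition_motif (IUPAC; empty = unknown), methylated_offset,
#' homolog_identity, genome (MAG/bin grouping), start, end (0-based
#' half-open gene coordinates, used for linkage-based orphan calls).
#' Type IV systems lack methylase activity, so role MTase is rejected
#' for system_type IV.
#'
#' @param path TSV file
#' @return data.frame of RM genes
#' @export
read_rm_table <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = 1:2)))
  need <- c("contig", "gene_id", "system_type", "role")
  miss <- setdiff(need, names(dt))
  .assert(length(miss) == 0L, "RM table missing column(s): %s",
          paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$system_type), .VALID_SYSTEM_TYPES)
  .assert(length(bad) == 0L, "unknown RM system_type token '%s'", bad[1])
  bad <- setdiff(unique(dt$role), .VALID_ROLES)
  .assert(length(bad) == 0L, "unknown RM role token '%s'", bad[1])
  .assert(!any(dt$system_type == "IV" & dt$role == "MTase"),
          "invalid RM gene: Type IV systems lack methylase activity")
  if (is.null(dt$recognition_motif)) dt$recognition_motif <- NA_character_
  dt$recognition_motif[!is.na(dt$recognition_motif) &
                         dt$recognition_motif == ""] <- NA_character_
  for (cc in c("methylated_offset", "start", "end")) {
    if (!is.null(dt[[cc]])) dt[[cc]] <- as.integer(dt[[cc]])
  }
  if (!is.null(dt$homolog_identity)) dt$homolog_identity <- as.numeric(dt$homolog_identity)
  dt
}

#' Read labelled regions from BED
#'
#' BED is already 0-based half-open; the name column (4th) carries the
#' region label (e.g. "prophage" / "host"). Regions sharing a contig and
#' label must not overlap.
#'
#' @param path BED file
#' @return data.frame: contig, start, end, label
#' @export
read_regions <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  label <- gr$name
  .assert(!any(is.na(label)), "BED region without a label (name column) in %s", path)
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    label = label, stringsAsFactors = FALSE)
  .assert(all(out$start < out$end), "BED region with start >= end in %s", path)
  sp <- split(out, paste(out$contig, out$label, sep = "\r"))
  for (grp in sp) {
    grp <- grp[order(grp$start), , drop = FALSE]
    if (nrow(grp) > 1L && any(grp$start[-1L] < grp$end[-nrow(grp)])) {
      stop(sprintf("overlapping '%s' regions on contig %s",
                   grp$label[1], grp$contig[1]), call. = FALSE)
    }
  }
  out
}

#' Write labelled regions to BED
#'
#' @param regions data.frame as returned by [read_regions()]
#' @param path output file
#' @export
write_regions <- function(regions, path) {
  out <- regions[, c("contig", "start", "end", "label")]
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, eol = "\n")
  invisible(path)
}

#' Write a report table as TSV
#'
#' UTF-8, LF line endings, header line, stable column order. Numeric cells
#' are serialised with full precision so that [read_report()] reproduces the
#' table cell-for-cell.
#'
#' @param table data.frame
#' @param path output file
#' @export
write_report <- function(table, path) {
  out <- as.data.frame(table)
  for (cc in names(out)) {
    if (is.double(out[[cc]])) {
      v <- sprintf("%.17g", out[[cc]])
      v[is.na(out[[cc]])] <- NA_character_
      out[[cc]] <- v
    }
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a report table written by [write_report()]
#'
#' @param path TSV file
#' @return data.frame
#' @export
read_report <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}
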