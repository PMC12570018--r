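#' Count restriction-modification genes by system type and role
#'
#' "combined" restriction-and-modification fusions (Type I/III) increment
#' both the methyltransferase and the restriction-enzyme counter;
#' specificity (S) subunits count as other.
#'
#' @param rm_genes RM gene table ([read_rm_table()])
#' @return data.frame with one row per system type I-IV: n_mtase, n_rease,
#'   n_other
#' @export
count_by_type <- function(rm_genes) {
  out <- data.frame(system_type = .VALID_SYSTEM_TYPES, n_mtase = 0L,
                    n_rease = 0L, n_other = 0L, stringsAsFactors = FALSE)
  if (nrow(rm_genes) > 0L) {
    for (i in seq_len(nrow(out))) {
      g <- rm_genes[rm_genes$system_type == out$system_type[i], , drop = FALSE]
      out$n_mtase[i] <- sum(g$role %in% c("MTase", "combined"))
      out$n_rease[i] <- sum(g$role %in% c("REase", "combined"))
      out$n_other[i] <- sum(g$role == "S")
    }
  }
  out
}

#' Detect orphan methyltransferases
#'
#' Within each genome group (the `genome` column when present, else the
#' contig), an MTase is orphan iff no restriction enzyme of the same system
#' type pairs with it, where pairing means either (a) both recognition
#' motifs are known and IUPAC-compatible in either direction, or (b) at
#' least one motif is unknown and the two genes lie within `linkage_kb` of
#' each other on the same contig (using the gap between gene intervals when
#' coordinates are available). Combined restriction-and-modification
#' fusions carry their own restriction activity and are never orphans.
#'
#' @param rm_genes RM gene table; optional columns genome, start, end
#' @param linkage_kb operon-linkage distance in kb for the unknown-motif rule
#' @return data.frame of orphan MTases with a `reason` column
#'   ("no_rease_of_type", "no_cognate_motif" or "no_linked_rease")
#' @export
orphan_mtases <- function(rm_genes, linkage_kb = 5) {
  cols <- c(names(rm_genes), "reason")
  empty <- rm_genes[integer(0), , drop = FALSE]
  empty$reason <- character(0)
  if (nrow(rm_genes) == 0L) return(empty)
  grp <- if (!is.null(rm_genes$genome)) rm_genes$genome else rm_genes$contig
  out <- list()
  for (g in unique(grp)) {
    sub <- rm_genes[grp == g, , drop = FALSE]
    mts <- sub[sub$role == "MTase", , drop = FALSE]
    for (i in seq_len(nrow(mts))) {
      m <- mts[i, , drop = FALSE]
      re <- sub[sub$role %in% c("REase", "combined") &
                  sub$system_type == m$system_type, , drop = FALSE]
      if (nrow(re) == 0L) {
        m$reason <- "no_rease_of_type"
        out[[length(out) + 1L]] <- m
        next
      }
      paired <- FALSE
      for (j in seq_len(nrow(re))) {
        r <- re[j, , drop = FALSE]
        m_motif <- m$recognition_motif %||% NA_character_
        r_motif <- r$recognition_motif %||% NA_character_
        if (!is.na(m_motif) && !is.na(r_motif)) {
          if (motif_compatible(m_motif, r_motif)) {
            paired <- TRUE
            break
          }
        } else if (.rm_linked(m, r, linkage_kb * 1000)) {
          paired <- TRUE
          break
        }
      }
      if (!paired) {
        known <- !is.na(m$recognition_motif %||% NA_character_) &&
          all(!is.na(re$recognition_motif %||% rep(NA_character_, nrow(re))))
        m$reason <- if (known) "no_cognate_motif" else "no_linked_rease"
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.rm_linked <- function(m, r, linkage_bp) {
  if (is.null(m$start) || is.null(r$start) ||
      is.na(m$start) || is.na(r$start)) {
    return(FALSE)
  }
  if (m$contig != r$contig) return(FALSE)
  m_end <- if (!is.null(m$end) && !is.na(m$end)) m$end else m$start + 1L
  r_end <- if (!is.null(r$end) && !is.na(r$end)) r$end else r$start + 1L
  gap <- max(m$start - r_end, r$start - m_end, 0L)
  gap <= linkage_bp
}

#' Methyltransferase surplus Z statistic
#'
#' Under the null that each of the N = n_mtase + n_rease role-assignable RM
#' genes is independently a methyltransferase or a restriction enzyme with
#' probability 1/2, `z = (n_mtase - n_rease) / sqrt(N)`; the two-sided
#' p-value comes from the standard normal, or from a seeded permutation of
#' role labels when `method = "permutation"`.
#'
#' @param n_mtase,n_rease gene counts
#' @param method "normal" (closed form) or "permutation"
#' @param n_perm permutation count
#' @return list with z, p_two_sided, n_mtase, n_rease, method
#' @examples
#' surplus_z(376, 48)  # z = 15.93
#' @export
surplus_z <- function(n_mtase, n_rease, method = c("normal", "permutation"),
                      n_perm = 10000) {
  method <- match.arg(method)
  .assert(.is_count(n_mtase) && .is_count(n_rease), "counts must be non-negative integers")
  n <- n_mtase + n_rease
  .assert(n >= 1, "surplus_z needs at least one role-assignable gene")
  z <- (n_mtase - n_rease) / sqrt(n)
  if (method == "normal") {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    m_star <- stats::rbinom(n_perm, n, 0.5)
    z_star <- (2 * m_star - n) / sqrt(n)
    p <- (sum(abs(z_star) >= abs(z)) + 1) / (n_perm + 1)
  }
  list(z = z, p_two_sided = p, n_mtase = n_mtase, n_rease = n_rease,
       method = method)
}
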