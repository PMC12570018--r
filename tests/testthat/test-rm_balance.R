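mk_rm <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(contig = r$contig %||% "c1", gene_id = r$gene_id,
               system_type = r$type, role = r$role,
               recognition_motif = r$motif %||% NA_character_,
               methylated_offset = NA_integer_, homolog_identity = NA_real_,
               genome = r$genome %||% "binA",
               start = r$start %||% NA_integer_,
               end = r$end %||% NA_integer_, stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("count_by_type: plain roles, combined fusions, and S subunits", {
  rm <- mk_rm(list(gene_id = "m1", type = "II", role = "MTase"),
              list(gene_id = "m2", type = "II", role = "MTase"),
              list(gene_id = "r1", type = "II", role = "REase"),
              list(gene_id = "c1g", type = "I", role = "combined"),
              list(gene_id = "s1", type = "I", role = "S"))
  ct <- count_by_type(rm)
  expect_equal(ct$n_mtase[ct$system_type == "II"], 2L)
  expect_equal(ct$n_rease[ct$system_type == "II"], 1L)
  expect_equal(ct$n_mtase[ct$system_type == "I"], 1L)   # combined counts both
  expect_equal(ct$n_rease[ct$system_type == "I"], 1L)
  expect_equal(ct$n_other[ct$system_type == "I"], 1L)
  expect_equal(count_by_type(rm[0, ])$n_mtase, rep(0L, 4))
})

test_that("an MTase without any same-type REase is orphan", {
  rm <- mk_rm(list(gene_id = "m1", type = "II", role = "MTase", motif = "GATC"),
              list(gene_id = "r1", type = "I", role = "REase", motif = "ACANNNNNNTT"))
  o <- orphan_mtases(rm)
  expect_equal(o$gene_id, "m1")
  expect_equal(o$reason, "no_rease_of_type")
})

test_that("a cognate-motif REase in the same genome rescues the MTase", {
  rm <- mk_rm(list(gene_id = "m1", type = "II", role = "MTase", motif = "GGCC"),
              list(gene_id = "r1", type = "II", role = "REase", motif = "GGCC"))
  expect_equal(nrow(orphan_mtases(rm)), 0L)

  # incompatible known motifs -> orphan with no_cognate_motif
  rm2 <- mk_rm(list(gene_id = "m1", type = "II", role = "MTase", motif = "GGCC"),
               list(gene_id = "r1", type = "II", role = "REase", motif = "GANTC"))
  o2 <- orphan_mtases(rm2)
  expect_equal(o2$reason, "no_cognate_motif")
})

test_that("unknown motifs fall back to the operon-linkage rule", {
  rm <- mk_rm(list(gene_id = "m1", type = "II", role = "MTase",
                   start = 1000L, end = 2000L),
              list(gene_id = "r1", type = "II", role = "REase",
                   start = 4000L, end = 4800L))  # 2 kb gap
  expect_equal(nrow(orphan_mtases(rm, linkage_kb = 5)), 0L)
  o <- orphan_mtases(rm, linkage_kb = 1)
  expect_equal(o$reason, "no_linked_rease")
})

test_that("removing an REase never decreases the orphan count", {
  set.seed(61)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    rows <- lapply(seq_len(n), function(j) {
      list(gene_id = paste0("g", j),
           type = sample(c("I", "II", "III"), 1),
           role = sample(c("MTase", "REase"), 1),
           motif = sample(c("GATC", "GGCC", "GANTC", NA), 1),
           start = j * 3000L, end = j * 3000L + 900L)
    })
    rm <- do.call(mk_rm, rows)
    before <- nrow(orphan_mtases(rm))
    expect_lte(before, sum(rm$role == "MTase"))
    re_idx <- which(rm$role == "REase")
    if (length(re_idx)) {
      after <- nrow(orphan_mtases(rm[-re_idx[1], , drop = FALSE]))
      expect_gte(after, before)
    }
  }
})

test_that("surplus z closed form, antisymmetry and edge cases", {
  expect_equal(surplus_z(10, 10)$z, 0)
  expect_equal(surplus_z(10, 10)$p_two_sided, 1)
  expect_equal(surplus_z(376, 48)$z, 328 / sqrt(424), tolerance = 1e-12)
  expect_equal(round(surplus_z(376, 48)$z, 2), 15.93)
  expect_equal(surplus_z(0, 10)$z, -3.162, tolerance = 1e-3)
  expect_equal(surplus_z(7, 2)$z, -surplus_z(2, 7)$z)
  expect_error(surplus_z(0, 0), "at least one")
})

test_that("permutation p-value agrees with the normal approximation for large N", {
  set.seed(8)
  s_norm <- surplus_z(230, 170)
  s_perm <- surplus_z(230, 170, method = "permutation", n_perm = 20000)
  expect_equal(s_perm$z, s_norm$z)
  expect_lt(abs(s_perm$p_two_sided - s_norm$p_two_sided), 0.01)
})
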