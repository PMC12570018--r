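test_that("motif spacing reproduces the printed prophage/host worked examples", {
  d1 <- motif_density(97, 63960)
  expect_equal(d1$spacing_display, 659)
  expect_equal(d1$spacing_bp, 63960 / 97)
  expect_equal(d1$density_per_bp * d1$spacing_bp, 1)

  d2 <- motif_density(23, 24047)
  expect_equal(d2$spacing_display, 1045)  # truncated from 1045.5

  d0 <- motif_density(0, 1000)
  expect_equal(d0$density_per_bp, 0)
  expect_true(is.na(d0$spacing_bp))
  expect_error(motif_density(5, 0), "length_bp")
})

test_that("density_compare: equal densities, degenerate zero counts, swap symmetry", {
  eq <- density_compare(10, 1000, 100, 10000)
  expect_equal(eq$ratio, 1)
  expect_equal(eq$p_two_sided, 1)

  z <- density_compare(0, 1000, 0, 500)
  expect_true(is.na(z$ratio))
  expect_equal(z$p_two_sided, 1)

  a <- density_compare(40, 9000, 70, 21000)
  b <- density_compare(70, 21000, 40, 9000)
  expect_equal(a$ratio, 1 / b$ratio)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("density_compare agrees with the exact conditional oracle on a seeded grid", {
  set.seed(99)
  for (i in 1:60) {
    c1 <- sample(0:500, 1)
    c2 <- sample(0:500, 1)
    l1 <- sample(5000:50000, 1)
    l2 <- sample(5000:50000, 1)
    if (c1 == 0 && c2 == 0) next
    p <- density_compare(c1, l1, c2, l2)$p_two_sided
    oracle <- fisher.test(matrix(c(c1, l1 - c1, c2, l2 - c2), 2,
                                 byrow = TRUE))$p.value
    expect_lte(abs(p - oracle), 0.01)
  }
})

test_that("GATC depletion counts from contig c_000000073417 bracket the reported P", {
  r <- density_compare(180, 36496, 32, 8923)
  expect_gt(r$ratio, 1)  # raw density is higher in the prophage
  expect_gte(r$p_two_sided, 0.08)
  expect_lte(r$p_two_sided, 0.13)
})

test_that("region density pools split host intervals and compares labels", {
  # GATC planted at known positions; host remainder split around the prophage
  seq <- paste(rep("ACGT", 500), collapse = "")   # no GATC
  seq <- paste0(substr(seq, 1, 100), "GATC", substr(seq, 105, 1000),
                "GATCGATC", substr(seq, 1109, 2000))
  regions <- data.frame(contig = "c", start = c(500L, 0L, 1200L),
                        end = c(1200L, 500L, nchar(seq)),
                        label = c("prophage", "host", "host"))
  r <- region_motif_density(seq, motif("GATC", 1, "6mA"), regions)
  expect_equal(sort(r$density$region_label), c("host", "prophage"))
  host_len <- 500 + (nchar(seq) - 1200)
  expect_equal(r$density$length_bp[r$density$region_label == "host"], host_len)
  expect_equal(sum(r$density$count), nrow(scan_motif(seq, motif("GATC", 1, "6mA"))))
})

test_that("motif_obs_exp expectation follows the mononucleotide model", {
  seq <- rand_seq(20000)
  oe <- motif_obs_exp(seq, motif("GATC", 1, "6mA"))
  # uniform composition: expected about 2 L / 256
  expect_lt(abs(oe$expected - 2 * (20000 - 3) / 256) / oe$expected, 0.1)
  expect_equal(oe$observed, nrow(scan_motif(seq, motif("GATC", 1, "6mA"))))
})

test_that("host matching scores: identical 1, disjoint 0, subsumption ranks first", {
  ids <- match_hosts(list(ph = c("GATC", "GANTC")),
                     list(h1 = c("GATC", "GANTC")))
  expect_equal(ids$score, 1)

  dis <- match_hosts(list(ph = "GATC"), list(h1 = "CCWGG"))
  expect_equal(dis$score, 0)

  r <- match_hosts(list(phage = "ACAY"),
                   list(other = "GATC", polaribacter = "ACAYNNNNNRTT"))
  expect_equal(r$host_id[1], "polaribacter")
  expect_gt(r$score[1], r$score[2])

  # symmetric in the two motif sets
  a <- match_hosts(list(x = c("GATC", "CCWGG")), list(y = "GATC"))$score
  b <- match_hosts(list(x = "GATC"), list(y = c("GATC", "CCWGG")))$score
  expect_equal(a, b)

  # ranking ties broken by host id
  tie <- match_hosts(list(p = "GATC"), list(b = "GATC", a = "GATC"))
  expect_equal(tie$host_id, c("a", "b"))
})

test_that("motif information weighting: concrete bases 2 bits, N contributes 0", {
  expect_equal(motif_information("GATC"), 8)
  expect_equal(motif_information("GANTC"), 8)
  expect_equal(motif_information("ACAYNNNNNRTT"), 5 * 2 + 2 * 1)
  expect_equal(motif_information("N"), 0)
})
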