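test_that("miS follows copies * hp * W / n with the documented W sensitivity", {
  toy <- toy_single_site()
  mt <- run_booking(toy$conditions, toy$sites, toy$params)
  # single booking: 2 copies, hp 0.02, 3' UTR (W = 1), n = 100
  expect_equal(mis(mt, "TXA")$mis, 2 * 0.02 * 1.0 / 100)
  expect_equal(mis(mt, "TXA", normalization = "total")$mis, 2 * 0.02)
  # relocate the booking to the CDS: exactly one tenth
  mt_cds <- mt
  mt_cds$bookings$region <- "cds"
  mt_cds$bookings$w <- 0.1
  expect_equal(mis(mt_cds, "TXA")$mis, mis(mt, "TXA")$mis / 10)
  expect_error(mis(mt, "NOPE"), "unknown transcript")
})

test_that("miS is zero iff a transcript has no bookings", {
  sys <- generate_system(fixture_spec(n_mirna = 2L, n_transcript = 4L,
                                      planted = data.frame(
                                        mirna = c(1L, 2L), transcript = c(1L, 2L),
                                        region = "three_prime_utr", mismatches = 0L),
                                      seed = 51L))
  sites <- candidate_sites(sys$conditions)
  mt <- run_booking(sys$conditions, sites)
  tab <- mis_table(mt)
  with_bookings <- unique(mt$bookings$transcript)
  expect_true(all(tab$mis[tab$transcript %in% with_bookings] > 0))
  expect_true(all(tab$mis[!tab$transcript %in% with_bookings] == 0))
})

test_that("miS is invariant to duplicating bookings while doubling n", {
  toy <- toy_single_site()
  mt <- run_booking(toy$conditions, toy$sites, toy$params)
  doubled <- mt
  doubled$bookings <- rbind(mt$bookings, mt$bookings)
  doubled$transcript_n["TXA"] <- 2 * mt$transcript_n["TXA"]
  expect_equal(mis(doubled, "TXA")$mis, mis(mt, "TXA")$mis)
})

test_that("overexpression forces abundance and is otherwise inert", {
  sys <- generate_system(fixture_spec(seed = 52L))
  cond <- sys$conditions
  up <- overexpress(cond, "mir-001", 100000)
  expect_equal(unname(up$mirna_abundance["mir-001"]), 100000)
  expect_equal(up$mirna_abundance[-1], cond$mirna_abundance[-1])
  expect_equal(up$transcript_abundance, cond$transcript_abundance)
  # idempotent no-op apart from the label
  same <- overexpress(cond, "mir-002", cond$mirna_abundance[["mir-002"]])
  expect_equal(same$mirna_abundance, cond$mirna_abundance)
  # knockout boundary
  ko <- overexpress(cond, "mir-001", 0)
  expect_equal(unname(ko$mirna_abundance["mir-001"]), 0)
  expect_error(overexpress(cond, "mir-999"), "mir-999")
})

test_that("an unexpressed miRNA with a known sequence can be overexpressed", {
  sys <- generate_system(fixture_spec(seed = 53L))
  cond <- sys$conditions
  cond$mirna_seq <- c(cond$mirna_seq, novel = "UCACAGUGGCUAAGUUCUGCAC")
  cond <- cell_conditions(cond$label, cond$mirna_abundance[names(cond$mirna_abundance) != "novel"],
                          cond$transcript_abundance, cond$mirna_seq, cond$transcripts)
  expect_equal(unname(cond$mirna_abundance["novel"]), 0)
  up <- overexpress(cond, "novel")
  expect_equal(unname(up$mirna_abundance["novel"]), 100000)
})

test_that("reporters join the condition at the requested copy number", {
  sys <- generate_system(fixture_spec(seed = 54L))
  utr <- strrep("AC", 60)
  cond <- add_reporter(sys$conditions, "luc", paste0(strrep("G", 30), utr), 0, 30)
  expect_equal(unname(cond$transcript_abundance["luc"]), 100)
  expect_error(add_reporter(cond, "luc", "ACGUACGUACGU", 0, 4), "already present")
  # a reporter with no candidate sites silences at exactly zero
  sites <- candidate_sites(cond)
  mt <- run_booking(cond, sites)
  if (!"luc" %in% mt$bookings$transcript) {
    expect_equal(mis(mt, "luc")$mis, 0)
  }
})

test_that("a planted reporter site responds to overexpression of its miRNA", {
  sys <- generate_system(fixture_spec(n_mirna = 2L, n_transcript = 2L, seed = 55L))
  cond <- sys$conditions
  mirna <- "mir-001"
  seed7 <- extract_seed(cond$mirna_seq[[mirna]])
  utr <- paste0(strrep("A", 40), reverse_complement(seed7), strrep("A", 40))
  cond <- add_reporter(cond, "luc-reporter", paste0(strrep("C", 30), utr), 0, 30,
                       copies = 100)
  cond$mirna_abundance[mirna] <- 0  # start from no copies of the miRNA
  vx <- virtual_overexpression(cond, mirna, 100000)
  sc <- vx$scores[vx$scores$transcript == "luc-reporter", ]
  expect_gt(sc$mis_after, sc$mis_before)
  expect_identical(sc$call, "positive")
})

test_that("downregulation calls use a strict miS increase", {
  s <- function(v) structure(list(transcript = "P", condition = "c", n = 30, mis = v),
                             class = "silencing_score")
  expect_identical(classify_downregulated(s(0.59), s(1.32)), "positive")
  expect_identical(classify_downregulated(s(1.0), s(1.0)), "negative")
  expect_identical(classify_downregulated(s(1.32), s(0.59)), "negative")
  s2 <- s(1); s2$transcript <- "Q"
  expect_error(classify_downregulated(s(1), s2), "different transcripts")
})
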