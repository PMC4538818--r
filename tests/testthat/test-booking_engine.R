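test_that("dilution factor is log_alpha with a clamp at one copy", {
  expect_equal(dilution_factor(512, 512), 1.0)
  expect_equal(dilution_factor(1, 512), 0.0)
  expect_equal(dilution_factor(0.2, 512), 0.0)
  expect_equal(dilution_factor(262144, 512), 2.0)  # 512^2
  expect_error(dilution_factor(10, alpha = 1), "alpha")
})

test_that("booking quantity applies the min(q_mre * dilution * hp, q_seed) rule", {
  expect_equal(booking_quantity(100, 512, hp = 0, alpha = 512), 0)
  expect_equal(booking_quantity(100, 512, hp = 0.02, alpha = 512), 2.0)
  expect_equal(booking_quantity(1e6, 512, hp = 1, alpha = 2), 512)  # capped by q(seed)
})

test_that("the single-site toy books exactly once", {
  toy <- toy_single_site()
  mt <- run_booking(toy$conditions, toy$sites, toy$params)
  expect_identical(nrow(mt$bookings), 1L)
  expect_equal(mt$bookings$copies, 2.0)
  expect_equal(unname(mt$residual["miR1"]), 510)
  expect_equal(unname(mt$transcript_bound["TXA"]), 2.0)
  expect_equal(occupancy(mt, "TXA"), 0.02)
  expect_true(isTRUE(verify_stability(mt, toy$conditions, toy$sites)))
})

test_that("no expressed miRNAs yields an empty microtargetome", {
  toy <- toy_single_site()
  toy$conditions$mirna_abundance["miR1"] <- 0
  mt <- run_booking(toy$conditions, toy$sites, toy$params)
  expect_identical(nrow(mt$bookings), 0L)
  expect_equal(occupancy(mt, "TXA"), 0)
})

test_that("id mismatches between sites and conditions are rejected", {
  toy <- toy_single_site()
  bad <- toy$sites; bad$transcript <- "GHOST"
  expect_error(run_booking(toy$conditions, bad, toy$params), "GHOST")
  bad2 <- toy$sites; bad2$hp <- 0.001
  expect_error(run_booking(toy$conditions, bad2, toy$params), "below params")
})

test_that("booking conserves miRNA copies and respects footprint capacity", {
  set.seed(41)
  for (i in 1:25) {
    inst <- random_instance()
    mt <- run_booking(inst$conditions, inst$sites, inst$params)
    expect_lt(conservation_error(mt, inst$conditions), 1e-6)
    expect_lte(footprint_excess(mt, inst$conditions), 1e-9)
  }
})

test_that("output is stable under the exhaustive no-improving-pair verifier", {
  set.seed(42)
  for (i in 1:60) {
    inst <- random_instance()
    mt <- run_booking(inst$conditions, inst$sites, inst$params)
    expect_true(isTRUE(verify_stability(mt, inst$conditions, inst$sites)))
  }
})

test_that("identical inputs produce byte-identical microtargetomes", {
  sys <- generate_system(fixture_spec(seed = 43L))
  sites <- candidate_sites(sys$conditions)
  mt1 <- run_booking(sys$conditions, sites)
  mt2 <- run_booking(sys$conditions, sites)
  expect_identical(mt1, mt2)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_microtargetome(mt1, f1)
  write_microtargetome(mt2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("footprint occlusion limits co-booking of overlapping sites", {
  # two sites 10 nt apart (overlapping 46-nt footprints) on a 100-copy
  # transcript; two abundant miRNAs with hp = 1 would each book 100 copies
  # if the sites were independent
  cond <- cell_conditions(
    "fp",
    mirna_abundance = c(m1 = 1e6, m2 = 1e6),
    transcript_abundance = c(T1 = 100),
    mirna_seq = c(m1 = strrep("ACGU", 6), m2 = strrep("CAGU", 6)),
    transcripts = data.frame(id = "T1", sequence = strrep("A", 200),
                             cds_start = 0, cds_end = 0))
  sites <- data.frame(transcript = "T1", position = c(50L, 60L),
                      mre = "AAAAAAA", region = "three_prime_utr", w = 1,
                      mirna = c("m1", "m2"), seed = c("CGUACGU", "AGUCAGU"),
                      mismatches = 0L, hp = c(0.9, 0.9),
                      stringsAsFactors = FALSE)
  mt <- run_booking(cond, sites, booking_params(alpha = 2))
  expect_lte(sum(mt$bookings$copies), 100 + 1e-9)
  # moved far apart, the sites decouple
  sites2 <- sites; sites2$position <- c(10L, 150L)
  mt2 <- run_booking(cond, sites2, booking_params(alpha = 2))
  expect_gt(sum(mt2$bookings$copies), sum(mt$bookings$copies))
})

test_that("raising a competing transcript never increases copies on the follower", {
  sys <- sponge_system()
  sites <- candidate_sites(sys$conditions)
  leader_grid <- seq(100, 6000, by = 590)
  bound_b <- numeric(length(leader_grid))
  for (i in seq_along(leader_grid)) {
    cond <- sys$conditions
    cond$transcript_abundance[[sys$leader]] <- leader_grid[i]
    mt <- run_booking(cond, sites)
    bound_b[i] <- sum(mt$bookings$copies[mt$bookings$transcript == sys$follower])
  }
  expect_true(all(diff(bound_b) <= 1e-9))
  expect_lt(bound_b[length(bound_b)], bound_b[1])  # the sponge really bites
})

test_that("the booked set is enriched in perfect duplexes relative to the candidates", {
  # equal availability of perfect and 1-mismatch sites: competition should
  # favour the high-HP perfect duplexes among booked copies
  set.seed(44)
  seed <- "UGGCAUC"
  perfect <- reverse_complement(seed)
  one_mm <- perfect
  substr(one_mm, 1, 1) <- setdiff(c("A", "C", "G", "U"), substr(perfect, 1, 1))[1]
  m <- energy_model()
  spacer <- function() paste(sample(c("A", "C"), 53, replace = TRUE), collapse = "")
  seqn <- paste0(spacer(), perfect, spacer(), one_mm, spacer(),
                 perfect, spacer(), one_mm, spacer())
  cond <- cell_conditions(
    "mix", mirna_abundance = c(mir = 300),
    transcript_abundance = stats::setNames(500, "T1"),
    mirna_seq = c(mir = paste0("A", seed, strrep("A", 14))),
    transcripts = data.frame(id = "T1", sequence = seqn,
                             cds_start = 0, cds_end = 0))
  tau_low <- 1e-4  # admit the 1-mismatch sites as candidates too
  sites <- candidate_sites(cond, m, tau = tau_low)
  expect_setequal(unique(sites$mismatches), c(0L, 1L))
  params <- booking_params(tau = tau_low, alpha = 512)
  mt <- run_booking(cond, sites, params)
  cand_perfect <- mean(sites$mismatches == 0)
  b <- merge(mt$bookings, sites[, c("transcript", "position", "mirna", "mismatches")],
             by = c("transcript", "position", "mirna"))
  booked_perfect <- sum(b$copies[b$mismatches == 0]) / sum(b$copies)
  expect_gt(booked_perfect, cand_perfect)
})
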