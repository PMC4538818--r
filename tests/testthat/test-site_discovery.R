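test_that("region labels follow the center-nucleotide, half-open convention", {
  # transcript of 100 nt, CDS = [20, 60)
  expect_identical(region_of(0L, 20, 60, 100), "five_prime_utr")
  expect_identical(region_of(30L, 20, 60, 100), "cds")
  expect_identical(region_of(80L, 20, 60, 100), "three_prime_utr")
  # window straddling cds_end with center exactly at cds_end -> 3' UTR
  expect_identical(region_of(57L, 20, 60, 100), "three_prime_utr")
  expect_identical(region_of(56L, 20, 60, 100), "cds")
  expect_error(region_of(94L, 20, 60, 100), "out of range")
  expect_equal(region_weight(c("cds", "three_prime_utr", "five_prime_utr")),
               c(0.1, 1.0, 0.1))
})

test_that("a planted perfect site is recovered at its position with w = 1", {
  set.seed(31)
  seed <- "UGGCAUC"
  bg <- paste(sample(c("A", "C"), 200, replace = TRUE), collapse = "")
  site <- reverse_complement(seed)
  sequence <- paste0(substr(bg, 1, 150), site, substr(bg, 158, 200))
  hits <- scan_transcript("TX1", sequence, 20, 100, c(mirA = seed),
                          tau = 0.0179)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 150L)
  expect_identical(hits$mismatches, 0L)
  expect_identical(hits$region, "three_prime_utr")
  expect_identical(hits$w, 1.0)
  expect_identical(hits$mirna, "mirA")
})

test_that("scanning agrees with an independent brute-force double loop", {
  set.seed(32)
  sequence <- paste(sample(c("A", "C", "G", "U"), 500, replace = TRUE), collapse = "")
  seeds <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = ""),
    character(1))
  names(seeds) <- sprintf("mir%d", 1:5)
  tau <- 0.0179
  m <- energy_model()
  got <- scan_transcript("TX", sequence, 100, 300, seeds, m, tau)

  brute <- list()
  for (p in 0:(500 - 7)) {
    win <- substr(sequence, p + 1, p + 7)
    for (k in seq_along(seeds)) {
      mm <- mismatch_count(seeds[[k]], win)
      hp <- hybridization_probability(seeds[[k]], win, m)
      if (mm <= 2 && hp >= tau) {
        brute[[length(brute) + 1]] <- data.frame(
          transcript = "TX", position = p, mre = win,
          region = region_of(p, 100, 300, 500),
          w = region_weight(region_of(p, 100, 300, 500)),
          mirna = names(seeds)[k], seed = seeds[[k]],
          mismatches = mm, hp = hp, stringsAsFactors = FALSE)
      }
    }
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$position, brute$mirna), ]
  rownames(brute) <- NULL
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("window count is length - 6 and short transcripts warn", {
  seeds <- c(mirA = "UGGCAUC")
  seq20 <- strrep("AC", 10)
  # uniform backend, tau below 1/16384 and the mismatch filter disabled:
  # every window is admitted, so the row count is the window count L - 6
  got <- scan_transcript("t", seq20, 0, 0, seeds, energy_model("uniform"),
                         tau = 1e-6, max_mismatches = 7L)
  expect_identical(nrow(got), 14L)
  expect_warning(out <- scan_transcript("t", "ACGUAC", 0, 0, seeds),
                 "shorter than 7")
  expect_identical(nrow(out), 0L)
})

test_that("raising tau never adds a site and filters hold exhaustively", {
  sys <- generate_system(fixture_spec(n_mirna = 3L, n_transcript = 3L, seed = 33L))
  taus <- c(0.005, 0.0179, 0.05, 0.2)
  sets <- lapply(taus, function(t) candidate_sites(sys$conditions, tau = t))
  for (i in seq_along(sets)) {
    expect_true(all(sets[[i]]$mismatches <= 2))
    expect_true(all(sets[[i]]$hp >= taus[i]))
    if (i > 1) {
      key <- function(s) paste(s$transcript, s$position, s$mirna)
      expect_true(all(key(sets[[i]]) %in% key(sets[[i - 1]])))
    }
  }
})

test_that("at the default tau all perfect duplexes pass but only a minority of 1-mismatch ones", {
  m <- energy_model()
  set.seed(34)
  frac1 <- numeric(20)
  for (i in 1:20) {
    seed <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
    hp <- hp_table(seed, m)[1, ]
    mm <- mismatch_count(seed, all_heptamers())
    expect_true(all(hp[mm == 0] >= 0.0179))     # perfect duplexes always admitted
    frac1[i] <- mean(hp[mm == 1] >= 0.0179)
  }
  expect_true(all(frac1 < 0.5))                 # 1-mismatch: a strict minority
  expect_gt(mean(frac1), 0)                     # but not none overall
})
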