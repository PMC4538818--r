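# Hand-built toy systems used across the suite. All fixtures are generated
# in code; nothing is read from disk except what a test itself writes.

# a condition with one miRNA (512 copies) and one transcript (100 copies)
# plus a single hand-specified candidate site of hp = 0.02 in the 3' UTR
toy_single_site <- function() {
  cond <- cell_conditions(
    "toy",
    mirna_abundance = c(miR1 = 512),
    transcript_abundance = c(TXA = 100),
    mirna_seq = c(miR1 = "AUGGCAUCGAUCGAUCGAUCGA"),
    transcripts = data.frame(id = "TXA",
                             sequence = strrep("A", 100),
                             cds_start = 10, cds_end = 50))
  sites <- data.frame(transcript = "TXA", position = 60L, mre = "GAUGCCA",
                      region = "three_prime_utr", w = 1.0, mirna = "miR1",
                      seed = "UGGCAUC", mismatches = 0L, hp = 0.02,
                      stringsAsFactors = FALSE)
  list(conditions = cond, sites = sites,
       params = booking_params(tau = 0.0179, alpha = 512))
}

# random small instance for stability / conservation property sweeps:
# <= n_mirna miRNAs x <= n_sites hand-made sites on <= 3 transcripts
random_instance <- function(n_mirna = 6L, n_sites = 6L) {
  nm <- sample(n_mirna, 1L)
  ns <- sample(n_sites, 1L)
  mirna_ids <- sprintf("m%02d", seq_len(nm))
  tx_ids <- sprintf("T%02d", seq_len(sample(3L, 1L)))
  cond <- cell_conditions(
    "rand",
    mirna_abundance = stats::setNames(round(exp(stats::runif(nm, log(2), log(5e4)))), mirna_ids),
    transcript_abundance = stats::setNames(round(exp(stats::runif(length(tx_ids), log(5), log(3e3)))), tx_ids),
    mirna_seq = stats::setNames(
      vapply(seq_len(nm), function(i)
        paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE), collapse = ""),
        character(1L)),
      mirna_ids),
    transcripts = data.frame(id = tx_ids, sequence = strrep("A", 400),
                             cds_start = 50, cds_end = 250))
  pos <- sample(seq(0L, 390L, by = 10L), ns)  # spaced, some footprints overlap
  tx <- sample(tx_ids, ns, replace = TRUE)
  mi <- sample(mirna_ids, ns, replace = TRUE)
  region <- region_of(pos, 50, 250, 400)
  sites <- data.frame(transcript = tx, position = pos, mre = "AAAAAAA",
                      region = region, w = region_weight(region), mirna = mi,
                      seed = "UUUUUUU",
                      mismatches = 0L,
                      hp = round(stats::runif(ns, 0.02, 0.9), 4),
                      stringsAsFactors = FALSE)
  sites <- sites[!duplicated(sites[, c("transcript", "position", "mirna")]), ]
  list(conditions = cond, sites = sites,
       params = booking_params(tau = 0.0179,
                               alpha = sample(c(2, 8, 512), 1L)))
}

conservation_error <- function(mt, conditions) {
  booked <- tapply(mt$bookings$copies, mt$bookings$mirna, sum)
  tot <- stats::setNames(rep(0, length(conditions$mirna_abundance)),
                         names(conditions$mirna_abundance))
  if (length(booked)) tot[names(booked)] <- booked
  max(abs(conditions$mirna_abundance - (mt$residual + tot)))
}

# max over transcripts and maximal cliques of mutually overlapping
# footprints of (booked copies - n); positive values break capacity.
# Footprints are intervals of equal length, so every maximal clique is the
# set of intervals covering the left endpoint of one of them.
footprint_excess <- function(mt, conditions) {
  b <- mt$bookings
  if (!nrow(b)) return(-Inf)
  fp <- mt$params$footprint
  worst <- -Inf
  for (tx in unique(b$transcript)) {
    d <- b[b$transcript == tx, ]
    n <- conditions$transcript_abundance[[tx]]
    for (i in seq_len(nrow(d))) {
      clique <- d$position > d$position[i] - fp & d$position <= d$position[i]
      worst <- max(worst, sum(d$copies[clique]) - n)
    }
  }
  worst
}
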