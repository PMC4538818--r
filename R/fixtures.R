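# Synthetic toy transcriptomes with planted seed-complementary sites and
# exact ground truth. All randomness in the package lives here, behind one
# seed; the simulator itself is deterministic.

#' Specify a synthetic system
#'
#' Describes a toy transcriptome: how many miRNAs and transcripts, their
#' abundance ranges (log-uniform draws, echoing the roughly log-normal
#' spread of real copy numbers), region geometry, and a list of planted
#' MREs. Background sequence is guaranteed free of accidental candidate
#' sites (no non-planted window within 2 mismatches of any seed), so the
#' manifest is the exact ground truth.
#'
#' @param n_mirna,n_transcript counts of species.
#' @param mirna_abundance_range,transcript_abundance_range log-uniform
#'   sampling ranges in copies/cell. Defaults span the observed ranges:
#'   tens to tens of thousands of copies for miRNAs, tens to thousands for
#'   mRNAs.
#' @param utr5_length,cds_length,utr3_length region lengths in nt (total
#'   transcript length is their sum).
#' @param planted data.frame with columns \code{mirna} (index),
#'   \code{transcript} (index), \code{region} ("five_prime_utr", "cds",
#'   "three_prime_utr"), \code{mismatches} (0-2) and optionally
#'   \code{offset} (0-based window start within the region; NA = draw at
#'   random). One site is planted per row. Fixed offsets allow footprint
#'   geometry to be controlled, e.g. to make two sites compete for the same
#'   occupancy pool.
#' @param seed RNG seed; the same spec and seed reproduce identical
#'   systems.
#' @return object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_mirna = 5L, n_transcript = 8L,
                         mirna_abundance_range = c(50, 50000),
                         transcript_abundance_range = c(10, 5000),
                         utr5_length = 50L, cds_length = 150L,
                         utr3_length = 300L,
                         planted = NULL, seed = 42L) {
  if (is.null(planted)) {
    planted <- data.frame(mirna = rep(seq_len(n_mirna), each = 2L)[seq_len(min(2L * n_mirna, n_transcript * 2L))],
                          transcript = rep_len(seq_len(n_transcript), min(2L * n_mirna, n_transcript * 2L)),
                          region = "three_prime_utr",
                          mismatches = 0L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("mirna", "transcript", "region", "mismatches") %in% names(planted)),
            all(planted$mirna >= 1 & planted$mirna <= n_mirna),
            all(planted$transcript >= 1 & planted$transcript <= n_transcript),
            all(planted$mismatches %in% 0:2),
            all(planted$region %in% c("five_prime_utr", "cds", "three_prime_utr")))
  region_len <- c(five_prime_utr = utr5_length, cds = cds_length,
                  three_prime_utr = utr3_length)
  if (any(region_len[planted$region] < 7L)) {
    stop("a planted site does not fit inside its region", call. = FALSE)
  }
  structure(list(n_mirna = n_mirna, n_transcript = n_transcript,
                 mirna_abundance_range = mirna_abundance_range,
                 transcript_abundance_range = transcript_abundance_range,
                 utr5_length = as.integer(utr5_length),
                 cds_length = as.integer(cds_length),
                 utr3_length = as.integer(utr3_length),
                 planted = planted, seed = as.integer(seed)),
            class = "fixture_spec")
}

.random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

# mutate `k` distinct positions of a 7-mer to non-WC, non-original bases
.mutate_site <- function(site, k) {
  if (k == 0L) return(site)
  s <- strsplit(site, "")[[1L]]
  pos <- sample(7L, k)
  for (p in pos) {
    s[p] <- sample(setdiff(RNA_BASES, s[p]), 1L)
  }
  paste(s, collapse = "")
}

#' Generate a synthetic system in memory
#'
#' Draws sequences and abundances per the spec, plants the requested sites,
#' scrubs the background of accidental candidate windows, and returns the
#' ready-to-run condition plus the ground-truth manifest.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{conditions} (\code{\link{cell_conditions}}),
#'   \code{manifest} (data.frame mirna, transcript, position, region,
#'   mismatches, mre) and \code{spec}.
#' @export
generate_system <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  # a freshly drawn background can (rarely) contain a window that overlaps
  # a planted site and stays seed-complementary whatever its free bases
  # are; such draws are rejected wholesale and re-drawn from a seed that is
  # a fixed function of spec$seed, so the output is still deterministic
  for (attempt in 0:49) {
    sys <- tryCatch(.build_system(spec, spec$seed + attempt * 100003L),
                    mirbooking_scrub_failure = function(e) NULL)
    if (!is.null(sys)) return(sys)
  }
  stop("could not generate a clean background for this fixture spec", call. = FALSE)
}

.build_system <- function(spec, rng_seed) {
  set.seed(rng_seed)
  mirna_ids <- sprintf("mir-%03d", seq_len(spec$n_mirna))
  tx_ids <- sprintf("TX%04d", seq_len(spec$n_transcript))
  mirna_seq <- stats::setNames(
    vapply(seq_len(spec$n_mirna), function(i) .random_rna(22L), character(1L)),
    mirna_ids)
  seeds <- vapply(mirna_ids, function(m) extract_seed(mirna_seq[[m]], m),
                  character(1L))
  logu <- function(n, range) exp(stats::runif(n, log(range[1L]), log(range[2L])))
  mirna_ab <- stats::setNames(round(logu(spec$n_mirna, spec$mirna_abundance_range)),
                              mirna_ids)
  tx_ab <- stats::setNames(round(logu(spec$n_transcript, spec$transcript_abundance_range)),
                           tx_ids)
  L <- spec$utr5_length + spec$cds_length + spec$utr3_length
  cds_start <- spec$utr5_length
  cds_end <- spec$utr5_length + spec$cds_length
  region_bounds <- list(five_prime_utr = c(0L, cds_start),
                        cds = c(cds_start, cds_end),
                        three_prime_utr = c(cds_end, L))

  sequences <- vapply(tx_ids, function(t) .random_rna(L), character(1L))
  manifest <- list()
  planted_at <- lapply(tx_ids, function(t) integer())  # window starts per tx
  names(planted_at) <- tx_ids

  for (r in seq_len(nrow(spec$planted))) {
    p <- spec$planted[r, ]
    tx <- tx_ids[p$transcript]
    mi <- mirna_ids[p$mirna]
    site <- .mutate_site(reverse_complement(seeds[[mi]]), p$mismatches)
    b <- region_bounds[[p$region]]
    # center rule: the window's center (start + 3) must fall in the region;
    # constraining the whole window inside the region is stricter and keeps
    # the label unambiguous. Avoid overlap with previously planted windows.
    cand <- b[1L]:(b[2L] - 7L)
    taken <- planted_at[[tx]]
    # >= 13 nt apart so no 7-nt window can overlap two plants at once,
    # which keeps the background scrub able to repair every accidental hit
    ok <- cand[vapply(cand, function(x) all(abs(x - taken) >= 13L), logical(1L))]
    if ("offset" %in% names(spec$planted) && !is.na(p$offset)) {
      start <- b[1L] + p$offset
      if (!(start %in% ok)) {
        stop(sprintf("planted site %d: offset %d is out of region bounds or too close (< 13 nt) to another plant",
                     r, p$offset), call. = FALSE)
      }
    } else {
      if (!length(ok)) {
        stop(sprintf("no room to plant site %d in %s/%s", r, tx, p$region),
             call. = FALSE)
      }
      start <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    substr(sequences[[tx]], start + 1L, start + 7L) <- site
    planted_at[[tx]] <- c(taken, start)
    manifest[[r]] <- data.frame(mirna = mi, transcript = tx, position = start,
                                region = p$region, mismatches = p$mismatches,
                                mre = site, stringsAsFactors = FALSE)
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(mirna = character(), transcript = character(),
               position = integer(), region = character(),
               mismatches = integer(), mre = character())

  # scrub accidental sites: any non-planted window within 2 mismatches of
  # any seed gets one of its free nucleotides resampled, repeatedly
  for (t in tx_ids) {
    sequences[[t]] <- .scrub_background(sequences[[t]], seeds,
                                        planted_at[[t]], t)
  }

  transcripts <- data.frame(id = tx_ids, sequence = unname(sequences),
                            cds_start = cds_start, cds_end = cds_end,
                            stringsAsFactors = FALSE)
  conditions <- cell_conditions(sprintf("fixture-seed%d", spec$seed),
                                mirna_ab, tx_ab, mirna_seq, transcripts)
  list(conditions = conditions, manifest = manifest, spec = spec)
}

# resample background nucleotides until no non-planted window is within
# 2 mismatches of any seed; planted 7-mers are never touched. Flips target
# free positions that still Watson-Crick pair with the seed, so each flip
# strictly raises that window's mismatch count.
.scrub_background <- function(sequence, seeds, planted_starts, tx_id,
                              max_iter = 200L) {
  L <- nchar(sequence)
  if (L < 7L) return(sequence)
  protected <- unique(unlist(lapply(planted_starts, function(s) s:(s + 6L))))
  wc_partner <- c(A = "U", C = "G", G = "C", U = "A")
  for (iter in seq_len(max_iter)) {
    starts <- 0:(L - 7L)
    windows <- substring(sequence, starts + 1L, starts + 7L)
    widx <- heptamer_index(windows)
    clean <- TRUE
    for (sd in unique(unname(seeds))) {
      mm <- .mismatch_profile(sd)[widx]
      offending <- starts[mm <= 2L & !(starts %in% planted_starts)]
      if (!length(offending)) next
      clean <- FALSE
      sdv <- strsplit(sd, "")[[1L]]
      for (st in offending) {
        free <- setdiff(st:(st + 6L), protected)
        if (!length(free)) next
        # window index k (0-based) faces seed position 7 - k (1-based)
        partner <- wc_partner[sdv[7L - (free - st)]]
        cur <- substring(sequence, free + 1L, free + 1L)
        matching <- free[cur == partner]
        p <- if (length(matching)) matching[1L] else free[1L]
        bad <- unique(c(substr(sequence, p + 1L, p + 1L),
                        wc_partner[[sdv[7L - (p - st)]]]))
        choices <- setdiff(RNA_BASES, bad)
        pick <- if (length(choices) == 1L) choices else sample(choices, 1L)
        substr(sequence, p + 1L, p + 1L) <- pick
      }
    }
    if (clean) return(sequence)
  }
  cond <- structure(class = c("mirbooking_scrub_failure", "error", "condition"),
                    list(message = sprintf(
                      "could not scrub accidental sites from transcript '%s' within %d iterations",
                      tx_id, max_iter), call = NULL))
  stop(cond)
}

#' Write a synthetic system to disk
#'
#' Produces the five input files a run consumes (miRNA/mRNA FASTA, BED4
#' regions, two expression TSVs), a ground-truth \code{manifest.json}, and
#' a ready-made \code{run.yaml}.
#'
#' @param system output of \code{\link{generate_system}} (or a
#'   \code{\link{fixture_spec}}, which is generated first).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_fixture <- function(system, dir) {
  if (inherits(system, "fixture_spec")) system <- generate_system(system)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cond <- system$conditions
  write_fasta(cond$mirna_seq, file.path(dir, "mirna.fa"))
  write_fasta(stats::setNames(cond$transcripts$sequence, cond$transcripts$id),
              file.path(dir, "mrna.fa"))
  utils::write.table(
    data.frame(cond$transcripts$id, cond$transcripts$cds_start,
               cond$transcripts$cds_end, cond$transcripts$id),
    file.path(dir, "regions.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_expression(cond$mirna_abundance, file.path(dir, "mirna_expression.tsv"))
  write_expression(cond$transcript_abundance, file.path(dir, "mrna_expression.tsv"))
  jsonlite::write_json(system$manifest, file.path(dir, "manifest.json"),
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(list(label = cond$label,
                        mirna_fasta = "mirna.fa", mrna_fasta = "mrna.fa",
                        regions_bed = "regions.bed",
                        mirna_expression = "mirna_expression.tsv",
                        mrna_expression = "mrna_expression.tsv",
                        energy_backend = "nearest-neighbor"),
                   file.path(dir, "run.yaml"))
  invisible(dir)
}

#' Build the classic two-transcript sponge system
#'
#' One limiting miRNA with perfect 3' UTR sites on both a leader and a
#' follower transcript: raising the leader's abundance sequesters miRNA
#' copies and relieves the follower. Used throughout the tests for the
#' ceRNA (sponge) direction checks.
#'
#' @param mirna_copies abundance of the shared miRNA.
#' @param leader_copies,follower_copies transcript abundances.
#' @param seed RNG seed for the background sequence.
#' @return list as in \code{\link{generate_system}}.
#' @export
sponge_system <- function(mirna_copies = 2000, leader_copies = 500,
                          follower_copies = 200, seed = 7L) {
  spec <- fixture_spec(n_mirna = 1L, n_transcript = 2L,
                       planted = data.frame(mirna = 1L, transcript = 1:2,
                                            region = "three_prime_utr",
                                            mismatches = 0L),
                       seed = seed)
  sys <- generate_system(spec)
  sys$conditions$mirna_abundance[] <- mirna_copies
  sys$conditions$transcript_abundance[] <- c(leader_copies, follower_copies)
  sys$leader <- "TX0001"
  sys$follower <- "TX0002"
  sys
}

#' Build the three-transcript indirect-propagation chain
#'
#' Transcript A shares miRNA 1 with the bridge X, X shares miRNA 2 with B,
#' and A and B share no miRNA. On X the two sites sit 20 nt apart, inside
#' one RISC footprint, so they draw on the same occupancy pool: sponging
#' miRNA 1 away from X (by raising A) frees capacity that miRNA 2 then
#' fills, depleting what reaches B. A's abundance therefore measurably
#' moves B's miS without any shared miRNA.
#'
#' @param seed RNG seed for the background sequence.
#' @return list as in \code{\link{generate_system}}, with \code{leader}
#'   ("A" end), \code{bridge} and \code{follower} ids.
#' @export
chain_system <- function(seed = 11L) {
  spec <- fixture_spec(
    n_mirna = 2L, n_transcript = 3L,
    planted = data.frame(mirna = c(1L, 1L, 2L, 2L),
                         transcript = c(1L, 2L, 2L, 3L),
                         region = "three_prime_utr", mismatches = 0L,
                         offset = c(NA, 100L, 120L, NA)),
    seed = seed)
  sys <- generate_system(spec)
  # miRNA 2 is kept scarce so the follower's booking is not saturated and
  # the propagated change is visible in its miS
  sys$conditions$mirna_abundance[] <- c(3000, 600)
  sys$conditions$transcript_abundance[] <- c(500, 400, 300)
  sys$leader <- "TX0001"; sys$bridge <- "TX0002"; sys$follower <- "TX0003"
  sys
}
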