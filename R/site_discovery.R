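# Enumeration of candidate MREs: every 7-nt transcript window a seed could
# book, with region labels, location weights W, mismatch counts and HPs.

#' Region of a 7-nt window on an annotated transcript
#'
#' A window is labelled by the region containing its center nucleotide
#' (start + 3, 0-based); this gives every site a single unambiguous label
#' even when the window straddles a CDS boundary. Regions follow the
#' half-open convention: 5' UTR = [0, cds_start), CDS = [cds_start,
#' cds_end), 3' UTR = [cds_end, length).
#'
#' @param position 0-based start(s) of the window.
#' @param cds_start,cds_end 0-based half-open CDS offsets.
#' @param length transcript length in nt.
#' @return character vector over \{"five_prime_utr", "cds",
#'   "three_prime_utr"\}.
#' @export
region_of <- function(position, cds_start, cds_end, length) {
  if (any(position < 0 | position > length - 7L)) {
    stop("window start out of range for a 7-nt window", call. = FALSE)
  }
  center <- position + 3L
  ifelse(center < cds_start, "five_prime_utr",
         ifelse(center < cds_end, "cds", "three_prime_utr"))
}

#' Location weight W of a region
#'
#' W = 1.0 in the 3' UTR and W = 0.1 in the 5' UTR or CDS, reflecting the
#' much stronger silencing contribution of 3' UTR sites.
#'
#' @param region region label(s) as returned by \code{\link{region_of}}.
#' @return numeric vector of weights.
#' @export
region_weight <- function(region) {
  ifelse(region == "three_prime_utr", 1.0, 0.1)
}

#' Scan a transcript for candidate miRNA recognition elements
#'
#' Slides a 7-nt window over the transcript (length - 6 windows) and
#' retains, for every seed, the windows that are complementary with at most
#' two mismatches AND whose hybridization probability reaches the admission
#' threshold tau. Both filters are applied conjunctively.
#'
#' @param id transcript id.
#' @param sequence transcript sequence (RNA letters).
#' @param cds_start,cds_end 0-based half-open CDS offsets.
#' @param seeds named character vector: miRNA id -> seed heptamer.
#' @param model an \code{\link{energy_model}}.
#' @param tau HP admission threshold in (0, 1).
#' @param max_mismatches complementarity filter (default 2).
#' @param hp_matrix optional precomputed \code{\link{hp_table}} for
#'   \code{seeds} (rows named by seed heptamer), to avoid recomputation when
#'   scanning many transcripts.
#' @return data.frame of candidate (site, seed) pairs with columns
#'   \code{transcript}, \code{position} (0-based window start), \code{mre},
#'   \code{region}, \code{w}, \code{mirna}, \code{seed}, \code{mismatches},
#'   \code{hp}, ordered by position. Zero rows (with a warning) when the
#'   transcript is shorter than 7 nt.
#' @export
scan_transcript <- function(id, sequence, cds_start, cds_end, seeds,
                            model = energy_model(), tau = 0.0179,
                            max_mismatches = 2L, hp_matrix = NULL) {
  stopifnot(tau > 0, tau < 1, !is.null(names(seeds)))
  sequence <- as_rna(sequence, sprintf("transcript '%s'", id))
  L <- nchar(sequence)
  empty <- data.frame(transcript = character(), position = integer(),
                      mre = character(), region = character(), w = numeric(),
                      mirna = character(), seed = character(),
                      mismatches = integer(), hp = numeric(),
                      stringsAsFactors = FALSE)
  if (L < 7L) {
    warning(sprintf("transcript '%s' is shorter than 7 nt; no windows to scan", id))
    return(empty)
  }
  starts <- 0:(L - 7L)
  windows <- substring(sequence, starts + 1L, starts + 7L)
  widx <- heptamer_index(windows)
  regions <- region_of(starts, cds_start, cds_end, L)
  if (is.null(hp_matrix)) hp_matrix <- hp_table(unique(unname(seeds)), model)
  out <- vector("list", length(seeds))
  for (k in seq_along(seeds)) {
    sd <- seeds[[k]]
    mm <- .mismatch_profile(sd)[widx]
    hp <- hp_matrix[sd, ][widx]
    keep <- mm <= max_mismatches & hp >= tau
    if (!any(keep)) next
    out[[k]] <- data.frame(transcript = id, position = starts[keep],
                           mre = windows[keep], region = regions[keep],
                           w = region_weight(regions[keep]),
                           mirna = names(seeds)[k], seed = sd,
                           mismatches = mm[keep], hp = hp[keep],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$mirna), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Candidate sites for every transcript of a condition
#'
#' @param conditions a \code{\link{cell_conditions}} object.
#' @param model an \code{\link{energy_model}}.
#' @param tau HP admission threshold.
#' @param max_mismatches complementarity filter.
#' @return data.frame as in \code{\link{scan_transcript}}, covering all
#'   transcripts, ordered by transcript then position.
#' @export
candidate_sites <- function(conditions, model = energy_model(), tau = 0.0179,
                            max_mismatches = 2L) {
  stopifnot(inherits(conditions, "cell_conditions"))
  seeds <- vapply(names(conditions$mirna_seq), function(m)
    extract_seed(conditions$mirna_seq[[m]], m), character(1L))
  hpm <- hp_table(unique(unname(seeds)), model)
  tx <- conditions$transcripts
  res <- lapply(seq_len(nrow(tx)), function(i)
    scan_transcript(tx$id[i], tx$sequence[i], tx$cds_start[i], tx$cds_end[i],
                    seeds, model, tau, max_mismatches, hp_matrix = hpm))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a candidate-site dump as TSV
#'
#' Columns: transcript, position, region, seed_mirna, mismatches, hp.
#'
#' @param sites data.frame from \code{\link{candidate_sites}}.
#' @param path output file.
#' @export
write_sites <- function(sites, path) {
  df <- data.frame(transcript = sites$transcript, position = sites$position,
                   region = sites$region, seed_mirna = sites$mirna,
                   mismatches = sites$mismatches,
                   hp = formatC(sites$hp, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
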