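# Per-gene miRNA-induced silencing (miS) scores and virtual
# overexpression / reporter experiments.

#' miRNA-induced silencing score of a transcript
#'
#' Sums, over all bookings on the transcript, the booked copies weighted by
#' the duplex HP and the MRE location factor W (1.0 in the 3' UTR, 0.1 in
#' the 5' UTR or CDS). With the default per-copy normalization the sum is
#' divided by the transcript abundance n, making scores comparable across
#' expression levels; \code{normalization = "total"} reports the raw sum.
#' miS is a relative score: it is not calibrated to experimental
#' fold-changes.
#'
#' @param mt a \code{microtargetome}.
#' @param transcript transcript id.
#' @param normalization "per-copy" (divide by n) or "total".
#' @param n transcript abundance; defaults to the abundance recorded at run
#'   time.
#' @return a list of class \code{silencing_score} with fields
#'   \code{transcript}, \code{condition}, \code{n}, \code{mis}.
#' @export
mis <- function(mt, transcript, normalization = c("per-copy", "total"),
                n = NULL) {
  stopifnot(inherits(mt, "microtargetome"))
  normalization <- match.arg(normalization)
  if (!transcript %in% names(mt$transcript_n)) {
    stop(sprintf("unknown transcript '%s'", transcript), call. = FALSE)
  }
  if (is.null(n)) n <- mt$transcript_n[[transcript]]
  if (n <= 0) stop(sprintf("miS of '%s' is undefined: n = 0", transcript), call. = FALSE)
  b <- mt$bookings[mt$bookings$transcript == transcript, , drop = FALSE]
  total <- sum(b$copies * b$hp * b$w)
  score <- if (normalization == "per-copy") total / n else total
  structure(list(transcript = transcript, condition = mt$condition,
                 n = n, mis = score), class = "silencing_score")
}

#' @export
print.silencing_score <- function(x, ...) {
  cat(sprintf("miS_%s(%s_%g) = %.6g\n", x$condition, x$transcript, x$n, x$mis))
  invisible(x)
}

#' miS scores for every transcript of a run
#'
#' @inheritParams mis
#' @return data.frame with columns \code{transcript}, \code{n}, \code{mis}.
#' @export
mis_table <- function(mt, normalization = c("per-copy", "total")) {
  normalization <- match.arg(normalization)
  ids <- names(mt$transcript_n)
  ids <- ids[mt$transcript_n[ids] > 0]
  data.frame(transcript = ids,
             n = unname(mt$transcript_n[ids]),
             mis = vapply(ids, function(t)
               mis(mt, t, normalization)$mis, numeric(1L)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Force the abundance of a miRNA (virtual overexpression / knockout)
#'
#' Returns new conditions with the miRNA set to \code{copies}; everything
#' else is untouched. The miRNA need not be expressed already, but its
#' mature sequence must be known. \code{copies = 0} amounts to a knockout.
#'
#' @param conditions a \code{\link{cell_conditions}} object.
#' @param mirna miRNA id.
#' @param copies forced abundance (default 100,000 copies, the standard
#'   virtual-overexpression level).
#' @return modified \code{cell_conditions}.
#' @export
overexpress <- function(conditions, mirna, copies = 100000) {
  stopifnot(inherits(conditions, "cell_conditions"), copies >= 0)
  if (!mirna %in% names(conditions$mirna_seq)) {
    stop(sprintf("no mature sequence known for miRNA '%s'", mirna), call. = FALSE)
  }
  conditions$mirna_abundance[[mirna]] <- copies
  conditions$label <- sprintf("%s+%s@%g", conditions$label, mirna, copies)
  conditions
}

#' Add a reporter transcript to a condition
#'
#' Extends the condition with an exogenous transcript (e.g. a luciferase
#' reporter carrying a 3' UTR of interest) at a fixed copy number, 100 by
#' default.
#'
#' @param conditions a \code{\link{cell_conditions}} object.
#' @param id reporter transcript id (must not collide).
#' @param sequence reporter sequence (RNA letters).
#' @param cds_start,cds_end 0-based half-open CDS offsets of the reporter.
#' @param copies reporter abundance.
#' @return modified \code{cell_conditions}.
#' @export
add_reporter <- function(conditions, id, sequence, cds_start, cds_end,
                         copies = 100) {
  stopifnot(inherits(conditions, "cell_conditions"))
  if (id %in% conditions$transcripts$id || id %in% names(conditions$transcript_abundance)) {
    stop(sprintf("transcript id '%s' already present", id), call. = FALSE)
  }
  sequence <- as_rna(sequence, sprintf("reporter '%s'", id))
  stopifnot(cds_start >= 0, cds_start <= cds_end, cds_end <= nchar(sequence))
  conditions$transcripts <- rbind(conditions$transcripts,
                                  data.frame(id = id, sequence = sequence,
                                             cds_start = cds_start,
                                             cds_end = cds_end,
                                             stringsAsFactors = FALSE))
  conditions$transcript_abundance <- c(conditions$transcript_abundance,
                                       stats::setNames(copies, id))
  conditions
}

#' Call downregulation from a before/after pair of miS scores
#'
#' A perturbation is called positive (downregulating) when it strictly
#' increases the silencing score of the transcript.
#'
#' @param before,after \code{silencing_score} objects for the same
#'   transcript.
#' @return "positive" or "negative".
#' @export
classify_downregulated <- function(before, after) {
  stopifnot(inherits(before, "silencing_score"), inherits(after, "silencing_score"))
  if (before$transcript != after$transcript) {
    stop(sprintf("scores refer to different transcripts ('%s' vs '%s')",
                 before$transcript, after$transcript), call. = FALSE)
  }
  if (after$mis > before$mis) "positive" else "negative"
}

#' Paired virtual-overexpression experiment
#'
#' Runs the booking simulation before and after forcing a miRNA's
#' abundance, and reports per-transcript miS pairs with downregulation
#' calls.
#'
#' @param conditions base \code{\link{cell_conditions}}.
#' @param mirna miRNA id to overexpress.
#' @param copies forced abundance.
#' @param model energy model used to enumerate sites.
#' @param params \code{\link{booking_params}}.
#' @param sites_before optional precomputed candidate sites of the base
#'   condition (reused for the perturbed run when the miRNA is already part
#'   of the condition's seed set).
#' @return list with \code{before}, \code{after} (microtargetomes) and
#'   \code{scores} (data.frame transcript, n, mis_before, mis_after, call).
#' @export
virtual_overexpression <- function(conditions, mirna, copies = 100000,
                                   model = energy_model(),
                                   params = booking_params(),
                                   sites_before = NULL) {
  if (is.null(sites_before)) {
    sites_before <- candidate_sites(conditions, model, params$tau)
  }
  cond2 <- overexpress(conditions, mirna, copies)
  mt1 <- run_booking(conditions, sites_before, params)
  mt2 <- run_booking(cond2, sites_before, params)
  ids <- names(conditions$transcript_abundance)
  ids <- ids[conditions$transcript_abundance[ids] > 0]
  sc <- data.frame(
    transcript = ids,
    n = unname(conditions$transcript_abundance[ids]),
    mis_before = vapply(ids, function(t) mis(mt1, t)$mis, numeric(1L)),
    mis_after = vapply(ids, function(t) mis(mt2, t)$mis, numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  sc$call <- ifelse(sc$mis_after > sc$mis_before, "positive", "negative")
  list(before = mt1, after = mt2, scores = sc)
}
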