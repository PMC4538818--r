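# Conversion of relative expression measurements into absolute copies/cell
# and assembly of cell-condition objects.

# median over strictly positive values; even length = mean of central pair
.positive_median <- function(x) {
  x <- x[x > 0]
  if (!length(x)) stop("no positive values", call. = FALSE)
  stats::median(x)
}

#' Calibrate relative miRNA intensities to absolute copies per cell
#'
#' Applies the monotone log-affine map y = exp(a*log(x) + b), with a and b
#' solved in closed form so that the input's median (over strictly positive
#' values; even length = mean of the two central order statistics) maps to
#' \code{median_target} and the input's maximum maps to \code{max_target}.
#' The default anchors (633 and 52,567 copies/cell) are the median and
#' maximum miRNA copy numbers measured by absolute quantification in liver
#' samples. Zeros are treated as "not expressed" and pass through
#' unchanged; they are excluded from the median. Because the map is
#' monotone, the output median hits the anchor exactly whenever the input
#' median is an observed value (always for odd-length vectors).
#'
#' @param values named numeric vector of non-negative relative intensities.
#' @param median_target,max_target anchors in copies/cell.
#' @return numeric vector of absolute abundances, names preserved.
#' @export
calibrate_mirna <- function(values, median_target = 633, max_target = 52567) {
  stopifnot(is.numeric(values), all(values >= 0))
  pos <- values[values > 0]
  if (length(unique(pos)) < 2L) {
    stop("calibration needs at least two distinct positive values; the log-affine map is undefined",
         call. = FALSE)
  }
  med_in <- .positive_median(values)
  max_in <- max(pos)
  if (med_in == max_in) {
    stop("input median equals input maximum; the log-affine map is undefined",
         call. = FALSE)
  }
  # 2x2 linear system in log space: the input median maps to the median
  # anchor and the input maximum to the maximum anchor
  a <- (log(max_target) - log(median_target)) / (log(max_in) - log(med_in))
  b <- log(max_target) - a * log(max_in)
  out <- values
  out[values > 0] <- exp(a * log(values[values > 0]) + b)
  out
}

#' Calibrate relative mRNA intensities against an absolute reference
#'
#' Affine map in log space matching the mean and standard deviation of the
#' log-transformed positive values to those of the reference table. Zeros
#' pass through unchanged.
#'
#' @param values named numeric vector of non-negative relative intensities.
#' @param reference numeric vector of absolute abundances defining the
#'   target log-mean and log-sd.
#' @return numeric vector of absolute abundances, names preserved.
#' @export
calibrate_mrna <- function(values, reference) {
  stopifnot(is.numeric(values), all(values >= 0),
            is.numeric(reference), all(reference >= 0))
  lx <- log(values[values > 0])
  lr <- log(reference[reference > 0])
  if (length(lx) < 2L || stats::sd(lx) == 0) {
    stop("input has zero variance on the log scale; the affine map is undefined",
         call. = FALSE)
  }
  if (length(lr) < 2L || stats::sd(lr) == 0) {
    stop("reference has zero variance on the log scale", call. = FALSE)
  }
  z <- (lx - mean(lx)) / stats::sd(lx)
  out <- values
  out[values > 0] <- exp(z * stats::sd(lr) + mean(lr))
  out
}

#' Remove between-array offsets using control genes
#'
#' Shifts every table by a single additive constant in log space so that the
#' mean log expression of the control genes (GAPDH and ACTB by default)
#' matches the first table, which serves as the anchor.
#'
#' @param tables list of named numeric vectors (positive control values
#'   required in each).
#' @param control_ids identifiers of the control genes.
#' @return list of realigned numeric vectors.
#' @export
realign_arrays <- function(tables, control_ids = c("GAPDH", "ACTB")) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  ctrl_mean <- function(tab, i) {
    miss <- setdiff(control_ids, names(tab))
    if (length(miss)) {
      stop(sprintf("table %d is missing control gene(s): %s", i,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    v <- tab[control_ids]
    if (any(v <= 0)) {
      stop(sprintf("table %d has non-positive control gene values", i),
           call. = FALSE)
    }
    mean(log(v))
  }
  anchor <- ctrl_mean(tables[[1L]], 1L)
  lapply(seq_along(tables), function(i) {
    tab <- tables[[i]]
    shift <- anchor - ctrl_mean(tab, i)
    out <- tab
    out[tab > 0] <- exp(log(tab[tab > 0]) + shift)
    out
  })
}

#' Choose the representative transcript of a gene
#'
#' When several transcripts map to the same gene, the one with the longest
#' 3' UTR is used; ties are broken lexicographically by transcript id so the
#' choice is deterministic.
#'
#' @param transcripts data.frame with columns \code{id} and either
#'   \code{utr3_length} or (\code{cds_end}, \code{length}) from which the
#'   3' UTR length is derived.
#' @return the selected transcript id.
#' @export
select_transcript <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) >= 1L)
  if (!"utr3_length" %in% names(transcripts)) {
    stopifnot(all(c("cds_end", "length") %in% names(transcripts)))
    transcripts$utr3_length <- transcripts$length - transcripts$cds_end
  }
  ord <- order(-transcripts$utr3_length, transcripts$id)
  transcripts$id[ord[1L]]
}

#' Assemble a cell condition
#'
#' A condition bundles everything a booking run needs: absolute miRNA and
#' transcript abundances (copies/cell), the mature miRNA sequences, and the
#' transcript sequences with their CDS boundaries (0-based half-open
#' offsets; the 5' UTR is [0, cds_start), the CDS [cds_start, cds_end), the
#' 3' UTR [cds_end, length)).
#'
#' @param label condition name (e.g. a cell line).
#' @param mirna_abundance named numeric vector, copies/cell.
#' @param transcript_abundance named numeric vector, copies/cell.
#' @param mirna_seq named character vector of mature miRNA sequences.
#' @param transcripts data.frame with columns \code{id}, \code{sequence},
#'   \code{cds_start}, \code{cds_end}.
#' @return an object of class \code{cell_conditions}.
#' @export
cell_conditions <- function(label, mirna_abundance, transcript_abundance,
                            mirna_seq, transcripts) {
  stopifnot(is.numeric(mirna_abundance), !is.null(names(mirna_abundance)),
            is.numeric(transcript_abundance), !is.null(names(transcript_abundance)),
            is.character(mirna_seq), !is.null(names(mirna_seq)),
            is.data.frame(transcripts),
            all(c("id", "sequence", "cds_start", "cds_end") %in% names(transcripts)))
  if (any(mirna_abundance < 0) || any(transcript_abundance < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  if (anyDuplicated(names(mirna_abundance)) || anyDuplicated(names(transcript_abundance))) {
    stop("duplicate ids in abundance tables", call. = FALSE)
  }
  orphan_mi <- setdiff(names(mirna_abundance), names(mirna_seq))
  if (length(orphan_mi)) {
    stop(sprintf("miRNA(s) without a mature sequence: %s",
                 paste(orphan_mi, collapse = ", ")), call. = FALSE)
  }
  orphan_tx <- setdiff(names(transcript_abundance), transcripts$id)
  if (length(orphan_tx)) {
    stop(sprintf("transcript(s) without sequence/annotation: %s",
                 paste(orphan_tx, collapse = ", ")), call. = FALSE)
  }
  transcripts$sequence <- as_rna(transcripts$sequence, "transcript sequence")
  L <- nchar(transcripts$sequence)
  ok <- transcripts$cds_start >= 0 & transcripts$cds_start <= transcripts$cds_end &
    transcripts$cds_end <= L
  if (!all(ok)) {
    stop(sprintf("inconsistent CDS bounds for transcript(s): %s",
                 paste(transcripts$id[!ok], collapse = ", ")), call. = FALSE)
  }
  nm <- names(mirna_seq)
  mirna_seq <- vapply(seq_along(mirna_seq), function(i)
    as_rna(mirna_seq[[i]], nm[i]), character(1L), USE.NAMES = FALSE)
  names(mirna_seq) <- nm
  # miRNAs with a known sequence but no abundance entry are unexpressed
  # (0 copies); keeping them in the table lets virtual experiments turn
  # them on without re-deriving the candidate-site set
  unexpressed <- setdiff(nm, names(mirna_abundance))
  if (length(unexpressed)) {
    mirna_abundance <- c(mirna_abundance,
                         stats::setNames(rep(0, length(unexpressed)), unexpressed))
  }
  structure(list(label = label,
                 mirna_abundance = mirna_abundance,
                 transcript_abundance = transcript_abundance,
                 mirna_seq = mirna_seq,
                 transcripts = transcripts),
            class = "cell_conditions")
}

#' @export
print.cell_conditions <- function(x, ...) {
  cat(sprintf("<cell_conditions '%s': %d miRNAs (%.0f copies total), %d transcripts (%.0f copies total)>\n",
              x$label, length(x$mirna_abundance), sum(x$mirna_abundance),
              length(x$transcript_abundance), sum(x$transcript_abundance)))
  invisible(x)
}
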