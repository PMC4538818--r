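# The core simulator: assignment of miRNA copies to candidate sites by the
# sorted stable-marriage booking procedure with logarithmic dilution,
# abundance depletion and RISC footprint occlusion.

#' Booking parameters
#'
#' @param tau HP admission threshold in (0, 1); sites must have been
#'   enumerated at the same (or a lower) threshold.
#' @param alpha base of the dilution logarithm (> 1). Larger alpha spreads
#'   fewer copies over more sites.
#' @param footprint span in nt considered occupied around a booked site,
#'   centered on the site (the minimum RISC footprint, 46 nt by default).
#' @param q_min smallest bookable quantity in copies; proposals below it are
#'   rejected, which also guarantees termination.
#' @param sort_order "hp-first" (default) ranks the complementary seeds of
#'   a site by descending HP, then by descending current miRNA abundance;
#'   "abundance-first" swaps the two keys. The final key is always the
#'   miRNA id, so runs are deterministic.
#' @return an object of class \code{booking_params}.
#' @export
booking_params <- function(tau = 0.0179, alpha = 512, footprint = 46L,
                           q_min = 1.0,
                           sort_order = c("hp-first", "abundance-first")) {
  sort_order <- match.arg(sort_order)
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)", call. = FALSE)
  if (alpha <= 1) stop("alpha must be > 1", call. = FALSE)
  if (footprint < 7L) stop("footprint must cover at least the 7-nt site", call. = FALSE)
  if (q_min <= 0) stop("q_min must be > 0", call. = FALSE)
  structure(list(tau = as.numeric(tau), alpha = as.numeric(alpha),
                 footprint = as.integer(footprint), q_min = as.numeric(q_min),
                 sort_order = sort_order),
            class = "booking_params")
}

#' Logarithmic dilution factor of a miRNA
#'
#' log_alpha of the current miRNA abundance, clamped at 0 for abundances of
#' one copy or fewer (a negative booking is meaningless). Models the
#' empirical dilution of miRNA activity with target abundance.
#'
#' @param q_seed current miRNA abundance in copies (>= 0).
#' @param alpha dilution log base (> 1).
#' @return non-negative dilution factor(s).
#' @export
dilution_factor <- function(q_seed, alpha = 512) {
  if (alpha <= 1) stop("alpha must be > 1", call. = FALSE)
  stopifnot(all(q_seed >= 0))
  pmax(0, log(pmax(q_seed, 1)) / log(alpha))
}

#' Copies booked by one seed::MRE proposal
#'
#' Q = min(q_mre * log_alpha(q_seed) * HP, q_seed): the available site
#' copies scaled by the dilution factor and the hybridization probability,
#' capped by what the miRNA still has.
#'
#' @param q_mre available copies of the site (transcript copies minus
#'   whatever is already booked within overlapping footprints).
#' @param q_seed current abundance of the proposing miRNA.
#' @param hp hybridization probability of the duplex.
#' @param alpha dilution log base.
#' @return booked quantity Q >= 0 (real-valued).
#' @export
booking_quantity <- function(q_mre, q_seed, hp, alpha = 512) {
  stopifnot(all(q_mre >= 0), all(q_seed >= 0), all(hp >= 0))
  pmin(q_mre * dilution_factor(q_seed, alpha) * hp, q_seed)
}

#' Run the stable-marriage booking simulation
#'
#' Visits candidate sites in descending order of their transcript's
#' abundance (ties: transcript id, then position). At each site the
#' complementary seeds propose in preference order; each accepted proposal
#' books Q copies (\code{\link{booking_quantity}}, evaluated at the miRNA's
#' current abundance and the site's current availability), depletes the
#' miRNA, and occupies footprint-overlapping availability on the
#' transcript. Proposals below \code{q_min} are rejected and retried on the
#' next pass; passes repeat until one books nothing. The run is
#' deterministic: identical inputs give identical microtargetomes.
#'
#' @param conditions a \code{\link{cell_conditions}} object with absolute
#'   abundances.
#' @param sites candidate sites from \code{\link{candidate_sites}},
#'   enumerated at \code{params$tau}.
#' @param params a \code{\link{booking_params}} object.
#' @param max_passes safety ceiling on the number of passes.
#' @param verbose emit one message per pass.
#' @return an object of class \code{microtargetome}: list with
#'   \code{condition}, \code{bookings} (data.frame mirna, transcript,
#'   position, region, w, hp, copies), \code{residual} (named miRNA
#'   vector), \code{transcript_bound} (named totals), \code{params},
#'   \code{passes}.
#' @export
run_booking <- function(conditions, sites, params = booking_params(),
                        max_passes = 10000L, verbose = FALSE) {
  stopifnot(inherits(conditions, "cell_conditions"),
            inherits(params, "booking_params"))
  n_tx <- conditions$transcript_abundance
  cur <- conditions$mirna_abundance

  empty <- data.frame(mirna = character(), transcript = character(),
                      position = integer(), region = character(),
                      w = numeric(), hp = numeric(), copies = numeric(),
                      stringsAsFactors = FALSE)
  mt <- function(book_df, passes) {
    structure(list(condition = conditions$label, bookings = book_df,
                   residual = cur, transcript_n = n_tx, transcript_bound = {
                     tb <- tapply(book_df$copies, book_df$transcript, sum)
                     v <- stats::setNames(rep(0, length(n_tx)), names(n_tx))
                     if (length(tb)) v[names(tb)] <- tb
                     v
                   },
                   params = params, passes = passes),
              class = "microtargetome")
  }
  if (!nrow(sites) || !length(cur) || all(cur == 0)) return(mt(empty, 0L))

  orphan_tx <- setdiff(unique(sites$transcript), names(n_tx))
  orphan_mi <- setdiff(unique(sites$mirna), names(cur))
  if (length(orphan_tx) || length(orphan_mi)) {
    stop(sprintf("sites refer to ids absent from the conditions: %s",
                 paste(c(orphan_tx, orphan_mi), collapse = ", ")), call. = FALSE)
  }
  if (any(sites$hp < params$tau)) {
    stop("sites contain HP values below params$tau; re-enumerate candidates at this threshold",
         call. = FALSE)
  }

  s <- sites
  s$n <- n_tx[s$transcript]
  s <- s[s$n > 0, , drop = FALSE]
  if (!nrow(s)) return(mt(empty, 0L))

  # site = unique (transcript, position); rows of `s` are (site, seed) pairs
  site_key <- paste(s$transcript, s$position, sep = "\r")
  usite <- !duplicated(site_key)
  site_tab <- data.frame(key = site_key[usite], transcript = s$transcript[usite],
                         position = s$position[usite], n = s$n[usite],
                         stringsAsFactors = FALSE)
  # outer order: transcript abundance desc, transcript id, position
  site_tab <- site_tab[order(-site_tab$n, site_tab$transcript, site_tab$position), ,
                       drop = FALSE]
  rows_by_site <- split(seq_len(nrow(s)), site_key)

  # per-transcript site centers for footprint overlap bookkeeping
  center <- s$position + 3L
  copies <- numeric(nrow(s))          # booked copies per (site, seed) row
  mirna_idx <- match(s$mirna, names(cur))

  half_ok <- params$footprint          # overlap iff |center_i - center_j| < footprint
  passes <- 0L
  repeat {
    passes <- passes + 1L
    if (passes > max_passes) {
      stop(sprintf("booking did not quiesce within %d passes", max_passes),
           call. = FALSE)
    }
    booked_any <- FALSE
    moved <- 0
    made <- 0L
    for (si in seq_len(nrow(site_tab))) {
      rows <- rows_by_site[[site_tab$key[si]]]
      tx <- site_tab$transcript[si]
      c0 <- site_tab$position[si] + 3L
      # availability: transcript copies minus copies booked within
      # footprint-overlapping windows anywhere on this transcript
      same_tx <- which(s$transcript == tx & abs(center - c0) < half_ok)
      avail <- site_tab$n[si] - sum(copies[same_tx])
      if (avail <= 0) next
      # seed preference order at this site, evaluated now (abundance is current)
      ab <- cur[mirna_idx[rows]]
      ord <- if (params$sort_order == "abundance-first") {
        order(-ab, -s$hp[rows], s$mirna[rows])
      } else {
        order(-s$hp[rows], -ab, s$mirna[rows])
      }
      for (r in rows[ord]) {
        if (copies[r] > 0) next  # a seed::MRE pair is made at most once
        mi <- mirna_idx[r]
        q_seed <- cur[mi]
        if (q_seed <= 0) next
        # the Q rule, additionally capped by the site's free capacity so
        # overlapping footprints can never hold more copies than the
        # transcript has (dilution * hp may exceed 1)
        Q <- min(booking_quantity(avail, q_seed, s$hp[r], params$alpha), avail)
        if (Q < params$q_min) next
        copies[r] <- copies[r] + Q
        cur[mi] <- cur[mi] - Q
        avail <- avail - Q
        booked_any <- TRUE
        moved <- moved + Q
        made <- made + 1L
        if (avail <= 0) break
      }
    }
    if (verbose) {
      message(sprintf("pass %d: %d bookings, %.3f copies moved", passes, made, moved))
    }
    if (!booked_any) break
  }

  keep <- copies > 0
  book_df <- data.frame(mirna = s$mirna[keep], transcript = s$transcript[keep],
                        position = s$position[keep], region = s$region[keep],
                        w = s$w[keep], hp = s$hp[keep], copies = copies[keep],
                        stringsAsFactors = FALSE)
  book_df <- book_df[order(book_df$transcript, book_df$position, book_df$mirna), ,
                     drop = FALSE]
  rownames(book_df) <- NULL
  mt(book_df, passes)
}

#' @export
print.microtargetome <- function(x, ...) {
  cat(sprintf("<microtargetome of '%s': %d bookings, %.1f copies bound, %d pass(es)>\n",
              x$condition, nrow(x$bookings), sum(x$bookings$copies), x$passes))
  invisible(x)
}

#' Occupancy of a transcript
#'
#' The average number of bound miRNA copies per copy of the transcript:
#' total booked copies divided by the transcript's abundance n. E.g. 15
#' booked copies on a transcript expressed at 30 copies give O = 0.5.
#'
#' @param mt a \code{microtargetome}.
#' @param transcript transcript id.
#' @param n abundance of the transcript; defaults to the abundance recorded
#'   at run time.
#' @return occupancy O >= 0.
#' @export
occupancy <- function(mt, transcript, n = NULL) {
  stopifnot(inherits(mt, "microtargetome"))
  if (is.null(n)) {
    if (!transcript %in% names(mt$transcript_n)) {
      stop(sprintf("transcript '%s' not present in the run", transcript), call. = FALSE)
    }
    n <- mt$transcript_n[[transcript]]
  }
  if (n <= 0) {
    stop(sprintf("occupancy of '%s' is undefined: transcript abundance is 0",
                 transcript), call. = FALSE)
  }
  b <- mt$bookings
  sum(b$copies[b$transcript == transcript]) / n
}

#' Verify stability of a microtargetome (exhaustive)
#'
#' Recomputes, from the output alone, every site's residual availability
#' and every miRNA's residual abundance, and checks that no admissible
#' seed::MRE pair that is not already part of the assignment could still
#' book at least \code{q_min} copies — i.e. no alternative pair exists in
#' which both the miRNA (unspent copies) and the MRE (free capacity) would
#' be individually better off. Intended as an independent oracle on small
#' instances.
#'
#' @param mt a \code{microtargetome}.
#' @param conditions the conditions it was run under.
#' @param sites the candidate sites it was run on.
#' @return TRUE if stable; otherwise a character vector describing the
#'   improving pairs.
#' @export
verify_stability <- function(mt, conditions, sites) {
  stopifnot(inherits(mt, "microtargetome"))
  params <- mt$params
  b <- mt$bookings
  # residuals recomputed independently of the engine's bookkeeping
  booked_by_mirna <- tapply(b$copies, b$mirna, sum)
  residual <- conditions$mirna_abundance
  if (length(booked_by_mirna)) {
    residual[names(booked_by_mirna)] <- residual[names(booked_by_mirna)] - booked_by_mirna
  }
  booked_pair <- paste(b$mirna, b$transcript, b$position, sep = "\r")
  bad <- character()
  for (r in seq_len(nrow(sites))) {
    if (paste(sites$mirna[r], sites$transcript[r], sites$position[r],
              sep = "\r") %in% booked_pair) next
    tx <- sites$transcript[r]
    n <- conditions$transcript_abundance[[tx]]
    if (is.na(n) || n <= 0) next
    c0 <- sites$position[r] + 3L
    same <- b$transcript == tx & abs(b$position + 3L - c0) < params$footprint
    avail <- n - sum(b$copies[same])
    q_seed <- residual[[sites$mirna[r]]]
    Q <- min(booking_quantity(max(avail, 0), max(q_seed, 0), sites$hp[r],
                              params$alpha), max(avail, 0))
    if (Q >= params$q_min) {
      bad <- c(bad, sprintf("%s could still book %.3f copies at %s:%d",
                            sites$mirna[r], Q, tx, sites$position[r]))
    }
  }
  if (length(bad)) bad else TRUE
}
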