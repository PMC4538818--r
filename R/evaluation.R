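# Classification metrics (MCC, precision/recall, AU-ROC) and the tau/alpha
# optimization grid.

#' Label an expression change from its log2 fold-change
#'
#' With the default two-threshold rule, genes with log2 fold-change below
#' \code{down_threshold} are positives (downregulated), those inside the
#' [down, up] band are excluded as noise, and the rest are negatives. When a
#' single cut \code{positive_cut} is supplied, the rule collapses to
#' "positive iff log2fc < cut" with no exclusion band.
#'
#' @param log2fc numeric vector of log2 fold-changes.
#' @param down_threshold,up_threshold noise band bounds (default -0.2/0.2).
#' @param positive_cut optional single strict cut t.
#' @return character vector over \{"positive", "negative", "excluded"\}.
#' @export
label_by_foldchange <- function(log2fc, down_threshold = -0.2,
                                up_threshold = 0.2, positive_cut = NULL) {
  if (!is.null(positive_cut)) {
    return(ifelse(log2fc < positive_cut, "positive", "negative"))
  }
  stopifnot(down_threshold <= up_threshold)
  ifelse(log2fc < down_threshold, "positive",
         ifelse(log2fc <= up_threshold, "excluded", "negative"))
}

#' Confusion counts from labels and calls
#'
#' Items labelled "excluded" are dropped before counting (optionally
#' counted as negatives).
#'
#' @param label reference labels ("positive"/"negative"/"excluded").
#' @param call predicted calls ("positive"/"negative").
#' @param excluded_as_negative count excluded items as reference negatives
#'   instead of dropping them.
#' @return list with integer fields tp, fp, fn, tn.
#' @export
confusion_counts <- function(label, call, excluded_as_negative = FALSE) {
  stopifnot(length(label) == length(call))
  if (excluded_as_negative) {
    label[label == "excluded"] <- "negative"
  } else {
    keep <- label != "excluded"
    label <- label[keep]; call <- call[keep]
  }
  list(tp = sum(label == "positive" & call == "positive"),
       fp = sum(label == "negative" & call == "positive"),
       fn = sum(label == "positive" & call == "negative"),
       tn = sum(label == "negative" & call == "negative"))
}

#' Matthews correlation coefficient
#'
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); defined as 0 when
#' any factor of the denominator vanishes.
#'
#' @param counts list with tp, fp, fn, tn (see
#'   \code{\link{confusion_counts}}).
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  if (tp + fp + fn + tn == 0) {
    stop("MCC is undefined on all-zero counts", call. = FALSE)
  }
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
}

#' Precision and recall
#'
#' precision = TP/(TP+FP), recall (sensitivity) = TP/(TP+FN); either is NA
#' when its denominator is zero.
#'
#' @inheritParams mcc
#' @return list with \code{precision} and \code{recall}.
#' @export
precision_recall <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Rank-based AU-ROC
#'
#' The probability that a positive item outscores a negative one, with ties
#' counted 1/2 (the Mann-Whitney formulation). Also returns the ROC curve.
#'
#' @param score numeric prediction scores (higher = more positive).
#' @param label reference labels; "excluded" items are dropped.
#' @return list with \code{auc} and \code{curve} (data.frame fpr, tpr).
#' @export
roc_auc <- function(score, label) {
  keep <- label != "excluded"
  score <- score[keep]; label <- label[keep]
  pos <- label == "positive"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) {
    stop("AU-ROC needs at least one positive and one negative", call. = FALSE)
  }
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-score)
  tpr <- c(0, cumsum(pos[ord]) / np)
  fpr <- c(0, cumsum(!pos[ord]) / nn)
  list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Grid search over tau and alpha by MCC
#'
#' Reruns the virtual-overexpression experiments at every (tau, alpha)
#' combination, calls downregulation per transcript (miS increases
#' strictly), scores the calls against the reference labels, and reports
#' the full results table with the argmax. Ties on MCC resolve to the
#' lowest tau, then the lowest alpha.
#'
#' @param conditions base \code{\link{cell_conditions}}.
#' @param experiments list of perturbations, each a list with \code{mirna}
#'   and \code{copies}.
#' @param labels data.frame with columns \code{experiment} (index into
#'   \code{experiments}), \code{transcript}, \code{label}
#'   ("positive"/"negative"/"excluded").
#' @param tau_grid,alpha_grid numeric grids (non-empty).
#' @param model energy model.
#' @param footprint,q_min fixed booking parameters.
#' @param excluded_as_negative see \code{\link{confusion_counts}}.
#' @return list with \code{table} (data.frame tau, alpha, tp, fp, fn, tn,
#'   mcc) and \code{best} (its argmax row).
#' @export
grid_search <- function(conditions, experiments, labels, tau_grid, alpha_grid,
                        model = energy_model(), footprint = 46L, q_min = 1.0,
                        excluded_as_negative = FALSE) {
  stopifnot(length(tau_grid) >= 1L, length(alpha_grid) >= 1L,
            all(c("experiment", "transcript", "label") %in% names(labels)))
  tau_min <- min(tau_grid)
  base_sites <- candidate_sites(conditions, model, tau_min)
  grid <- expand.grid(tau = sort(tau_grid), alpha = sort(alpha_grid),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    tau <- grid$tau[g]; alpha <- grid$alpha[g]
    params <- booking_params(tau = tau, alpha = alpha, footprint = footprint,
                             q_min = q_min)
    sites <- base_sites[base_sites$hp >= tau, , drop = FALSE]
    calls <- character(nrow(labels))
    for (e in seq_along(experiments)) {
      sel <- labels$experiment == e
      if (!any(sel)) next
      vx <- virtual_overexpression(conditions, experiments[[e]]$mirna,
                                   experiments[[e]]$copies, model, params,
                                   sites_before = sites)
      sc <- vx$scores
      idx <- match(labels$transcript[sel], sc$transcript)
      calls[sel] <- ifelse(is.na(idx), "negative", sc$call[idx])
    }
    cc <- confusion_counts(labels$label, calls, excluded_as_negative)
    rows[[g]] <- data.frame(tau = tau, alpha = alpha, tp = cc$tp, fp = cc$fp,
                            fn = cc$fn, tn = cc$tn, mcc = mcc(cc))
  }
  tab <- do.call(rbind, rows)
  best <- tab[order(-tab$mcc, tab$tau, tab$alpha), ][1L, ]
  rownames(best) <- NULL
  list(table = tab, best = best)
}
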