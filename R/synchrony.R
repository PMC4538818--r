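# Leader/follower synchronous-silencing analysis: abundance sweeps,
# correlation matrices, Ward clustering.

#' Sweep a leader transcript's abundance and record follower miS
#'
#' For every grid point the leader's abundance is forced to that value, the
#' booking simulation is rerun, and the miS of every other (follower)
#' transcript is recorded. The default grid, 100 to 6000 copies by steps of
#' 100, spans the physiological mRNA abundance range.
#'
#' @param conditions a \code{\link{cell_conditions}} object.
#' @param leader transcript id to sweep.
#' @param grid strictly increasing abundance grid (copies).
#' @param sites candidate sites of the condition (sequence-derived, so they
#'   are valid at every grid point); computed if missing.
#' @param model energy model (used only if \code{sites} is missing).
#' @param params \code{\link{booking_params}}.
#' @param followers follower ids; all non-leader expressed transcripts by
#'   default.
#' @return object of class \code{leader_sweep}: list with \code{leader},
#'   \code{grid}, \code{mis} (matrix, grid points x followers).
#' @export
leader_sweep <- function(conditions, leader, grid = seq(100, 6000, by = 100),
                         sites = NULL, model = energy_model(),
                         params = booking_params(), followers = NULL) {
  stopifnot(inherits(conditions, "cell_conditions"), length(grid) >= 1L)
  if (!leader %in% names(conditions$transcript_abundance)) {
    stop(sprintf("unknown leader transcript '%s'", leader), call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("the abundance grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(sites)) sites <- candidate_sites(conditions, model, params$tau)
  if (is.null(followers)) {
    followers <- setdiff(names(conditions$transcript_abundance)[
      conditions$transcript_abundance > 0], leader)
  }
  m <- matrix(NA_real_, nrow = length(grid), ncol = length(followers),
              dimnames = list(NULL, followers))
  for (i in seq_along(grid)) {
    cond <- conditions
    cond$transcript_abundance[[leader]] <- grid[i]
    mt <- run_booking(cond, sites, params)
    m[i, ] <- vapply(followers, function(t) mis(mt, t)$mis, numeric(1L))
  }
  structure(list(leader = leader, grid = grid, mis = m),
            class = "leader_sweep")
}

#' Leader/follower synchrony correlation matrix
#'
#' Entry (i, j) is the correlation between leader i's forced abundance grid
#' and the miS induced on follower j. The matrix is square over the union
#' of roles but need not be symmetric. A follower whose miS does not vary
#' over a sweep gets a 0 entry, recorded in the \code{flagged} matrix. The
#' diagonal (a leader against itself) is NA.
#'
#' @param conditions a \code{\link{cell_conditions}} object.
#' @param leaders,followers transcript id vectors.
#' @param grid abundance grid for every sweep.
#' @param sites,model,params as in \code{\link{leader_sweep}}.
#' @param method "pearson" (default) or "spearman".
#' @return object of class \code{synchrony_matrix}: list with \code{matrix}
#'   (leaders x followers), \code{flagged} (logical matrix of zero-variance
#'   entries), \code{grid}, \code{method}.
#' @export
synchrony_matrix <- function(conditions, leaders, followers = leaders,
                             grid = seq(100, 6000, by = 100), sites = NULL,
                             model = energy_model(),
                             params = booking_params(),
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.null(sites)) sites <- candidate_sites(conditions, model, params$tau)
  m <- matrix(NA_real_, length(leaders), length(followers),
              dimnames = list(leaders, followers))
  fl <- matrix(FALSE, length(leaders), length(followers),
               dimnames = list(leaders, followers))
  for (i in seq_along(leaders)) {
    fo <- setdiff(followers, leaders[i])
    sw <- leader_sweep(conditions, leaders[i], grid, sites = sites,
                       params = params, followers = fo)
    for (j in seq_along(followers)) {
      if (followers[j] == leaders[i]) next  # diagonal stays NA
      y <- sw$mis[, followers[j]]
      if (stats::sd(y) == 0) {
        m[i, j] <- 0
        fl[i, j] <- TRUE
      } else {
        m[i, j] <- stats::cor(grid, y, method = method)
      }
    }
  }
  structure(list(matrix = m, flagged = fl, grid = grid, method = method),
            class = "synchrony_matrix")
}

#' Ward-cluster a synchrony matrix
#'
#' Reorders rows and columns by agglomerative hierarchical clustering with
#' Ward linkage on Euclidean distances; NA entries (the diagonal) and
#' flagged zero-variance entries are imputed as 0 for clustering only. The
#' leaf order of \code{\link[stats]{hclust}} is deterministic, so identical
#' inputs give identical orderings.
#'
#' @param sm a \code{synchrony_matrix} (or plain numeric matrix).
#' @return list with \code{matrix} (reordered, original values),
#'   \code{row_hclust}, \code{col_hclust}.
#' @export
cluster_matrix <- function(sm) {
  m <- if (inherits(sm, "synchrony_matrix")) sm$matrix else sm
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("clustering needs at least a 2x2 matrix", call. = FALSE)
  }
  imp <- m
  imp[is.na(imp)] <- 0
  hr <- stats::hclust(stats::dist(imp), method = "ward.D2")
  hc <- stats::hclust(stats::dist(t(imp)), method = "ward.D2")
  list(matrix = m[hr$order, hc$order, drop = FALSE],
       row_hclust = hr, col_hclust = hc)
}

#' Export a dendrogram in Newick format
#'
#' @param h an \code{hclust} object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Write a synchrony matrix as TSV (row/column ids kept)
#'
#' @param sm a \code{synchrony_matrix} or matrix.
#' @param path output file.
#' @export
write_synchrony_matrix <- function(sm, path) {
  m <- if (inherits(sm, "synchrony_matrix")) sm$matrix else sm
  df <- data.frame(leader = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
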