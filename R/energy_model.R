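# Seed extraction, duplex free energies over all 4^7 heptamers, and
# Boltzmann-normalized hybridization probabilities (HP).

RNA_BASES <- c("A", "C", "G", "U")

# heptamer index: base-4 integer in 0..16383, A=0, C=1, G=2, U=3,
# position 1 is the most significant digit
N_HEPTAMERS <- 4L^7L

.pkg_cache <- new.env(parent = emptyenv())

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U; rejects any other character.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector over {A,C,G,U}.
#' @export
as_rna <- function(x, what = "sequence") {
  x <- chartr("tT", "uU", toupper(as.character(x)))
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the RNA alphabet: %s",
                 what, paste(utils::head(x[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Extract the seed heptamer (nucleotides 2-8) of a mature miRNA
#'
#' The seed is the hybridization template exposed by the RISC: positions
#' 2 to 8 of the mature sequence, read 5' to 3'.
#'
#' @param mature_sequence mature miRNA sequence (RNA or DNA letters), length
#'   at least 8 nt.
#' @param id optional miRNA identifier, used in error messages.
#' @return a 7-character seed string over {A,C,G,U}.
#' @examples
#' extract_seed("AUGGCAUCGAUCGAUCGAUCGA")  # "UGGCAUC"
#' @export
extract_seed <- function(mature_sequence, id = "<unnamed miRNA>") {
  seq <- as_rna(mature_sequence, what = sprintf("miRNA '%s'", id))
  if (nchar(seq) < 8L) {
    stop(sprintf("mature sequence of miRNA '%s' is %d nt; at least 8 nt are required to extract nucleotides 2-8",
                 id, nchar(seq)), call. = FALSE)
  }
  substr(seq, 2L, 8L)
}

.check_heptamer <- function(x, what = "heptamer") {
  x <- as_rna(x, what = what)
  if (any(nchar(x) != 7L)) {
    stop(sprintf("%s must be exactly 7 nt", what), call. = FALSE)
  }
  x
}

# integer codes 0..3 per base, as a matrix n x 7
.encode <- function(seqs) {
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), RNA_BASES) - 1L,
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) stop("non-ACGU character in heptamer", call. = FALSE)
  m
}

.decode <- function(codes) {
  apply(codes, 1L, function(r) paste(RNA_BASES[r + 1L], collapse = ""))
}

#' Index of a heptamer among all 4^7 possibilities
#'
#' Base-4 encoding (A=0, C=1, G=2, U=3), first position most significant;
#' returns 1-based indices into the canonical enumeration of
#' \code{\link{all_heptamers}}.
#'
#' @param heptamer character vector of 7-mers.
#' @return integer vector of indices in 1..16384.
#' @export
heptamer_index <- function(heptamer) {
  m <- .encode(.check_heptamer(heptamer))
  as.integer(m %*% 4L^(6:0)) + 1L
}

#' Enumerate all 16,384 heptamers in canonical order
#'
#' @return character vector of length 4^7 such that
#'   \code{heptamer_index(all_heptamers())} is \code{1:16384}.
#' @export
all_heptamers <- function() {
  if (is.null(.pkg_cache$heptamers)) {
    g <- expand.grid(RNA_BASES, RNA_BASES, RNA_BASES, RNA_BASES,
                     RNA_BASES, RNA_BASES, RNA_BASES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; we want position 7 fastest
    .pkg_cache$heptamers <- do.call(paste0, rev(g))
  }
  .pkg_cache$heptamers
}

# cached n x 7 code matrix of all heptamers
.all_heptamer_codes <- function() {
  if (is.null(.pkg_cache$hcodes)) .pkg_cache$hcodes <- .encode(all_heptamers())
  .pkg_cache$hcodes
}

#' Reverse complement of an RNA sequence
#' @param x character vector of RNA sequences.
#' @return character vector.
#' @export
reverse_complement <- function(x) {
  x <- as_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1L))
}

#' Count seed::MRE mismatches under the antiparallel alignment
#'
#' Seed position i faces MRE position 8-i; a position counts as matched only
#' when it forms a Watson-Crick pair (A:U or G:C). G:U wobbles count as
#' mismatches for this complementarity filter (their energetic treatment is
#' a separate matter, see \code{\link{energy_model}}).
#'
#' @param seed seed heptamer(s), 5' to 3'.
#' @param mre MRE heptamer(s) on the mRNA, 5' to 3'. Recycled against
#'   \code{seed}.
#' @return integer vector of mismatch counts in 0..7.
#' @export
mismatch_count <- function(seed, mre) {
  seed <- .check_heptamer(seed, "seed")
  mre <- .check_heptamer(mre, "MRE")
  n <- max(length(seed), length(mre))
  seed <- rep_len(seed, n); mre <- rep_len(mre, n)
  sm <- .encode(seed)
  mm <- .encode(mre)[, 7:1, drop = FALSE]  # antiparallel partner positions
  # WC partner code: A(0)<->U(3), C(1)<->G(2): partner = 3 - code
  as.integer(rowSums(mm != (3L - sm)))
}

# per-seed mismatch counts against every heptamer, vectorized and cached
.mismatch_profile <- function(seed) {
  key <- paste0("mm_", seed)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  sm <- .encode(.check_heptamer(seed, "seed"))[1L, ]
  H <- .all_heptamer_codes()[, 7:1, drop = FALSE]
  v <- as.integer(rowSums(H != matrix(3L - sm, nrow = nrow(H), ncol = 7L, byrow = TRUE)))
  .pkg_cache[[key]] <- v
  v
}

# Watson-Crick dinucleotide stack free energies (model units, kT = 1),
# indexed by the seed-strand bases of two adjacent paired positions.
# Filled from the 10 distinct helix stacks plus the rotational symmetry
# S[x, y] = S[comp(y), comp(x)].
.wc_stack_matrix <- function() {
  S <- matrix(c(
    -0.93, -2.24, -2.08, -1.10,
    -2.11, -3.26, -2.36, -2.08,
    -2.35, -3.42, -3.26, -2.24,
    -1.33, -2.35, -2.11, -0.93), nrow = 4L, byrow = TRUE,
    dimnames = list(RNA_BASES, RNA_BASES))
  S
}

#' Construct a duplex free-energy backend
#'
#' Three backends share one interface:
#' \describe{
#'   \item{nearest-neighbor}{the default. The seed::MRE duplex energy is the
#'     sum of Watson-Crick dinucleotide stack energies over adjacent
#'     positions where both positions pair, plus a fixed destabilizing
#'     penalty per non-Watson-Crick position: \code{wobble_penalty} for G:U
#'     wobbles and \code{mismatch_penalty} for everything else. All values
#'     are in model units with kT = 1, so only relative scale matters.}
#'   \item{table}{an exact lookup of precomputed seed::heptamer energies,
#'     e.g. imported with \code{\link{read_delta_g_table}}. Every queried
#'     seed must be present with all 16,384 heptamers.}
#'   \item{uniform}{delta G identically 0; every heptamer is equally likely
#'     (HP = 1/16384). Intended for tests and as a null model.}
#' }
#'
#' @param backend one of "nearest-neighbor", "table", "uniform".
#' @param table for the table backend: a named list mapping seed -> numeric
#'   vector of 16,384 energies in canonical heptamer order (see
#'   \code{\link{all_heptamers}}).
#' @param mismatch_penalty,wobble_penalty per-position penalties of the
#'   nearest-neighbor backend, model units.
#' @param kT thermal energy scale used in the Boltzmann weights; fixed at 1
#'   by convention and exposed only for sensitivity analysis.
#' @return an object of class \code{energy_model}.
#' @export
energy_model <- function(backend = c("nearest-neighbor", "uniform", "table"),
                         table = NULL,
                         mismatch_penalty = 2.5,
                         wobble_penalty = 1.0,
                         kT = 1.0) {
  backend <- match.arg(backend)
  if (backend == "table") {
    if (is.null(table) || is.null(names(table))) {
      stop("table backend requires a named seed -> energy-vector list", call. = FALSE)
    }
    ok <- vapply(table, function(v) is.numeric(v) && length(v) == N_HEPTAMERS,
                 logical(1L))
    if (!all(ok)) {
      stop("every seed in the energy table must map to 16,384 finite energies",
           call. = FALSE)
    }
  }
  structure(list(backend = backend, table = table,
                 mismatch_penalty = mismatch_penalty,
                 wobble_penalty = wobble_penalty, kT = kT),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model: %s backend, kT = %g>\n", x$backend, x$kT))
  if (x$backend == "nearest-neighbor") {
    cat(sprintf("  mismatch penalty %+.2f, G:U wobble penalty %+.2f (model units)\n",
                x$mismatch_penalty, x$wobble_penalty))
  }
  if (x$backend == "table") {
    cat(sprintf("  %d seed(s) tabulated\n", length(x$table)))
  }
  invisible(x)
}

# delta G of one seed against every heptamer, canonical order
.energy_profile <- function(seed, model) {
  stopifnot(inherits(model, "energy_model"))
  seed <- .check_heptamer(seed, "seed")
  if (model$backend == "uniform") return(numeric(N_HEPTAMERS))
  if (model$backend == "table") {
    v <- model$table[[seed]]
    if (is.null(v)) {
      stop(sprintf("seed '%s' is not present in the energy table", seed),
           call. = FALSE)
    }
    return(as.numeric(v))
  }
  sm <- .encode(seed)[1L, ]
  H <- .all_heptamer_codes()[, 7:1, drop = FALSE]  # partner position per seed pos
  wc <- H == matrix(3L - sm, nrow = nrow(H), ncol = 7L, byrow = TRUE)
  # G:U wobble: seed G faces U, or seed U faces G
  wob <- (H == 3L & matrix(sm == 2L, nrow(H), 7L, byrow = TRUE)) |
         (H == 2L & matrix(sm == 3L, nrow(H), 7L, byrow = TRUE))
  wob <- wob & !wc
  mism <- !wc & !wob
  S <- .wc_stack_matrix()
  stack_vals <- S[cbind(sm[1:6] + 1L, sm[2:7] + 1L)]
  dg <- numeric(N_HEPTAMERS)
  for (j in 1:6) dg <- dg + stack_vals[j] * (wc[, j] & wc[, j + 1L])
  dg + model$mismatch_penalty * rowSums(mism) + model$wobble_penalty * rowSums(wob)
}

#' Free energy of a seed::MRE duplex
#'
#' @param seed seed heptamer, 5' to 3'.
#' @param mre MRE heptamer(s), 5' to 3' on the mRNA; vectorized.
#' @param model an \code{\link{energy_model}}.
#' @return numeric vector of free energies (model units; lower = more
#'   stable).
#' @export
duplex_delta_g <- function(seed, mre, model = energy_model()) {
  prof <- .energy_profile(seed, model)
  dg <- prof[heptamer_index(mre)]
  if (any(!is.finite(dg))) {
    bad <- mre[!is.finite(dg)][1L]
    stop(sprintf("non-finite duplex energy for %s::%s", seed, bad), call. = FALSE)
  }
  dg
}

# full HP vector for one seed (sums to 1); log-space with max subtraction
.hp_profile <- function(seed, model) {
  dg <- .energy_profile(seed, model)
  if (any(!is.finite(dg))) {
    bad <- all_heptamers()[which(!is.finite(dg))[1L]]
    stop(sprintf("non-finite duplex energy for %s::%s", seed, bad), call. = FALSE)
  }
  loga <- -dg / model$kT
  w <- exp(loga - max(loga))
  w / sum(w)
}

#' Boltzmann-normalized hybridization probability HP(seed::MRE)
#'
#' HP(seed::MRE) = exp(-dG(seed::MRE)/kT) / sum_h exp(-dG(seed::h)/kT),
#' where the sum runs over all 4^7 = 16,384 heptamers h and kT = 1 by
#' default. For a fixed seed the probabilities over all heptamers sum to 1.
#'
#' @inheritParams duplex_delta_g
#' @return numeric vector of probabilities in [0, 1].
#' @export
hybridization_probability <- function(seed, mre, model = energy_model()) {
  hp <- .hp_profile(seed, model)
  hp[heptamer_index(mre)]
}

#' Full HP table for a set of seeds
#'
#' @param seeds character vector of seed heptamers (names, if present, are
#'   kept as row names).
#' @param model an \code{\link{energy_model}}.
#' @return numeric matrix, one row per seed, 16,384 columns in canonical
#'   heptamer order; every row sums to 1.
#' @export
hp_table <- function(seeds, model = energy_model()) {
  m <- t(vapply(seeds, .hp_profile, numeric(N_HEPTAMERS), model = model))
  colnames(m) <- all_heptamers()
  m
}

#' Read / write seed::heptamer free-energy tables
#'
#' TSV with header \code{seed<TAB>heptamer<TAB>delta_g}; a seed is usable by
#' the table backend only when all 16,384 heptamer rows are present.
#'
#' @param path file path.
#' @return \code{read_delta_g_table}: a named list of energy vectors in
#'   canonical heptamer order, suitable for
#'   \code{energy_model("table", table = ...)}.
#' @export
read_delta_g_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seed", "heptamer", "delta_g")
  if (!all(need %in% names(df))) {
    stop(sprintf("energy table '%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(df, df$seed), function(d) {
    if (nrow(d) != N_HEPTAMERS || anyDuplicated(d$heptamer)) {
      stop(sprintf("seed '%s' must have exactly one row per 16,384 heptamers (got %d)",
                   d$seed[1L], nrow(d)), call. = FALSE)
    }
    v <- numeric(N_HEPTAMERS)
    v[heptamer_index(d$heptamer)] <- d$delta_g
    v
  })
  out
}

#' @param model an energy model whose energies should be exported.
#' @param seeds seeds to export.
#' @rdname read_delta_g_table
#' @export
write_delta_g_table <- function(model, seeds, path) {
  rows <- lapply(seeds, function(s)
    data.frame(seed = s, heptamer = all_heptamers(),
               # %.17g survives the double -> text -> double round trip
               delta_g = sprintf("%.17g", .energy_profile(s, model))))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export hybridization probabilities as TSV
#'
#' Columns \code{seed<TAB>heptamer<TAB>hp}, probabilities printed with 12
#' significant digits.
#'
#' @inheritParams write_delta_g_table
#' @export
write_hp_table <- function(model, seeds, path) {
  rows <- lapply(seeds, function(s)
    data.frame(seed = s, heptamer = all_heptamers(),
               hp = formatC(.hp_profile(s, model), digits = 12, format = "g")))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
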