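# Readers and writers for the formats the pipeline touches: FASTA,
# transcript-relative BED4, expression TSV, microtargetome TSV, YAML run
# configuration and JSON run manifests.

#' Read a FASTA file into a named character vector
#'
#' DNA letters are transcribed to RNA (T -> U); duplicate record ids and
#' characters outside the nucleotide alphabet are rejected.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- anyDuplicated(ids)
  if (dup) {
    stop(sprintf("duplicate FASTA id '%s' in %s (record %d)", ids[dup], path, dup),
         call. = FALSE)
  }
  seqs <- as_rna(as.character(set), sprintf("FASTA file '%s'", path))
  stats::setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read / write an expression table
#'
#' TSV with header \code{id<TAB>value}; ids must be unique and values
#' non-negative.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "value") %in% names(df))) {
    stop(sprintf("expression table '%s' must have columns id, value", path),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop(sprintf("duplicate id in expression table '%s'", path), call. = FALSE)
  }
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    stop(sprintf("expression table '%s' has negative or non-finite values", path),
         call. = FALSE)
  }
  stats::setNames(df$value, df$id)
}

#' @param values named numeric vector to write.
#' @rdname read_expression
#' @export
write_expression <- function(values, path) {
  utils::write.table(data.frame(id = names(values), value = unname(values)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript-relative CDS bounds (BED4)
#'
#' Four tab-separated columns, no header:
#' \code{transcript_id<TAB>cds_start<TAB>cds_end<TAB>gene_id}, coordinates
#' 0-based half-open on the transcript.
#'
#' @param path BED file.
#' @return data.frame with columns id, cds_start, cds_end, gene.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop(sprintf("regions file '%s' must have 4 columns (transcript, cds_start, cds_end, gene)",
                 path), call. = FALSE)
  }
  names(df)[1:4] <- c("id", "cds_start", "cds_end", "gene")
  if (any(df$cds_start < 0 | df$cds_end < df$cds_start)) {
    stop(sprintf("inconsistent CDS bounds in '%s'", path), call. = FALSE)
  }
  df[, 1:4]
}

#' Write / read a microtargetome
#'
#' Bookings TSV with header
#' \code{mirna<TAB>transcript<TAB>position<TAB>region<TAB>copies<TAB>hp}
#' (copies with 6 decimals, HP with 12 significant digits), a residuals TSV
#' alongside (suffix \code{.residuals.tsv}) and a JSON run manifest
#' (suffix \code{.manifest.json}) recording the parameters and pass count.
#'
#' @param mt a \code{microtargetome}.
#' @param path bookings TSV path; side files derive from it.
#' @return \code{read_microtargetome}: the reconstructed
#'   \code{microtargetome} (region weights re-derived from the region
#'   label).
#' @export
write_microtargetome <- function(mt, path) {
  stopifnot(inherits(mt, "microtargetome"))
  b <- mt$bookings
  df <- data.frame(mirna = b$mirna, transcript = b$transcript,
                   position = b$position, region = b$region,
                   copies = sprintf("%.6f", b$copies),
                   hp = formatC(b$hp, digits = 12, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- function(suffix) paste0(sub("\\.tsv$", "", path), suffix)
  write_expression(mt$residual, side(".residuals.tsv"))
  utils::write.table(
    data.frame(id = names(mt$transcript_n), value = unname(mt$transcript_n)),
    side(".transcripts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(condition = mt$condition,
                   parameters = unclass(mt$params),
                   passes = mt$passes,
                   bookings = nrow(b),
                   copies_bound = sum(b$copies))
  jsonlite::write_json(manifest, side(".manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_microtargetome
#' @export
read_microtargetome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(position = "integer",
                                         copies = "numeric", hp = "numeric"))
  need <- c("mirna", "transcript", "position", "region", "copies", "hp")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("microtargetome '%s' is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df$w <- region_weight(df$region)
  side <- function(suffix) paste0(sub("\\.tsv$", "", path), suffix)
  residual <- read_expression(side(".residuals.tsv"))
  tx <- read_expression(side(".transcripts.tsv"))
  manifest <- jsonlite::read_json(side(".manifest.json"))
  p <- manifest$parameters
  structure(list(condition = manifest$condition,
                 bookings = df[, c("mirna", "transcript", "position",
                                   "region", "w", "hp", "copies")],
                 residual = residual, transcript_n = tx,
                 transcript_bound = {
                   tb <- tapply(df$copies, df$transcript, sum)
                   v <- stats::setNames(rep(0, length(tx)), names(tx))
                   if (length(tb)) v[names(tb)] <- tb
                   v
                 },
                 params = booking_params(p$tau, p$alpha, p$footprint,
                                         p$q_min, p$sort_order),
                 passes = manifest$passes),
            class = "microtargetome")
}

#' Load a run configuration
#'
#' YAML with a flat schema: paths \code{mirna_fasta}, \code{mrna_fasta},
#' \code{regions_bed}, \code{mirna_expression}, \code{mrna_expression},
#' optional \code{delta_g_table}; scalars \code{label}, \code{tau},
#' \code{alpha}, \code{footprint}, \code{q_min}, \code{energy_backend}.
#' Relative paths resolve against the YAML file's directory.
#'
#' @param path YAML config.
#' @return list with \code{conditions} (\code{\link{cell_conditions}}),
#'   \code{model} (\code{\link{energy_model}}) and \code{params}
#'   (\code{\link{booking_params}}).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!file.exists(p)) p <- file.path(base, p)
    if (!file.exists(p)) stop(sprintf("config file reference not found: %s", p),
                              call. = FALSE)
    p
  }
  need <- c("mirna_fasta", "mrna_fasta", "regions_bed",
            "mirna_expression", "mrna_expression")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop(sprintf("run config is missing key(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  mirna_seq <- read_fasta(resolve(cfg$mirna_fasta))
  mrna_seq <- read_fasta(resolve(cfg$mrna_fasta))
  regions <- read_regions_bed(resolve(cfg$regions_bed))
  mirna_expr <- read_expression(resolve(cfg$mirna_expression))
  mrna_expr <- read_expression(resolve(cfg$mrna_expression))
  orphans <- setdiff(regions$id, names(mrna_seq))
  if (length(orphans)) {
    stop(sprintf("regions refer to transcripts absent from the FASTA: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  transcripts <- data.frame(id = regions$id,
                            sequence = unname(mrna_seq[regions$id]),
                            cds_start = regions$cds_start,
                            cds_end = regions$cds_end,
                            stringsAsFactors = FALSE)
  conditions <- cell_conditions(cfg$label %||% "condition",
                                mirna_expr, mrna_expr, mirna_seq, transcripts)
  backend <- cfg$energy_backend %||% "nearest-neighbor"
  model <- if (backend == "table") {
    energy_model("table", table = read_delta_g_table(resolve(cfg$delta_g_table)))
  } else {
    energy_model(backend)
  }
  params <- booking_params(tau = cfg$tau %||% 0.0179,
                           alpha = cfg$alpha %||% 512,
                           footprint = cfg$footprint %||% 46L,
                           q_min = cfg$q_min %||% 1.0,
                           sort_order = cfg$sort_order %||% "hp-first")
  list(conditions = conditions, model = model, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a machine-readable run manifest
#'
#' Records input file digests (MD5), parameters and package version next to
#' an output for reproducibility.
#'
#' @param inputs character vector of input file paths.
#' @param params a \code{\link{booking_params}} (or any list).
#' @param path output JSON path.
#' @param extra optional named list of extra fields.
#' @export
write_run_manifest <- function(inputs, params, path, extra = list()) {
  digests <- as.list(tools::md5sum(inputs))
  manifest <- c(list(inputs = digests, parameters = unclass(params),
                     package_version = as.character(utils::packageVersion("mirbooking"))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
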