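# Readers and writers for the plain-text exchange formats. All genomic
# intervals are held internally as 0-based half-open [start, end); CNV call
# tables on disk default to the 1-based inclusive caller convention, gene
# models are BED (already half-open).

read_tsv_checked <- function(path, cols, what, colClasses = NA) {
  check_that(file.exists(path), "%s file not found: %s", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = colClasses,
                          check.names = FALSE)
  check_columns(df, cols, sprintf("%s (%s)", what, path))
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a CNV call table
#'
#' Expects columns `sample_id, chrom, start, end, type, copy_number, n_snps`
#' with `type` in `del`/`dup`. Coordinates on disk are 1-based inclusive by
#' default (`coords = "onebased"`, the CNV-caller convention); use
#' `coords = "bed"` for 0-based half-open input. Internally all intervals are
#' 0-based half-open.
#'
#' @param path TSV file path.
#' @param coords Coordinate convention of the file.
#' @return A data.frame of calls in internal coordinates.
#' @export
read_cnv_calls <- function(path, coords = c("onebased", "bed")) {
  coords <- match.arg(coords)
  df <- read_tsv_checked(path, c("sample_id", "chrom", "start", "end",
                                 "type", "copy_number", "n_snps"),
                         "CNV call table")
  if (coords == "onebased") df$start <- df$start - 1L
  validate_calls(df)
  df
}

#' Write a CNV call table
#' @param calls Call data.frame in internal (0-based half-open) coordinates.
#' @param path Output TSV path.
#' @param coords Convention to write: `"onebased"` (default) or `"bed"`.
#' @export
write_cnv_calls <- function(calls, path, coords = c("onebased", "bed")) {
  coords <- match.arg(coords)
  out <- calls[, c("sample_id", "chrom", "start", "end", "type",
                   "copy_number", "n_snps")]
  if (coords == "onebased") out$start <- out$start + 1L
  write_tsv_plain(out, path)
}

validate_calls <- function(calls) {
  check_columns(calls, c("sample_id", "chrom", "start", "end", "type"),
                "CNV call table")
  check_that(all(calls$start < calls$end),
             "every CNV call must satisfy start < end")
  bad <- setdiff(unique(calls$type), c("del", "dup"))
  check_that(length(bad) == 0L, "unknown CNV type(s): %s",
             paste(bad, collapse = ", "))
  invisible(calls)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id, cohort, ancestry, call_rate, lrr_sd, gcwf, n_cnv,
#' quality_score`; `cohort` is `case`/`control`.
#' @param path TSV file path.
#' @return Sample data.frame.
#' @export
read_samples <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "cohort"), "sample table")
  check_that(!anyDuplicated(df$sample_id), "duplicate sample_id in %s", path)
  bad <- setdiff(unique(df$cohort), c("case", "control"))
  check_that(length(bad) == 0L, "unknown cohort label(s): %s",
             paste(bad, collapse = ", "))
  df
}

#' @rdname read_samples
#' @param samples Sample data.frame.
#' @export
write_samples <- function(samples, path) write_tsv_plain(samples, path)

#' Read gene models from a BED-like TSV
#'
#' Six columns without header: chrom, start, end, symbol, score, strand,
#' 0-based half-open (standard BED).
#' @param path BED file path.
#' @return Gene data.frame with columns `chrom, start, end, symbol, strand`.
#' @export
read_genes_bed <- function(path) {
  check_that(file.exists(path), "gene BED file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_that(ncol(df) >= 4, "gene BED needs at least 4 columns: %s", path)
  names(df)[1:4] <- c("chrom", "start", "end", "symbol")
  df$strand <- if (ncol(df) >= 6) df[[6]] else "+"
  check_that(all(df$start < df$end), "gene intervals must satisfy start < end")
  df[, c("chrom", "start", "end", "symbol", "strand")]
}

#' @rdname read_genes_bed
#' @param genes Gene data.frame.
#' @export
write_genes_bed <- function(genes, path) {
  out <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                    symbol = genes$symbol, score = 0L,
                    strand = if ("strand" %in% names(genes)) genes$strand else "+")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a gene family membership table
#'
#' Two columns `root, member`: one row per family member, keyed by the family
#' root symbol.
#' @param path TSV file path.
#' @export
read_families <- function(path) {
  read_tsv_checked(path, c("root", "member"), "gene family table")
}

#' @rdname read_families
#' @param families Family data.frame.
#' @export
write_families <- function(families, path) write_tsv_plain(families, path)

#' Read / write an IBS pair table
#'
#' Columns `id_a, id_b, ibs` with identity-by-state similarity in [0, 1].
#' @param path TSV file path.
#' @export
read_ibs_pairs <- function(path) {
  df <- read_tsv_checked(path, c("id_a", "id_b", "ibs"), "IBS pair table")
  check_that(all(df$ibs >= 0 & df$ibs <= 1), "ibs values must lie in [0, 1]")
  check_that(all(df$id_a != df$id_b), "IBS pairs must join distinct samples")
  df
}

#' @rdname read_ibs_pairs
#' @param pairs IBS pair data.frame.
#' @export
write_ibs_pairs <- function(pairs, path) write_tsv_plain(pairs, path)

#' Read / write ancestry eigenvector features
#'
#' Columns `sample_id, ev1..evD, label`; `label` is `NA` for samples awaiting
#' classification.
#' @param path TSV file path.
#' @export
read_ancestry_features <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "label"), "ancestry features")
  check_that(any(grepl("^ev[0-9]+$", names(df))),
             "ancestry feature table needs ev1..evD columns")
  df
}

#' @rdname read_ancestry_features
#' @param features Feature data.frame.
#' @export
write_ancestry_features <- function(features, path) {
  write_tsv_plain(features, path)
}

#' Read / write an interactome edge list
#'
#' Two or three tab-separated columns: `source, target[, dataset]`, one edge
#' per line, no header. See [load_interactome()] for the merge semantics.
#' @param pairs,edges,features,calls Data frames to serialise.
#' @param path TSV file path.
#' @export
write_edges <- function(edges, path) {
  out <- edges[, intersect(c("source", "target", "dataset", "datasets"),
                           names(edges))]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
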