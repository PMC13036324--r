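# Plain-text readers/writers shared by the generators and the
# pipeline stages: TSV with header row, Newick, FASTA, JSON sidecars.

#' Write a data frame as TSV with a header row
#'
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#'
#' @param path input path.
#' @return data frame (no name mangling, no factors).
#' @export
read_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a numeric matrix as TSV with an id column
#'
#' @param mat matrix with row names.
#' @param path output path.
#' @param id_col name of the first (row id) column.
#' @return invisibly, `path`.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read and validate a MAG metadata table
#'
#' @param path TSV path with the MAG record columns.
#' @return validated data frame.
#' @export
read_mag_table <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("mag_id", "completeness", "contamination"),
              "MAG table")
  if (any(df$completeness < 0 | df$completeness > 100))
    stopf("completeness outside [0, 100] in %s", path)
  if (any(df$contamination < 0))
    stopf("negative contamination in %s", path)
  for (col in c("has_rrna_5s", "has_rrna_16s", "has_rrna_23s"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Read and validate a sample geography table
#'
#' @param path TSV with `sample_id`, `latitude`, `longitude`,
#'   `elevation`.
#' @return validated data frame.
#' @export
read_sample_geo <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("sample_id", "latitude", "longitude", "elevation"),
              "sample geography")
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stopf("invalid coordinates in %s", path)
  df
}

# sidecar helpers -----------------------------------------------------

write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar written by [sim_write()]
#'
#' @param path JSON path.
#' @return list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulated artifact to disk
#'
#' Every generator output has a `sim_write()` method emitting the
#' artifact's standard formats (Newick / FASTA / TSV with header) plus
#' a `truth.json` ground-truth sidecar used only by tests.  Identical
#' configurations produce byte-identical files.
#'
#' @param x a `gen_*()` result.
#' @param dir output directory (created if absent).
#' @return invisibly, character vector of files written.
#' @export
sim_write <- function(x, dir) UseMethod("sim_write")

#' @export
sim_write.sim_time_tree <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "tree.nwk")
  ape::write.tree(x$tree, f1)
  f2 <- write_tsv(x$groups, file.path(dir, "tip_groups.tsv"))
  f3 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2, f3))
}

#' @export
sim_write.sim_mag_table <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_tsv(x$mags, file.path(dir, "mags.tsv"))
  f2 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2))
}

#' @export
sim_write.sim_ddr <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_matrix_tsv(x$abundance, file.path(dir, "abundance.tsv"),
                         "sample_id")
  f2 <- write_tsv(x$geo, file.path(dir, "geo.tsv"))
  f3 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2, f3))
}

#' @export
sim_write.sim_ncm <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_tsv(x$data, file.path(dir, "ncm_data.tsv"))
  f2 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2))
}

#' @export
sim_write.sim_ko <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_matrix_tsv(x$counts, file.path(dir, "ko_counts.tsv"), "mag_id")
  f2 <- write_tsv(data.frame(mag_id = names(x$sizes),
                             size_mb = unname(x$sizes),
                             ecosystem = unname(x$ecosystems[names(x$sizes)]),
                             stringsAsFactors = FALSE),
                  file.path(dir, "mag_meta.tsv"))
  f3 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2, f3))
}

#' @export
sim_write.sim_bgc <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- write_tsv(x$records, file.path(dir, "bgc_records.tsv"))
  f2 <- write_tsv(x$gene_abund, file.path(dir, "gene_abundance.tsv"))
  f3 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2, f3))
}

#' @export
sim_write.sim_probe <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "target.fasta")
  Biostrings::writeXStringSet(x$target, f1)
  f2 <- file.path(dir, "offtargets.fasta")
  Biostrings::writeXStringSet(x$offtargets, f2)
  f3 <- write_truth_json(x$truth, file.path(dir, "truth.json"))
  invisible(c(f1, f2, f3))
}
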