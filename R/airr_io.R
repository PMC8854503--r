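#' Read per-cell V(D)J contig annotations
#'
#' Reads an assembled-contig annotation table in either the 10x Genomics
#' `filtered_contig_annotations.csv` dialect or the AIRR Rearrangement TSV
#' dialect, and returns one tidy tibble of contig records with a common
#' column set. Default filters keep contigs that belong to a called cell
#' (`is_cell`), are high confidence (when the dialect carries that column)
#' and have at least one UMI; rows whose chain/locus is not one of
#' IGH/IGK/IGL (e.g. 10x "Multi") are skipped with a warning.
#'
#' @param path Path to the contig annotation file.
#' @param dialect `"10x"` (comma-separated, cellranger column names) or
#'   `"airr"` (tab-separated, MiAIRR column names).
#' @param require_full_length If `TRUE` and the dialect carries a
#'   `full_length` column, drop non-full-length contigs. Default keeps them
#'   when productive.
#'
#' @return A tibble with columns `barcode`, `contig_id`, `locus` (one of
#'   `"IGH"`, `"IGK"`, `"IGL"`), `v_gene`, `d_gene`, `j_gene`, `c_gene`,
#'   `cdr3_aa`, `productive`, `umis`, `reads`, `is_cell`,
#'   `high_confidence`, in input row order. Gene names are preserved
#'   verbatim (allele suffixes are kept; comparisons normalise later).
#' @seealso [write_contigs()], [assemble_cells()]
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_contigs(example_contigs(), tmp, dialect = "10x")
#' read_contigs(tmp, dialect = "10x")
read_contigs <- function(path, dialect = c("10x", "airr"),
                         require_full_length = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "10x") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    required <- c("barcode", "is_cell", "contig_id", "high_confidence", "chain",
                  "v_gene", "d_gene", "j_gene", "c_gene", "full_length",
                  "productive", "cdr3", "cdr3_nt", "reads", "umis",
                  "raw_clonotype_id")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort(paste0("not a 10x contig table: missing column(s) ",
                   paste(missing, collapse = ", ")))
    }
    out <- tibble(
      barcode = raw$barcode,
      contig_id = raw$contig_id,
      locus = raw$chain,
      v_gene = empty_gene(raw$v_gene),
      d_gene = empty_gene(raw$d_gene),
      j_gene = empty_gene(raw$j_gene),
      c_gene = empty_gene(raw$c_gene),
      cdr3_aa = empty_gene(raw$cdr3),
      productive = parse_truth(raw$productive),
      umis = as.integer(raw$umis),
      reads = as.integer(raw$reads),
      is_cell = parse_truth(raw$is_cell),
      high_confidence = parse_truth(raw$high_confidence)
    )
    if (require_full_length) out <- out[parse_truth(raw$full_length), , drop = FALSE]
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
    required <- c("cell_id", "locus", "v_call", "d_call", "j_call", "c_call",
                  "junction_aa", "productive", "duplicate_count")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort(paste0("not an AIRR rearrangement table: missing column(s) ",
                   paste(missing, collapse = ", ")))
    }
    nrows <- nrow(raw)
    out <- tibble(
      barcode = raw$cell_id,
      contig_id = if ("sequence_id" %in% names(raw)) raw$sequence_id else
        paste0(raw$cell_id, "_contig_", seq_len(nrows)),
      locus = raw$locus,
      v_gene = empty_gene(raw$v_call),
      d_gene = empty_gene(raw$d_call),
      j_gene = empty_gene(raw$j_call),
      c_gene = empty_gene(raw$c_call),
      cdr3_aa = empty_gene(raw$junction_aa),
      productive = parse_truth(raw$productive),
      umis = as.integer(raw$duplicate_count),
      reads = if ("consensus_count" %in% names(raw))
        as.integer(raw$consensus_count) else as.integer(raw$duplicate_count),
      is_cell = if ("is_cell" %in% names(raw)) parse_truth(raw$is_cell) else TRUE,
      high_confidence = if ("high_confidence" %in% names(raw))
        parse_truth(raw$high_confidence) else TRUE
    )
  }
  bad_locus <- !(out$locus %in% c("IGH", "IGK", "IGL"))
  if (any(bad_locus)) {
    warn(paste0("skipped ", sum(bad_locus),
                " contig(s) with unrecognised chain/locus: ",
                paste(unique(out$locus[bad_locus]), collapse = ", ")))
    out <- out[!bad_locus, , drop = FALSE]
  }
  out <- out %>%
    filter(.data$is_cell, .data$high_confidence, .data$umis >= 1L)
  out
}

#' Write contig records to a dialect-valid annotation file
#'
#' Inverse of [read_contigs()]: writes a contig tibble out as a 10x
#' `filtered_contig_annotations.csv` or an AIRR Rearrangement TSV such that
#' reading it back with the same dialect reproduces the records exactly.
#' Columns the common record model does not carry (10x `cdr3_nt`,
#' `raw_clonotype_id`) are written empty; `full_length` is written true for
#' every retained contig. Missing genes are rendered per dialect ("None"
#' for 10x, empty for AIRR).
#'
#' @param contigs A contig tibble as returned by [read_contigs()].
#' @param path Output file path.
#' @param dialect `"10x"` or `"airr"`.
#' @return The input, invisibly.
#' @export
write_contigs <- function(contigs, path, dialect = c("10x", "airr")) {
  dialect <- match.arg(dialect)
  contigs <- as_tibble(contigs)
  if (dialect == "10x") {
    out <- tibble(
      barcode = contigs$barcode,
      is_cell = render_truth_10x(contigs$is_cell),
      contig_id = contigs$contig_id,
      high_confidence = render_truth_10x(contigs$high_confidence),
      chain = contigs$locus,
      v_gene = render_gene_10x(contigs$v_gene),
      d_gene = render_gene_10x(contigs$d_gene),
      j_gene = render_gene_10x(contigs$j_gene),
      c_gene = render_gene_10x(contigs$c_gene),
      full_length = "True",
      productive = render_truth_10x(contigs$productive),
      cdr3 = render_gene_10x(contigs$cdr3_aa),
      cdr3_nt = "None",
      reads = contigs$reads,
      umis = contigs$umis,
      raw_clonotype_id = ""
    )
    readr::write_csv(out, path, na = "")
  } else {
    out <- tibble(
      cell_id = contigs$barcode,
      sequence_id = contigs$contig_id,
      locus = contigs$locus,
      v_call = contigs$v_gene,
      d_call = contigs$d_gene,
      j_call = contigs$j_gene,
      c_call = contigs$c_gene,
      junction_aa = contigs$cdr3_aa,
      productive = ifelse(contigs$productive, "T", "F"),
      duplicate_count = contigs$umis,
      consensus_count = contigs$reads,
      is_cell = ifelse(contigs$is_cell, "T", "F"),
      high_confidence = ifelse(contigs$high_confidence, "T", "F")
    )
    readr::write_tsv(out, path, na = "")
  }
  invisible(contigs)
}

#' Write the per-cell clonotype table
#'
#' Serialises classified cells (see [assemble_cells()]) to a UTF-8 CSV with
#' one row per cell barcode, sorted by barcode so repeated writes of the
#' same cells are byte-identical.
#'
#' @param cells Classified cell tibble from [assemble_cells()].
#' @param path Output CSV path.
#' @return The input cells, invisibly.
#' @export
write_clonotype_table <- function(cells, path) {
  cols <- c("barcode", "heavy_v_gene", "heavy_d_gene", "heavy_j_gene",
            "heavy_c_gene", "heavy_cdr3_aa", "isotype_class",
            "lc1_locus", "lc1_v_gene", "lc1_j_gene",
            "lc2_locus", "lc2_v_gene", "lc2_j_gene",
            "lc_class", "vh4_34", "analyzable")
  out <- cells %>%
    select(dplyr::any_of(cols)) %>%
    arrange(.data$barcode)
  readr::write_csv(out, path, na = "")
  invisible(cells)
}

#' A tiny example contig table
#'
#' Six contigs over three cells (a single-kappa cell, a kappa/lambda dual
#' cell, and a cell with an ambient non-productive contig), handy for
#' examples and quick interactive checks.
#'
#' @return A contig tibble in the [read_contigs()] column layout.
#' @export
example_contigs <- function() {
  tibble(
    barcode = c("AAACCTGAGAAACCAT-1", "AAACCTGAGAAACCAT-1",
                "AAACCTGAGAAACCTA-1", "AAACCTGAGAAACCTA-1",
                "AAACCTGAGAAACCTA-1", "AAACCTGAGAAACGAG-1"),
    contig_id = paste0("contig_", 1:6),
    locus = c("IGH", "IGK", "IGH", "IGK", "IGL", "IGK"),
    v_gene = c("IGHV4-34*01", "IGKV1-5", "IGHV3-23", "IGKV3-20",
               "IGLV2-14", "IGKV1-39"),
    d_gene = c("IGHD3-10", "", "IGHD2-15", "", "", ""),
    j_gene = c("IGHJ4", "IGKJ1", "IGHJ6", "IGKJ5", "IGLJ2", "IGKJ2"),
    c_gene = c("IGHM", "IGKC", "IGHG1", "IGKC", "IGLC2", "IGKC"),
    cdr3_aa = c("CARGDYW", "CQQYNSYPF", "CARDPAGW", "CQQYGSSPF",
                "CSSYTSSSTF", "CQQSYSTPF"),
    productive = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    umis = c(34L, 28L, 41L, 30L, 17L, 1L),
    reads = c(510L, 420L, 615L, 450L, 255L, 15L),
    is_cell = TRUE,
    high_confidence = TRUE
  )
}

# dialect truth encodings: 10x "True"/"False" (any case), AIRR "T"/"F",
# plus bare TRUE/FALSE from hand-built tables
parse_truth <- function(x) {
  up <- toupper(trimws(x %||% ""))
  up %in% c("TRUE", "T", "1")
}

render_truth_10x <- function(x) ifelse(x, "True", "False")

# 10x renders absent genes as "None"
empty_gene <- function(x) {
  x <- ifelse(is.na(x), "", x)
  ifelse(x %in% c("None", "NA"), "", x)
}

render_gene_10x <- function(x) ifelse(is.na(x) | x == "", "None", x)
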