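#' Secondary light-chain calling parameters
#'
#' Evidence thresholds used when deciding whether a cell genuinely
#' expresses a second light chain rather than carrying an ambient contig.
#' A non-primary light contig is called only when its UMI count reaches
#' `max(min_secondary_umis_abs, ceiling(min_secondary_umis_frac * primary
#' UMIs))`. The default (3 absolute, 10% of the primary chain) absorbs
#' low-UMI ambient contamination while keeping genuinely co-expressed
#' chains, which sit at comparable UMI depth to primary chains.
#'
#' @param min_secondary_umis_abs Absolute UMI floor for a secondary chain
#'   call (integer, >= 1). Default 3.
#' @param min_secondary_umis_frac Secondary chain must also reach this
#'   fraction of the primary chain's UMIs (in `[0, 1]`). Default 0.10.
#' @param require_productive_lc Only productive light contigs are eligible
#'   for chain calls. Default `TRUE`; set `FALSE` for sensitivity analyses
#'   that count non-productive rearrangements.
#' @return A `calling_params` list.
#' @export
calling_params <- function(min_secondary_umis_abs = 3L,
                           min_secondary_umis_frac = 0.10,
                           require_productive_lc = TRUE) {
  min_secondary_umis_abs <- as.integer(min_secondary_umis_abs)
  if (is.na(min_secondary_umis_abs) || min_secondary_umis_abs < 1L)
    abort("min_secondary_umis_abs must be an integer >= 1")
  if (!is.numeric(min_secondary_umis_frac) || min_secondary_umis_frac < 0 ||
      min_secondary_umis_frac > 1)
    abort("min_secondary_umis_frac must be in [0, 1]")
  structure(
    list(min_secondary_umis_abs = min_secondary_umis_abs,
         min_secondary_umis_frac = min_secondary_umis_frac,
         require_productive_lc = isTRUE(require_productive_lc)),
    class = "calling_params"
  )
}

#' Classify heavy-chain isotype from the constant-region gene
#'
#' Cells whose single productive heavy chain carries an IGHM or IGHD
#' constant region are unswitched (`"IgMD"`); IGHG/IGHA/IGHE are
#' class-switched (`"switched"`); anything else (including a missing call)
#' is `"ambiguous"` and excludes the cell from analysis.
#'
#' @param c_gene Character vector of heavy constant-region gene symbols
#'   (e.g. `"IGHM"`, `"IGHG1"`); allele suffixes are ignored.
#' @return Character vector over `{"IgMD", "switched", "ambiguous"}`.
#' @export
#' @examples
#' classify_isotype(c("IGHM", "IGHG1", ""))
classify_isotype <- function(c_gene) {
  g <- normalize_gene(c_gene)
  dplyr::case_when(
    startsWith(g, "IGHM") | startsWith(g, "IGHD") ~ "IgMD",
    startsWith(g, "IGHG") | startsWith(g, "IGHA") | startsWith(g, "IGHE") ~ "switched",
    TRUE ~ "ambiguous"
  )
}

#' Flag IGHV4-34 heavy chains
#'
#' The IGHV4-34 germline segment carries a hydrophobic patch that binds
#' I/i carbohydrate antigens on B cells; clonotypes using it are the ones
#' serum 9G4 reagents detect. Matching strips any `*NN` allele suffix and
#' whitespace and is case-insensitive; stored gene names are unchanged.
#'
#' @param v_gene Character vector of heavy V gene symbols.
#' @return Logical vector, `TRUE` where the gene is IGHV4-34.
#' @export
#' @examples
#' flag_vh434(c("IGHV4-34*01", "IGHV4-39", "ighv4-34"))
flag_vh434 <- function(v_gene) {
  normalize_gene(v_gene) == "IGHV4-34"
}

#' Assemble contigs into classified per-cell clonotypes
#'
#' Groups contig records by cell barcode and applies the clonotype
#' filtering and classification rules: a cell is analyzable when it has
#' exactly one productive heavy chain, an unambiguous isotype (IgM/D or
#' class switched) and one or two called light chains. Light contigs are
#' ranked by UMIs (ties broken by reads, then contig id); the top-ranked
#' eligible contig is the primary chain and further chains are called only
#' when they pass the [calling_params()] evidence threshold. Analyzable
#' cells fall in exactly one of five light-chain classes:
#' `single_kappa`, `single_lambda`, `dual_kappa`, `dual_lambda`,
#' `kappa_lambda`; all other cells are `unclassified`. Cells with three or
#' more called light chains, or two productive heavy chains, are excluded
#' (not treated as dual-receptor cells).
#'
#' @param contigs Contig tibble from [read_contigs()] or
#'   [generate_repertoire()], one sample.
#' @param params Evidence thresholds, see [calling_params()].
#' @return A tibble with one row per barcode: heavy-chain gene calls and
#'   CDR3, `isotype_class`, ranked called light chains (`lc1_*`, `lc2_*`),
#'   `n_light_called`, `lc_class`, `vh4_34` and `analyzable`. Row order
#'   follows first appearance of each barcode in the input.
#' @export
#' @examples
#' assemble_cells(example_contigs())
assemble_cells <- function(contigs, params = calling_params()) {
  stopifnot(inherits(params, "calling_params"))
  contigs <- as_tibble(contigs)
  if (nrow(contigs) == 0) return(empty_cells())
  barcode_order <- unique(contigs$barcode)

  heavy_all <- contigs %>% filter(.data$locus == "IGH")
  heavy_counts <- heavy_all %>%
    group_by(.data$barcode) %>%
    summarise(n_heavy = dplyr::n(),
              n_heavy_productive = sum(.data$productive), .groups = "drop")
  # representative heavy = the single productive one when it exists
  heavy_rep <- heavy_all %>%
    filter(.data$productive) %>%
    arrange(.data$barcode, .data$contig_id) %>%
    distinct(.data$barcode, .keep_all = TRUE) %>%
    select("barcode", heavy_v_gene = "v_gene", heavy_d_gene = "d_gene",
           heavy_j_gene = "j_gene", heavy_c_gene = "c_gene",
           heavy_cdr3_aa = "cdr3_aa", heavy_umis = "umis")
  heavies <- left_join(heavy_counts, heavy_rep, by = "barcode")

  lights <- contigs %>%
    filter(.data$locus %in% c("IGK", "IGL"))
  if (!params$require_productive_lc) {
    eligible <- lights
  } else {
    eligible <- lights %>% filter(.data$productive)
  }
  ranked <- eligible %>%
    arrange(.data$barcode, dplyr::desc(.data$umis), dplyr::desc(.data$reads),
            .data$contig_id) %>%
    mutate(new_bc = .data$barcode != dplyr::lag(.data$barcode, default = "")) %>%
    mutate(
      lc_rank = stats::ave(rep(1L, dplyr::n()), cumsum(.data$new_bc),
                           FUN = cumsum),
      primary_umis = rep(.data$umis[.data$new_bc], diff(c(
        which(.data$new_bc), dplyr::n() + 1L)))
    )
  called <- ranked %>%
    filter(.data$lc_rank == 1L |
             .data$umis >= pmax(params$min_secondary_umis_abs,
                                ceiling(params$min_secondary_umis_frac *
                                          .data$primary_umis))) %>%
    mutate(new_bc = .data$barcode != dplyr::lag(.data$barcode, default = "")) %>%
    mutate(lc_rank = stats::ave(rep(1L, dplyr::n()), cumsum(.data$new_bc),
                                FUN = cumsum))

  n_called <- called %>% count(.data$barcode, name = "n_light_called")
  light_summary <- called %>%
    filter(.data$lc_rank <= 2L) %>%
    select("barcode", "lc_rank", "locus", "v_gene", "j_gene", "umis") %>%
    tidyr::pivot_wider(names_from = "lc_rank",
                       values_from = c("locus", "v_gene", "j_gene", "umis"),
                       names_glue = "lc{lc_rank}_{.value}") %>%
    left_join(n_called, by = "barcode")
  for (col in c("lc1_locus", "lc1_v_gene", "lc1_j_gene",
                "lc2_locus", "lc2_v_gene", "lc2_j_gene")) {
    if (!col %in% names(light_summary))
      light_summary[[col]] <- NA_character_
  }
  for (col in c("lc1_umis", "lc2_umis")) {
    if (!col %in% names(light_summary))
      light_summary[[col]] <- NA_integer_
  }

  cells <- tibble(barcode = barcode_order) %>%
    left_join(heavies, by = "barcode") %>%
    left_join(light_summary, by = "barcode") %>%
    mutate(
      n_heavy = dplyr::coalesce(.data$n_heavy, 0L),
      n_heavy_productive = dplyr::coalesce(.data$n_heavy_productive, 0L),
      n_light_called = dplyr::coalesce(.data$n_light_called, 0L),
      isotype_class = ifelse(.data$n_heavy_productive == 1L,
                             classify_isotype(.data$heavy_c_gene), "ambiguous"),
      vh4_34 = .data$n_heavy_productive == 1L & flag_vh434(.data$heavy_v_gene),
      analyzable = .data$n_heavy_productive == 1L &
        .data$isotype_class != "ambiguous" &
        .data$n_light_called >= 1L & .data$n_light_called <= 2L,
      lc_class = ifelse(.data$analyzable,
                        lc_class_from_loci(.data$lc1_locus, .data$lc2_locus),
                        "unclassified")
    )
  cells
}

# locus multiset -> light-chain class (callers guarantee 1 or 2 called)
lc_class_from_loci <- function(lc1, lc2) {
  dplyr::case_when(
    is.na(lc2) & lc1 == "IGK" ~ "single_kappa",
    is.na(lc2) & lc1 == "IGL" ~ "single_lambda",
    lc1 == "IGK" & lc2 == "IGK" ~ "dual_kappa",
    lc1 == "IGL" & lc2 == "IGL" ~ "dual_lambda",
    TRUE ~ "kappa_lambda"
  )
}

empty_cells <- function() {
  tibble(
    barcode = character(0), n_heavy = integer(0),
    n_heavy_productive = integer(0), heavy_v_gene = character(0),
    heavy_d_gene = character(0), heavy_j_gene = character(0),
    heavy_c_gene = character(0), heavy_cdr3_aa = character(0),
    heavy_umis = integer(0), n_light_called = integer(0),
    lc1_locus = character(0), lc1_v_gene = character(0),
    lc1_j_gene = character(0), lc1_umis = integer(0),
    lc2_locus = character(0), lc2_v_gene = character(0),
    lc2_j_gene = character(0), lc2_umis = integer(0),
    isotype_class = character(0), vh4_34 = logical(0),
    analyzable = logical(0), lc_class = character(0)
  )
}

#' The five analyzable light-chain classes, in canonical order
#' @return Character vector of class labels.
#' @export
lc_classes <- function() {
  c("single_kappa", "single_lambda", "dual_kappa", "dual_lambda", "kappa_lambda")
}
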