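#' Configuration for the synthetic repertoire generator
#'
#' Defaults encode the statistical structure of circulating human B-cell
#' repertoires that the analysis assumes: roughly 1:1 kappa:lambda usage
#' among single light-chain cells, ~2% kappa/lambda dual cells and ~5%
#' dual light-chain cells in total, ~5% IGHV4-34 heavy-chain usage, ~20%
#' class-switched cells, and a receptor-editing walk that skews the
#' Jkappa usage of included (dual) cells toward distal segments.
#'
#' @param n_cells Number of cells to generate.
#' @param p_lambda Probability a single-light-chain cell uses lambda.
#' @param p_kl,p_kk,p_ll Probabilities that a cell is kappa/lambda,
#'   dual-kappa, dual-lambda included (defaults 0.02, 0.02, 0.01 — about
#'   5% dual cells in total).
#' @param p_vh434 Probability the heavy chain uses IGHV4-34 (default 0.05).
#' @param p_switched Probability a cell is class switched (default 0.20).
#' @param edit_mean Mean number of receptor-editing rounds for
#'   non-included cells (geometric; included cells use twice this mean).
#' @param jk_prior Initial-rearrangement probabilities over IGKJ1..IGKJ5
#'   (proximal to distal).
#' @param umi_mean_primary,umi_mean_secondary Mean UMI counts of primary
#'   and secondary chains (negative binomial).
#' @param nb_dispersion UMI variance inflation: variance =
#'   `nb_dispersion * mean` (must exceed 1; default 2).
#' @param ambient_rate Expected number of spurious non-productive low-UMI
#'   contigs per cell (Poisson; default 0.05).
#' @param subset_priors Named probabilities of the coarse B-cell subset
#'   labels (naive, aNAV, MZlike, BND, DN, switched_memory); sampled
#'   independently of the receptor genotype.
#' @param seed Optional RNG seed; with a seed the generator output is a
#'   pure function of the configuration.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_cells = 5000,
                             p_lambda = 0.5,
                             p_kl = 0.02, p_kk = 0.02, p_ll = 0.01,
                             p_vh434 = 0.05,
                             p_switched = 0.20,
                             edit_mean = 0.5,
                             jk_prior = c(0.40, 0.25, 0.15, 0.10, 0.10),
                             umi_mean_primary = 30,
                             umi_mean_secondary = 15,
                             nb_dispersion = 2.0,
                             ambient_rate = 0.05,
                             subset_priors = c(naive = 0.50, aNAV = 0.03,
                                               MZlike = 0.10, BND = 0.05,
                                               DN = 0.07, switched_memory = 0.25),
                             seed = NULL) {
  probs <- c(p_lambda = p_lambda, p_kl = p_kl, p_kk = p_kk, p_ll = p_ll,
             p_vh434 = p_vh434, p_switched = p_switched)
  if (any(probs < 0 | probs > 1))
    abort("all probabilities must lie in [0, 1]")
  if (p_kl + p_kk + p_ll > 1)
    abort("p_kl + p_kk + p_ll must not exceed 1")
  if (length(jk_prior) != 5 || any(jk_prior < 0) ||
      abs(sum(jk_prior) - 1) > 1e-9)
    abort("jk_prior must be 5 non-negative probabilities summing to 1")
  if (edit_mean < 0) abort("edit_mean must be non-negative")
  if (nb_dispersion <= 1) abort("nb_dispersion must exceed 1 (variance > mean)")
  if (ambient_rate < 0) abort("ambient_rate must be non-negative")
  if (any(subset_priors < 0) || abs(sum(subset_priors) - 1) > 1e-9)
    abort("subset_priors must sum to 1")
  structure(
    list(n_cells = as.integer(n_cells), p_lambda = p_lambda,
         p_kl = p_kl, p_kk = p_kk, p_ll = p_ll, p_vh434 = p_vh434,
         p_switched = p_switched, edit_mean = edit_mean,
         jk_prior = unname(jk_prior),
         umi_mean_primary = umi_mean_primary,
         umi_mean_secondary = umi_mean_secondary,
         nb_dispersion = nb_dispersion, ambient_rate = ambient_rate,
         subset_priors = subset_priors, seed = seed),
    class = "generator_config"
  )
}

# gene pools: symbols adequate for usage statistics, no germline database
# needed. Heavy V usage follows a truncated power law.
ighv_pool <- function() {
  c("IGHV1-2", "IGHV1-18", "IGHV1-46", "IGHV1-69", "IGHV2-5", "IGHV2-70",
    "IGHV3-7", "IGHV3-9", "IGHV3-11", "IGHV3-15", "IGHV3-21", "IGHV3-23",
    "IGHV3-30", "IGHV3-33", "IGHV3-43", "IGHV3-48", "IGHV3-53", "IGHV3-74",
    "IGHV4-4", "IGHV4-31", "IGHV4-34", "IGHV4-39", "IGHV4-59", "IGHV4-61",
    "IGHV5-51", "IGHV6-1", "IGHV7-4-1", "IGHV1-8", "IGHV3-64", "IGHV5-10-1")
}

ighv_weights <- function() {
  pool <- ighv_pool()
  w <- seq_along(pool)^-0.8
  names(w) <- pool
  w
}

igkv_pool <- function() {
  c("IGKV1-5", "IGKV1-39", "IGKV1-33", "IGKV2-28", "IGKV2-30", "IGKV3-11",
    "IGKV3-15", "IGKV3-20", "IGKV4-1", "IGKV1-9", "IGKV1-12", "IGKV1-27")
}

iglv_pool <- function() {
  c("IGLV1-40", "IGLV1-44", "IGLV1-51", "IGLV2-8", "IGLV2-11", "IGLV2-14",
    "IGLV2-23", "IGLV3-1", "IGLV3-19", "IGLV3-21")
}

#' Sample Jkappa segments under the receptor-editing walk
#'
#' Models secondary kappa rearrangement: an initial Jkappa is drawn from
#' `jk_prior`; a geometric number of editing rounds follows (mean
#' `edit_mean`, doubled for allelically/isotypically included cells,
#' encoding the interpretation that inclusion arises during editing); each
#' round re-draws a segment strictly downstream (distal) of the current
#' one from the renormalised prior, and editing halts at IGKJ5. More
#' editing therefore shifts mass from IGKJ1 toward IGKJ5.
#'
#' @param n Number of chains to draw.
#' @param is_included Logical scalar or length-`n` vector: is the chain on
#'   an included (dual light-chain) cell?
#' @param config A [generator_config()].
#' @return A tibble with `j_gene` (e.g. `"IGKJ5"`), `j_index` (1-5) and
#'   `rounds` (editing rounds drawn).
#' @export
#' @examples
#' sample_jk_with_editing(5, FALSE, generator_config(seed = 1))
sample_jk_with_editing <- function(n, is_included, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  is_included <- rep_len(as.logical(is_included), n)
  prior <- config$jk_prior
  j <- sample.int(5L, n, replace = TRUE, prob = prior)
  mean_rounds <- ifelse(is_included, 2 * config$edit_mean, config$edit_mean)
  # geometric number of rounds with the given mean: P(success) = 1/(1+m)
  rounds <- rgeom(n, 1 / (1 + mean_rounds))
  left <- rounds
  while (any(active <- left > 0L & j < 5L)) {
    idx <- which(active)
    # renormalised draw strictly downstream of the current segment; the
    # pre-round states are frozen so each round edits every chain once
    u <- runif(length(idx))
    cur_j <- j[idx]
    for (cur in sort(unique(cur_j))) {
      sel <- which(cur_j == cur)
      p <- prior[(cur + 1L):5L]
      cdf <- cumsum(p / sum(p))
      j[idx[sel]] <- cur + findInterval(u[sel], cdf, left.open = TRUE) + 1L
    }
    left[idx] <- left[idx] - 1L
  }
  tibble(j_gene = paste0("IGKJ", j), j_index = j, rounds = rounds)
}

#' Generate a synthetic single-cell BCR repertoire
#'
#' Draws `n_cells` ground-truth cells (inclusion category, heavy and light
#' chain gene usage, isotype, subset label, editing-driven Jkappa usage)
#' and emits the contig records a V(D)J assembly pipeline would report for
#' them: one productive contig per expressed chain with negative-binomial
#' UMI counts (secondary chains at lower depth), plus Poisson-distributed
#' spurious non-productive low-UMI ambient contigs. With `config$seed`
#' set, output is fully reproducible.
#'
#' @param config A [generator_config()].
#' @return A list of class `b2r_repertoire` with `truth` (one row per
#'   cell: `barcode`, `true_lc_class`, `subset`, `isotype_class`,
#'   `vh4_34`, heavy genes, per-chain light loci / Jkappa / surface
#'   weights) and `contigs` (one row per contig, [read_contigs()] layout).
#' @export
#' @examples
#' rep <- generate_repertoire(generator_config(n_cells = 100, seed = 1))
#' dplyr::count(rep$truth, true_lc_class)
generate_repertoire <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed_if(config$seed, generate_repertoire_impl(config))
}

generate_repertoire_impl <- function(config) {
  n <- config$n_cells
  if (n == 0L) {
    return(structure(list(truth = empty_truth(), contigs = empty_contig_tbl(),
                          config = config), class = "b2r_repertoire"))
  }
  barcode <- make_barcodes(n)

  category <- sample_categorical(
    n, c("kappa_lambda", "dual_kappa", "dual_lambda", "single"),
    c(config$p_kl, config$p_kk, config$p_ll,
      1 - config$p_kl - config$p_kk - config$p_ll))
  single_lambda <- runif(n) < config$p_lambda
  true_lc_class <- ifelse(category == "single",
                          ifelse(single_lambda, "single_lambda", "single_kappa"),
                          category)
  included <- category != "single"

  subset <- sample_categorical(n, names(config$subset_priors),
                               as.numeric(config$subset_priors))

  # heavy chain
  vh4_34 <- runif(n) < config$p_vh434
  w <- ighv_weights()
  other <- names(w)[names(w) != "IGHV4-34"]
  heavy_v <- ifelse(vh4_34, "IGHV4-34",
                    sample_categorical(n, other, w[other]))
  heavy_d <- sample_categorical(
    n, c("IGHD1-26", "IGHD2-15", "IGHD3-10", "IGHD3-22", "IGHD6-19", ""),
    c(0.18, 0.18, 0.22, 0.16, 0.16, 0.10))
  heavy_j <- sample_categorical(n, paste0("IGHJ", 1:6),
                                c(0.04, 0.06, 0.12, 0.38, 0.08, 0.32))
  switched <- runif(n) < config$p_switched
  heavy_c <- ifelse(
    switched,
    sample_categorical(n, c("IGHG1", "IGHG2", "IGHG3", "IGHA1", "IGHA2", "IGHE"),
                       c(0.42, 0.25, 0.10, 0.14, 0.06, 0.03)),
    sample_categorical(n, c("IGHM", "IGHD"), c(0.90, 0.10)))
  isotype_class <- ifelse(switched, "switched", "IgMD")
  cdr3_len <- pmin(30L, pmax(8L, round(rnorm(n, 15.5, 3))))
  heavy_cdr3 <- random_aa(n, cdr3_len, "C", "W")

  # light chains: chain 1 is the primary (higher expression)
  lc1_locus <- dplyr::case_when(
    true_lc_class %in% c("single_kappa", "dual_kappa") ~ "IGK",
    true_lc_class %in% c("single_lambda", "dual_lambda") ~ "IGL",
    TRUE ~ ifelse(runif(n) < 0.5, "IGK", "IGL"))
  lc2_locus <- dplyr::case_when(
    true_lc_class == "dual_kappa" ~ "IGK",
    true_lc_class == "dual_lambda" ~ "IGL",
    true_lc_class == "kappa_lambda" ~ ifelse(lc1_locus == "IGK", "IGL", "IGK"),
    TRUE ~ NA_character_)

  jk <- draw_light_genes(lc1_locus, included, config)
  jk2 <- draw_light_genes(lc2_locus, included, config)
  lc1_weight <- rep(1, n)
  lc2_weight <- ifelse(is.na(lc2_locus), NA_real_, runif(n, 0.2, 1))

  truth <- tibble(
    barcode = barcode, true_lc_class = true_lc_class, subset = subset,
    isotype_class = isotype_class, vh4_34 = vh4_34,
    heavy_v_gene = heavy_v, heavy_j_gene = heavy_j, heavy_c_gene = heavy_c,
    lc1_locus = lc1_locus, lc1_v_gene = jk$v_gene, lc1_j_gene = jk$j_gene,
    lc1_edit_rounds = jk$rounds, lc1_weight = lc1_weight,
    lc2_locus = lc2_locus, lc2_v_gene = jk2$v_gene, lc2_j_gene = jk2$j_gene,
    lc2_edit_rounds = jk2$rounds, lc2_weight = lc2_weight
  )

  # contig emission
  disp <- config$nb_dispersion
  heavy_umis <- rumi(n, config$umi_mean_primary, disp)
  lc1_umis <- rumi(n, config$umi_mean_primary, disp)
  has2 <- !is.na(lc2_locus)
  lc2_umis <- ifelse(has2, rumi(n, config$umi_mean_secondary, disp), NA_integer_)

  heavy_contigs <- tibble(
    barcode = barcode, locus = "IGH", v_gene = heavy_v, d_gene = heavy_d,
    j_gene = heavy_j,
    c_gene = heavy_c, cdr3_aa = heavy_cdr3, productive = TRUE,
    umis = as.integer(heavy_umis))
  lc1_contigs <- tibble(
    barcode = barcode, locus = lc1_locus, v_gene = jk$v_gene, d_gene = "",
    j_gene = jk$j_gene, c_gene = jk$c_gene,
    cdr3_aa = random_aa(n, 9L + (runif(n) < 0.3), "C", "F"),
    productive = TRUE, umis = as.integer(lc1_umis))
  n2 <- sum(has2)
  lc2_contigs <- tibble(
    barcode = barcode[has2], locus = lc2_locus[has2],
    v_gene = jk2$v_gene[has2], d_gene = "", j_gene = jk2$j_gene[has2],
    c_gene = jk2$c_gene[has2],
    cdr3_aa = random_aa(n2, 9L + (runif(n2) < 0.3), "C", "F"),
    productive = TRUE, umis = as.integer(lc2_umis[has2]))

  n_amb <- rpois(n, config$ambient_rate)
  total_amb <- sum(n_amb)
  if (total_amb > 0) {
    ambient <- tibble(
      barcode = rep(barcode, n_amb),
      locus = sample_categorical(total_amb, c("IGH", "IGK", "IGL"),
                                 c(0.3, 0.4, 0.3)),
      v_gene = "", d_gene = "", j_gene = "", c_gene = "", cdr3_aa = "",
      productive = FALSE,
      umis = sample(1:2, total_amb, replace = TRUE))
    ambient$v_gene <- ifelse(ambient$locus == "IGH",
                             sample_categorical(total_amb, ighv_pool(), ighv_weights()),
                             ifelse(ambient$locus == "IGK",
                                    sample_categorical(total_amb, igkv_pool(),
                                                       rep(1, length(igkv_pool()))),
                                    sample_categorical(total_amb, iglv_pool(),
                                                       rep(1, length(iglv_pool())))))
  } else {
    ambient <- NULL
  }

  contigs <- bind_rows(heavy_contigs, lc1_contigs, lc2_contigs, ambient) %>%
    arrange(.data$barcode, .data$locus, dplyr::desc(.data$umis)) %>%
    mutate(
      reads = as.integer(.data$umis * sample(8:30, dplyr::n(), replace = TRUE)),
      is_cell = TRUE, high_confidence = TRUE
    ) %>%
    group_by(.data$barcode) %>%
    mutate(contig_id = paste0(.data$barcode, "_contig_", row_number())) %>%
    ungroup() %>%
    select("barcode", "contig_id", "locus", "v_gene", "d_gene", "j_gene",
           "c_gene", "cdr3_aa", "productive", "umis", "reads", "is_cell",
           "high_confidence")

  structure(list(truth = truth, contigs = contigs, config = config),
            class = "b2r_repertoire")
}

# V/J/C genes for one light chain vector (NA locus rows -> NA genes);
# kappa chains take their J from the editing walk
draw_light_genes <- function(locus, included, config) {
  n <- length(locus)
  out <- tibble(v_gene = NA_character_, j_gene = NA_character_,
                c_gene = NA_character_, rounds = NA_integer_, .rows = n)
  isk <- !is.na(locus) & locus == "IGK"
  isl <- !is.na(locus) & locus == "IGL"
  if (any(isk)) {
    jk <- sample_jk_with_editing(sum(isk), included[isk], config)
    out$j_gene[isk] <- jk$j_gene
    out$rounds[isk] <- jk$rounds
    out$v_gene[isk] <- sample_categorical(sum(isk), igkv_pool(),
                                          rep(1, length(igkv_pool())))
    out$c_gene[isk] <- "IGKC"
  }
  if (any(isl)) {
    out$v_gene[isl] <- sample_categorical(sum(isl), iglv_pool(),
                                          rep(1, length(iglv_pool())))
    out$j_gene[isl] <- sample_categorical(sum(isl),
                                          c("IGLJ1", "IGLJ2", "IGLJ3", "IGLJ7"),
                                          c(0.15, 0.40, 0.35, 0.10))
    out$c_gene[isl] <- sample_categorical(sum(isl),
                                          c("IGLC1", "IGLC2", "IGLC3", "IGLC7"),
                                          c(0.25, 0.35, 0.30, 0.10))
  }
  out
}

#' @export
print.b2r_repertoire <- function(x, ...) {
  cat("<b2r_repertoire>", nrow(x$truth), "cells,", nrow(x$contigs), "contigs\n")
  invisible(x)
}

empty_truth <- function() {
  tibble(barcode = character(0), true_lc_class = character(0),
         subset = character(0), isotype_class = character(0),
         vh4_34 = logical(0), heavy_v_gene = character(0),
         heavy_j_gene = character(0), heavy_c_gene = character(0),
         lc1_locus = character(0), lc1_v_gene = character(0),
         lc1_j_gene = character(0), lc1_edit_rounds = integer(0),
         lc1_weight = numeric(0), lc2_locus = character(0),
         lc2_v_gene = character(0), lc2_j_gene = character(0),
         lc2_edit_rounds = integer(0), lc2_weight = numeric(0))
}

empty_contig_tbl <- function() {
  tibble(barcode = character(0), contig_id = character(0),
         locus = character(0), v_gene = character(0), d_gene = character(0),
         j_gene = character(0), c_gene = character(0), cdr3_aa = character(0),
         productive = logical(0), umis = integer(0), reads = integer(0),
         is_cell = logical(0), high_confidence = logical(0))
}
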