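# Brute-force re-statement of the clonotype rules, written independently
# of assemble_cells(): plain loops and explicit if/else per barcode. Used
# as the oracle in equivalence tests.

oracle_strip_allele <- function(g) toupper(trimws(sub("\\*.*", "", g)))

oracle_isotype <- function(c_gene) {
  g <- oracle_strip_allele(c_gene)
  if (is.na(g) || nchar(g) < 4) return("ambiguous")
  p4 <- substr(g, 1, 4)
  if (p4 %in% c("IGHM", "IGHD")) return("IgMD")
  if (p4 %in% c("IGHG", "IGHA", "IGHE")) return("switched")
  "ambiguous"
}

oracle_classify_barcode <- function(df, params = calling_params()) {
  res <- list(isotype_class = "ambiguous", lc_class = "unclassified",
              vh4_34 = FALSE, analyzable = FALSE, n_light_called = 0L)
  heavy <- df[df$locus == "IGH", , drop = FALSE]
  prod_heavy <- heavy[heavy$productive, , drop = FALSE]
  one_heavy <- nrow(prod_heavy) == 1
  if (one_heavy) {
    res$isotype_class <- oracle_isotype(prod_heavy$c_gene)
    res$vh4_34 <- oracle_strip_allele(prod_heavy$v_gene) == "IGHV4-34"
  }
  lights <- df[df$locus %in% c("IGK", "IGL"), , drop = FALSE]
  if (params$require_productive_lc)
    lights <- lights[lights$productive, , drop = FALSE]
  if (nrow(lights) > 0) {
    ord <- order(-lights$umis, -lights$reads, lights$contig_id)
    lights <- lights[ord, , drop = FALSE]
    thr <- max(params$min_secondary_umis_abs,
               ceiling(params$min_secondary_umis_frac * lights$umis[1]))
    keep <- rep(FALSE, nrow(lights))
    keep[1] <- TRUE
    if (nrow(lights) > 1) {
      for (i in 2:nrow(lights)) keep[i] <- lights$umis[i] >= thr
    }
    called <- lights[keep, , drop = FALSE]
    res$n_light_called <- nrow(called)
    if (one_heavy && res$isotype_class != "ambiguous" &&
        nrow(called) %in% 1:2) {
      res$analyzable <- TRUE
      loci <- called$locus
      if (length(loci) == 1) {
        res$lc_class <- if (loci == "IGK") "single_kappa" else "single_lambda"
      } else if (all(loci == "IGK")) {
        res$lc_class <- "dual_kappa"
      } else if (all(loci == "IGL")) {
        res$lc_class <- "dual_lambda"
      } else {
        res$lc_class <- "kappa_lambda"
      }
    }
  }
  res
}

# random contig sets designed to hit the rule edges: multiple heavies,
# non-productive chains, UMI ties, allele suffixes, odd constant genes
random_contig_set <- function(n_barcodes, max_contigs = 6) {
  rows <- list()
  for (b in seq_len(n_barcodes)) {
    k <- sample(0:max_contigs, 1)
    if (k == 0) next
    bc <- sprintf("BC%04d-1", b)
    for (i in seq_len(k)) {
      locus <- sample(c("IGH", "IGK", "IGL"), 1, prob = c(0.35, 0.35, 0.3))
      v <- switch(locus,
                  IGH = sample(c("IGHV4-34", "IGHV4-34*01", "ighv4-34",
                                 "IGHV3-23", "IGHV1-69"), 1),
                  IGK = sample(c("IGKV1-5", "IGKV3-20*02"), 1),
                  IGL = sample(c("IGLV2-14", "IGLV3-1*01"), 1))
      cg <- switch(locus,
                   IGH = sample(c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHA1",
                                  "IGHE", "", "IGHX"), 1),
                   IGK = "IGKC", IGL = "IGLC2")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        barcode = bc,
        contig_id = sprintf("%s_c%02d", bc, i),
        locus = locus, v_gene = v, d_gene = "",
        j_gene = if (locus == "IGK") sample(paste0("IGKJ", 1:5), 1) else "IGXJ1",
        c_gene = cg, cdr3_aa = "CASSF",
        productive = runif(1) < 0.8,
        umis = sample(c(1:6, 10L, 30L, 40L), 1),
        reads = sample(c(10L, 100L, 100L), 1),
        is_cell = TRUE, high_confidence = TRUE)
    }
  }
  dplyr::bind_rows(rows)
}

# random valid contig records for I/O round-trip tests
random_contig_records <- function(n) {
  locus <- sample(c("IGH", "IGK", "IGL"), n, replace = TRUE)
  tibble::tibble(
    barcode = sprintf("RT%05d-1", sample.int(10 * n, n)),
    contig_id = sprintf("rt_contig_%04d", seq_len(n)),
    locus = locus,
    v_gene = ifelse(locus == "IGH", "IGHV4-34*01",
                    ifelse(locus == "IGK", "IGKV1-5", "IGLV2-14")),
    d_gene = ifelse(locus == "IGH" & runif(n) < 0.5, "IGHD3-10", ""),
    j_gene = ifelse(locus == "IGH", "IGHJ4",
                    ifelse(locus == "IGK", "IGKJ5", "IGLJ2")),
    c_gene = ifelse(locus == "IGH",
                    sample(c("IGHM", "IGHG1", ""), n, replace = TRUE),
                    ifelse(locus == "IGK", "IGKC", "IGLC2")),
    cdr3_aa = ifelse(runif(n) < 0.1, "", "CARDYW"),
    productive = runif(n) < 0.85,
    umis = sample(1:80, n, replace = TRUE),
    reads = sample(1:900, n, replace = TRUE),
    is_cell = TRUE,
    high_confidence = TRUE
  )
}

binom_3sd_pct <- function(p, n) 300 * sqrt(p * (1 - p) / n)

# exact post-editing Jkappa distribution: geometric mixture of powers of
# the one-round distal-redraw transition matrix
jk_walk_expected <- function(jk_prior, mean_rounds, tol = 1e-12) {
  Tm <- matrix(0, 5, 5)
  for (i in 1:4) Tm[i, (i + 1):5] <- jk_prior[(i + 1):5] / sum(jk_prior[(i + 1):5])
  Tm[5, 5] <- 1
  p_stop <- 1 / (1 + mean_rounds)
  dist <- numeric(5)
  state <- jk_prior
  r <- 0
  repeat {
    w <- p_stop * (1 - p_stop)^r  # P(rounds = r)
    dist <- dist + w * state
    if (w < tol && r > 10) break
    state <- as.numeric(state %*% Tm)
    r <- r + 1
  }
  dist / sum(dist)
}
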