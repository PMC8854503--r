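# internal helpers shared across modules

# vectorised categorical draw: one value per row of `prob` support
sample_categorical <- function(n, values, prob) {
  stopifnot(length(values) == length(prob), all(prob >= 0))
  values[sample.int(length(values), n, replace = TRUE, prob = prob)]
}

# NB counts with variance = dispersion * mean (dispersion > 1), floored at 1
# so every emitted contig has molecular support
rumi <- function(n, mean, dispersion) {
  stopifnot(dispersion > 1, mean > 0)
  pmax(1L, rnbinom(n, size = mean / (dispersion - 1), mu = mean))
}

# deterministic unique cell barcodes in 10x style: 16-mer over ACGT + "-1"
make_barcodes <- function(n) {
  if (n == 0L) return(character(0))
  idx <- seq_len(n) - 1L
  chars <- c("A", "C", "G", "T")
  out <- matrix("A", nrow = n, ncol = 16L)
  for (pos in 16:1) {
    out[, pos] <- chars[idx %% 4L + 1L]
    idx <- idx %/% 4L
  }
  paste0(apply(out, 1L, paste0, collapse = ""), "-1")
}

# strip IMGT allele suffix ("*01") and whitespace for gene comparisons;
# stored gene names are never modified
normalize_gene <- function(x) {
  toupper(trimws(sub("\\*.*$", "", x %||% "")))
}

random_aa <- function(n, len, prefix = "C", suffix = "W") {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  core <- pmax(0L, len - nchar(prefix) - nchar(suffix))
  if (n == 0L) return(character(0))
  # vectorised: slice random windows out of one long random residue string
  pool_len <- 10000L
  pool <- paste0(sample(aa, pool_len, replace = TRUE), collapse = "")
  start <- sample.int(pool_len - max(core, 1L), n, replace = TRUE)
  body <- substring(pool, start, start + core - 1L)
  paste0(prefix, body, suffix)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
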