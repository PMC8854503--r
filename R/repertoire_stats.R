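#' Summarise a classified single-cell repertoire
#'
#' Computes the per-sample frequency tables used throughout the analysis:
#' heavy V gene usage, Jkappa usage (proximal IGKJ1 through distal IGKJ5),
#' light-chain class fractions, IGHV4-34 usage by isotype, heavy CDR3
#' amino-acid length, and the class-switched fraction.
#'
#' Denominators: V usage is computed over cells with exactly one
#' productive heavy chain; light-chain class fractions, CDR3 length and
#' switched fraction over analyzable cells; Jkappa usage over called
#' kappa chains (both chains of a dual-kappa cell count) within the
#' `jk_subset` cells — by default unswitched (IgM/D) clonotypes, the
#' subset in which receptor-editing skew is read out. CDR3 length is the
#' length of the delivered `cdr3_aa` string, flanking residues included.
#'
#' @param cells Classified cell tibble from [assemble_cells()].
#' @param sample_id Sample label carried into the summary.
#' @param jk_subset Cells contributing kappa chains to Jkappa usage:
#'   `"IgMD"` (default), `"switched"`, or `"all"`.
#' @return A `b2r_repertoire_summary` object: a list with `sample_id`,
#'   `n_cells`, `n_analyzable`, tibbles `vh_usage`, `jk_usage`,
#'   `lc_class_fractions`, `vh434_by_isotype`, and scalars
#'   `cdr3_len_mean`, `cdr3_len_sd`, `switched_fraction`, `kl_pct`
#'   (kappa+lambda+ percent of analyzable cells), `dual_pct` (all dual
#'   classes). [glance()] returns the scalars as one row; [tidy()] returns
#'   the light-chain class table.
#' @export
summarize_repertoire <- function(cells, sample_id = "sample",
                                 jk_subset = c("IgMD", "switched", "all")) {
  jk_subset <- match.arg(jk_subset)
  cells <- as_tibble(cells)
  ana <- cells %>% filter(.data$analyzable)
  one_heavy <- cells %>% filter(.data$n_heavy_productive == 1L)

  vh_usage <- one_heavy %>%
    count(v_gene = normalize_gene(.data$heavy_v_gene), name = "n") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n), .data$v_gene)

  jk_cells <- switch(jk_subset, all = ana,
                     ana %>% filter(.data$isotype_class == jk_subset))
  jk_calls <- c(
    jk_cells$lc1_j_gene[!is.na(jk_cells$lc1_locus) & jk_cells$lc1_locus == "IGK"],
    jk_cells$lc2_j_gene[!is.na(jk_cells$lc2_locus) & jk_cells$lc2_locus == "IGK"]
  )
  jk_levels <- paste0("IGKJ", 1:5)
  jk_n <- as.integer(table(factor(normalize_gene(jk_calls), levels = jk_levels)))
  jk_usage <- tibble(
    j_gene = jk_levels, n = jk_n,
    fraction = if (sum(jk_n) > 0) jk_n / sum(jk_n) else rep(NA_real_, 5)
  )

  lc_n <- as.integer(table(factor(ana$lc_class, levels = lc_classes())))
  lc_class_fractions <- tibble(
    lc_class = lc_classes(), n = lc_n,
    fraction = if (nrow(ana) > 0) lc_n / nrow(ana) else rep(NA_real_, 5)
  )

  vh434_by_isotype <- ana %>%
    group_by(isotype_class = .data$isotype_class) %>%
    summarise(n = dplyr::n(), n_vh434 = sum(.data$vh4_34),
              fraction = mean(.data$vh4_34), .groups = "drop")

  cdr3_len <- nchar(ana$heavy_cdr3_aa)
  kl_frac <- lc_class_fractions$fraction[lc_class_fractions$lc_class == "kappa_lambda"]
  dual_frac <- sum(lc_class_fractions$fraction[lc_class_fractions$lc_class %in%
                     c("dual_kappa", "dual_lambda", "kappa_lambda")])

  structure(
    list(
      sample_id = sample_id,
      n_cells = nrow(cells),
      n_analyzable = nrow(ana),
      vh_usage = vh_usage,
      jk_usage = jk_usage,
      jk_subset = jk_subset,
      lc_class_fractions = lc_class_fractions,
      vh434_by_isotype = vh434_by_isotype,
      vh434_fraction = if (nrow(ana) > 0) mean(ana$vh4_34) else NA_real_,
      cdr3_len_mean = if (nrow(ana) > 0) mean(cdr3_len) else NA_real_,
      cdr3_len_sd = if (nrow(ana) > 1) sd(cdr3_len) else NA_real_,
      switched_fraction = if (nrow(ana) > 0)
        mean(ana$isotype_class == "switched") else NA_real_,
      kl_pct = 100 * kl_frac,
      dual_pct = 100 * dual_frac
    ),
    class = "b2r_repertoire_summary"
  )
}

#' @export
print.b2r_repertoire_summary <- function(x, ...) {
  cat("<b2r_repertoire_summary> sample:", x$sample_id, "\n")
  cat("  cells:", x$n_cells, " analyzable:", x$n_analyzable, "\n")
  cat(sprintf("  kappa+lambda+: %.2f%%  total dual-LC: %.2f%%  VH4-34: %.2f%%\n",
              x$kl_pct, x$dual_pct, 100 * x$vh434_fraction))
  cat(sprintf("  switched: %.1f%%  CDR3 length: %.1f +/- %.1f aa\n",
              100 * x$switched_fraction, x$cdr3_len_mean, x$cdr3_len_sd))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.b2r_repertoire_summary <- function(x, ...) {
  tibble(
    sample_id = x$sample_id, n_cells = x$n_cells,
    n_analyzable = x$n_analyzable, kl_pct = x$kl_pct, dual_pct = x$dual_pct,
    vh434_pct = 100 * x$vh434_fraction,
    switched_pct = 100 * x$switched_fraction,
    cdr3_len_mean = x$cdr3_len_mean, cdr3_len_sd = x$cdr3_len_sd
  )
}

#' @exportS3Method generics::tidy
tidy.b2r_repertoire_summary <- function(x, ...) {
  x$lc_class_fractions %>% mutate(sample_id = x$sample_id, .before = 1)
}

#' Flow-cytometry threshold for calling a patient kappa+lambda+ high
#'
#' The elevated (H) group is defined relative to healthy controls as a
#' kappa+lambda+ B-cell frequency greater than the control mean plus three
#' control standard deviations (sample SD, n - 1 denominator).
#'
#' @param control_freqs Per-subject kappa+lambda+ percentages of at least
#'   two healthy controls.
#' @return The threshold, in the same percentage units.
#' @export
#' @examples
#' high_kl_threshold(c(0.3, 0.6, 0.9, 1.2))
high_kl_threshold <- function(control_freqs) {
  control_freqs <- as.numeric(control_freqs)
  if (length(control_freqs) < 2 || anyNA(control_freqs))
    abort("need >= 2 non-missing control values to set a threshold")
  mean(control_freqs) + 3 * sd(control_freqs)
}

#' Call a subject H (elevated) or L relative to a threshold
#'
#' Strict inequality: a frequency exactly at the threshold is `"L"`.
#'
#' @param freq Subject kappa+lambda+ percentage(s).
#' @param threshold Threshold from [high_kl_threshold()].
#' @return Character vector over `{"H", "L"}`.
#' @export
classify_patient <- function(freq, threshold) {
  ifelse(freq > threshold, "H", "L")
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. The U statistic is computed
#' from midrank sums. The p value is exact, by full enumeration of rank
#' assignments, when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used. `tails = "one"` reports the one-sided
#' p value in the direction favoured by the data.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param tails `"two"` (default) or `"one"`.
#' @return A `b2r_test` object with `statistic` (U for `x`), `p_value`,
#'   `method`, `effect` (U), `tails`, and sample sizes; see [tidy()] and
#'   [glance()].
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || anyNA(x) || anyNA(y))
    abort("both samples must be non-empty and free of missing values")
  nx <- length(x); ny <- length(y); N <- nx + ny
  combined <- c(x, y)
  r <- rank(combined)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(combined) > 0
  exact <- !has_ties && min(nx, ny) <= 8
  if (exact) {
    # enumerate every assignment of ranks 1..N to the x sample
    usims <- combn(N, nx, FUN = sum) - nx * (nx + 1) / 2
    p_le <- mean(usims <= u); p_ge <- mean(usims >= u)
    p <- if (tails == "two") min(1, 2 * min(p_le, p_ge)) else min(p_le, p_ge)
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u - mu
      z <- z - sign(z) * 0.5  # continuity correction toward the mean
      z <- z / sqrt(sigma2)
      p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
      p <- min(1, p)
    }
  }
  structure(
    list(statistic = u, p_value = p, method = "mann_whitney_u",
         effect = u, r_squared = NA_real_, tails = tails,
         n_x = nx, n_y = ny, exact = exact),
    class = c("b2r_mwu", "b2r_test")
  )
}

#' Simple linear regression
#'
#' Ordinary least-squares fit of `y` on `x` (via [stats::lm()]) for
#' scatter-plot correlations: slope, intercept, r-squared and the
#' two-sided p value for the slope from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y Paired numeric vectors, at least 3 points, `x` not constant.
#' @return A `b2r_test` object with `effect` (slope), `intercept`,
#'   `statistic` (slope t value), `r_squared` and `p_value`.
#' @export
#' @examples
#' linear_regression(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3)
    abort("need >= 3 complete paired points")
  if (var(x) == 0) abort("x is constant; slope is not identifiable")
  if (var(y) == 0) {
    # flat response: zero slope carries no evidence; lm's r-squared is
    # 0/0 here so the limits are set explicitly
    return(structure(
      list(statistic = 0, p_value = 1, method = "linear_regression",
           effect = 0, intercept = mean(y), r_squared = 0, tails = "two",
           n = length(x)),
      class = c("b2r_lm", "b2r_test")))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(statistic = unname(sm$coefficients["x", "t value"]),
         p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
         method = "linear_regression",
         effect = unname(coef(fit)[["x"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r_squared = sm$r.squared, tails = "two",
         n = length(x)),
    class = c("b2r_lm", "b2r_test")
  )
}

#' @export
print.b2r_test <- function(x, ...) {
  cat("<b2r_test>", x$method, "\n")
  if (x$method == "linear_regression") {
    cat(sprintf("  slope %.4g  intercept %.4g  r^2 %.4f  p %.4g (n = %d)\n",
                x$effect, x$intercept, x$r_squared, x$p_value, x$n))
  } else {
    cat(sprintf("  U = %g (n = %d, %d)  p %.4g [%s-tailed, %s]\n",
                x$statistic, x$n_x, x$n_y, x$p_value, x$tails,
                if (isTRUE(x$exact)) "exact" else "normal approx."))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.b2r_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, effect = x$effect,
         r_squared = x$r_squared, p_value = x$p_value, tails = x$tails)
}

#' @exportS3Method generics::glance
glance.b2r_test <- function(x, ...) tidy(x)
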