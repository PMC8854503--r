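#' Serum decoration profile
#'
#' Parameters of one serum's B-cell-reactive VH4-34 (9G4) IgM content. A
#' susceptible cell is decorated with probability
#' `min(1, titer * p_decorate_base * susceptibility[subset])`. The
#' decorating antibody carries a kappa or lambda light chain; with
#' probability `p_opposite_lc` it is the isotype opposite the cell's own
#' primary chain, in which case decoration pushes the cell into the
#' kappa/lambda double-positive gate. B-cell-binding VH4-34 antibodies are
#' not skewed for light-chain isotype, hence the 0.5 default.
#'
#' @param titer Relative VH4-34 IgM titer (healthy reference ~1; 0
#'   disables decoration).
#' @param p_decorate_base Decoration probability of a fully susceptible
#'   cell at titer 1.
#' @param p_opposite_lc Probability the decorating antibody's light chain
#'   is opposite the cell's intrinsic one.
#' @param susceptibility Named multipliers in `[0, 1]` per B-cell subset.
#'   Defaults spare anergic BND cells entirely, decorate naive, activated
#'   naive, MZ-like and double-negative cells fully, and switched memory
#'   cells partially.
#' @param id Optional serum label.
#' @return A `serum_profile` list.
#' @export
serum_profile <- function(titer = 1,
                          p_decorate_base = 0.05,
                          p_opposite_lc = 0.5,
                          susceptibility = c(naive = 1, aNAV = 1, MZlike = 1,
                                             BND = 0, DN = 1,
                                             switched_memory = 0.3),
                          id = NULL) {
  if (titer < 0) abort("titer must be non-negative")
  if (p_decorate_base < 0 || p_decorate_base > 1)
    abort("p_decorate_base must be in [0, 1]")
  if (p_opposite_lc < 0 || p_opposite_lc > 1)
    abort("p_opposite_lc must be in [0, 1]")
  if (any(susceptibility < 0 | susceptibility > 1))
    abort("susceptibility multipliers must be in [0, 1]")
  structure(list(titer = titer, p_decorate_base = p_decorate_base,
                 p_opposite_lc = p_opposite_lc,
                 susceptibility = susceptibility,
                 id = id %||% paste0("serum_titer", format(titer))),
            class = "serum_profile")
}

#' @rdname serum_profile
#' @details `healthy_serum()` is the documented healthy default (titer 0:
#'   no B-cell-reactive VH4-34 content, decoration disabled);
#'   `sleh_serum()` is the documented SLE-H default (relative titer 16,
#'   within the elevated-titer band of kappa/lambda-high patients).
#' @export
healthy_serum <- function() serum_profile(titer = 0, id = "healthy_control")

#' @rdname serum_profile
#' @export
sleh_serum <- function() serum_profile(titer = 16, id = "sle_high")

#' Flow-cytometry gate set
#'
#' Gate thresholds on log10-scale intensities plus the secondary-chain
#' detection efficiency. Surface staining under-detects genuinely
#' co-expressed secondary chains relative to sequencing (the lower-
#' expressed chain often sits below the gate); `detection_efficiency` is
#' the probability a true secondary chain stains above its gate. The
#' default 0.35 is a calibration chosen so that a true ~2% kappa/lambda
#' rate reads out at ~0.7% by flow in healthy subjects, not a measured
#' quantity.
#'
#' @param kappa_pos,lambda_pos,g4_pos Positivity thresholds (log10
#'   arbitrary units, > 0).
#' @param detection_efficiency Probability a genuinely expressed
#'   secondary chain exceeds its gate.
#' @return A `gate_set` list.
#' @export
gate_set <- function(kappa_pos = 2.0, lambda_pos = 2.0, g4_pos = 2.0,
                     detection_efficiency = 0.35) {
  if (any(c(kappa_pos, lambda_pos, g4_pos) <= 0))
    abort("gate thresholds must be positive")
  if (detection_efficiency < 0 || detection_efficiency > 1)
    abort("detection_efficiency must be in [0, 1]")
  structure(list(kappa_pos = kappa_pos, lambda_pos = lambda_pos,
                 g4_pos = g4_pos,
                 detection_efficiency = detection_efficiency),
            class = "gate_set")
}

# intensity draws (log10 AU): negative population clipped below the
# default gates, positive population strictly above them, so gate
# membership is an exact function of chain expression and decoration
# (false-positive background staining is not modelled)
intensity_negative <- function(n) pmin(pmax(0, rnorm(n, 1.0, 0.25)), 1.95)
intensity_positive <- function(n, gate) gate + 0.05 + abs(rnorm(n, 0.95, 0.40))

#' Simulate surface staining of a repertoire under a serum
#'
#' Produces one flow event per cell. Intrinsic primary chains stain
#' positive on their own channel; intrinsic secondary chains exceed the
#' gate with probability `gates$detection_efficiency`; cells intrinsically
#' expressing IGHV4-34 IgM stain on the 9G4 channel. Each cell is then
#' decorated with the serum-dependent probability; decoration lights the
#' 9G4 channel and adds the decorating antibody's light-chain isotype to
#' the corresponding kappa or lambda channel (one dominant serum clone per
#' cell), which creates apparent kappa+lambda+ events whenever that
#' isotype is opposite the cell's own.
#'
#' @param truth Ground-truth cell tibble from [generate_repertoire()].
#' @param serum A [serum_profile()].
#' @param gates A [gate_set()].
#' @param seed Optional RNG seed.
#' @param attenuation Multiplier on the decoration probability (in-vitro
#'   serum-transfer staining uses < 1; see [simulate_serum_transfer()]).
#' @return A tibble of flow events: intensities (`kappa_intensity`,
#'   `lambda_intensity`, `g4_intensity`), `subset`, and truth links
#'   (`true_lc_class`, `lc2_detected`, `decorated`, `decorating_lc`,
#'   `vh4_34`, `isotype_class`).
#' @export
stain <- function(truth, serum, gates = gate_set(), seed = NULL,
                  attenuation = 1) {
  stopifnot(inherits(serum, "serum_profile"), inherits(gates, "gate_set"))
  with_seed_if(seed, stain_impl(truth, serum, gates, attenuation))
}

stain_impl <- function(truth, serum, gates, attenuation) {
  n <- nrow(truth)
  kappa <- intensity_negative(n)
  lambda <- intensity_negative(n)
  g4 <- intensity_negative(n)

  put <- function(channel, on, gate) {
    channel[on] <- pmax(channel[on], intensity_positive(sum(on), gate))
    channel
  }

  lc1k <- truth$lc1_locus == "IGK"
  kappa <- put(kappa, lc1k, gates$kappa_pos)
  lambda <- put(lambda, !lc1k, gates$lambda_pos)

  has2 <- !is.na(truth$lc2_locus)
  lc2_detected <- has2 & runif(n) < gates$detection_efficiency
  kappa <- put(kappa, lc2_detected & truth$lc2_locus == "IGK", gates$kappa_pos)
  lambda <- put(lambda, lc2_detected & truth$lc2_locus == "IGL", gates$lambda_pos)

  g4 <- put(g4, truth$vh4_34 & truth$isotype_class == "IgMD", gates$g4_pos)

  susc <- unname(serum$susceptibility[truth$subset])
  susc[is.na(susc)] <- 0
  p_dec <- pmin(1, serum$titer * serum$p_decorate_base * susc * attenuation)
  decorated <- runif(n) < p_dec
  opposite <- runif(n) < serum$p_opposite_lc
  decorating_lc <- ifelse(
    decorated,
    ifelse(opposite, ifelse(lc1k, "IGL", "IGK"), ifelse(lc1k, "IGK", "IGL")),
    NA_character_)
  g4 <- put(g4, decorated, gates$g4_pos)
  kappa <- put(kappa, !is.na(decorating_lc) & decorating_lc == "IGK",
               gates$kappa_pos)
  lambda <- put(lambda, !is.na(decorating_lc) & decorating_lc == "IGL",
                gates$lambda_pos)

  tibble(
    barcode = truth$barcode,
    kappa_intensity = kappa, lambda_intensity = lambda, g4_intensity = g4,
    subset = truth$subset, true_lc_class = truth$true_lc_class,
    vh4_34 = truth$vh4_34, isotype_class = truth$isotype_class,
    lc2_detected = lc2_detected, decorated = decorated,
    decorating_lc = decorating_lc
  )
}

#' Apparent gate frequencies of simulated flow events
#'
#' Applies the gates and reports the percentage of events in the
#' kappa/lambda double-positive gate and the 9G4-positive gate, overall
#' or per B-cell subset. Positivity is strict (`intensity > gate`).
#'
#' @param events Event tibble from [stain()].
#' @param gates A [gate_set()].
#' @param by `"overall"` (one row) or `"subset"` (one row per subset).
#' @return A tibble with `n_events`, `kl_apparent_pct`, `g4_pct` and, with
#'   `by = "subset"`, the `subset` column. Zero events give `n_events = 0`
#'   and missing percentages.
#' @export
apparent_frequencies <- function(events, gates = gate_set(),
                                 by = c("overall", "subset")) {
  by <- match.arg(by)
  events <- as_tibble(events)
  if (nrow(events) == 0) {
    return(tibble(n_events = 0L, kl_apparent_pct = NA_real_,
                  g4_pct = NA_real_))
  }
  gated <- events %>%
    mutate(
      kl_pos = .data$kappa_intensity > gates$kappa_pos &
        .data$lambda_intensity > gates$lambda_pos,
      g4_pos = .data$g4_intensity > gates$g4_pos
    )
  if (by == "subset") gated <- gated %>% group_by(.data$subset)
  gated %>%
    summarise(n_events = dplyr::n(),
              kl_apparent_pct = 100 * mean(.data$kl_pos),
              g4_pct = 100 * mean(.data$g4_pos), .groups = "drop")
}

#' Sequencing-detected true kappa+lambda percentage of stained events
#'
#' Companion readout for [stain()] truth links: the percentage of events
#' whose cell genuinely expresses one kappa and one lambda chain, and the
#' percentage among those whose secondary chain was detected at the
#' surface (what a perfect two-colour gate would see without decoration).
#'
#' @param events Event tibble from [stain()].
#' @return One-row tibble with `true_kl_pct` and `detected_true_kl_pct`.
#' @export
true_kl_summary <- function(events) {
  tibble(
    true_kl_pct = 100 * mean(events$true_lc_class == "kappa_lambda"),
    detected_true_kl_pct = 100 * mean(events$true_lc_class == "kappa_lambda" &
                                        events$lc2_detected)
  )
}

#' Simulate a flow-cytometry cohort of controls and patients
#'
#' Generates an independent synthetic repertoire per subject, stains it
#' under a subject-specific serum titer, and assembles the per-subject
#' table that the patient-level analysis operates on: sequencing-true and
#' flow-apparent kappa+lambda percentages, 9G4-positive percentage and
#' relative VH4-34 titer. The H/L call applies [high_kl_threshold()] to
#' the control column, and the apparent kappa+lambda versus 9G4 relation
#' across patients is fit with [linear_regression()].
#'
#' Default titers: controls log-normal around the healthy reference
#' (meanlog 0, sdlog 0.4); patients a two-component mixture in which
#' `p_high` of subjects carry elevated titers (log-normal around the
#' SLE-H default, `sleh_serum()$titer`) and the rest sit near control
#' levels.
#'
#' @param n_controls,n_patients Subjects per group (`n_controls >= 2`).
#' @param config [generator_config()] used for every subject's repertoire.
#' @param gates A [gate_set()].
#' @param control_titers,patient_titers Optional explicit titer vectors;
#'   lengths must match the group sizes.
#' @param p_high Mixture weight of the elevated-titer patient component.
#' @param seed Optional RNG seed.
#' @return A `b2r_cohort` object: `subjects` tibble (`subject_id`,
#'   `group`, `titer`, `true_kl_pct`, `kl_apparent_pct`, `g4_pct`,
#'   `hl_call`), `threshold`, and `regression` (a `b2r_test`). [tidy()]
#'   returns the subject table; [glance()] the threshold and fit.
#' @export
simulate_cohort <- function(n_controls = 18, n_patients = 18,
                            config = generator_config(n_cells = 5000),
                            gates = gate_set(),
                            control_titers = NULL, patient_titers = NULL,
                            p_high = 1 / 3, seed = NULL) {
  if (n_controls < 2) abort("need at least 2 controls to set a threshold")
  with_seed_if(seed, {
    if (is.null(control_titers))
      control_titers <- rlnorm(n_controls, meanlog = 0, sdlog = 0.4)
    if (is.null(patient_titers)) {
      high <- runif(n_patients) < p_high
      patient_titers <- ifelse(
        high, rlnorm(n_patients, meanlog = log(sleh_serum()$titer), sdlog = 0.6),
        rlnorm(n_patients, meanlog = log(1.5), sdlog = 0.5))
    }
    stopifnot(length(control_titers) == n_controls,
              length(patient_titers) == n_patients)
    subjects <- tibble(
      subject_id = c(sprintf("HC-%02d", seq_len(n_controls)),
                     sprintf("SLE-%02d", seq_len(n_patients))),
      group = rep(c("control", "patient"), c(n_controls, n_patients)),
      titer = c(control_titers, patient_titers)
    )
    one_subject <- function(titer) {
      cfg <- config
      cfg$seed <- NULL  # subject draws come from the cohort RNG stream
      rep <- generate_repertoire(cfg)
      ev <- stain(rep$truth, serum_profile(titer = titer), gates)
      app <- apparent_frequencies(ev, gates)
      tk <- true_kl_summary(ev)
      tibble(true_kl_pct = tk$true_kl_pct,
             detected_true_kl_pct = tk$detected_true_kl_pct,
             kl_apparent_pct = app$kl_apparent_pct, g4_pct = app$g4_pct)
    }
    subjects <- dplyr::bind_cols(subjects,
                                 purrr::map_dfr(subjects$titer, one_subject))
    threshold <- high_kl_threshold(
      subjects$kl_apparent_pct[subjects$group == "control"])
    subjects$hl_call <- classify_patient(subjects$kl_apparent_pct, threshold)
    pat <- subjects[subjects$group == "patient", ]
    # degenerate cohorts (too few patients, constant readouts) carry no fit
    regression <- tryCatch(linear_regression(pat$g4_pct, pat$kl_apparent_pct),
                           error = function(e) NULL)
    structure(list(subjects = subjects, threshold = threshold,
                   regression = regression),
              class = "b2r_cohort")
  })
}

#' @export
print.b2r_cohort <- function(x, ...) {
  cat("<b2r_cohort>", nrow(x$subjects), "subjects; H threshold",
      sprintf("%.2f%%", x$threshold), "\n")
  if (!is.null(x$regression)) {
    cat(sprintf("  apparent kl ~ 9G4 (patients): slope %.3f, r^2 %.3f, p %.3g\n",
                x$regression$effect, x$regression$r_squared,
                x$regression$p_value))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.b2r_cohort <- function(x, ...) x$subjects

#' @exportS3Method generics::glance
glance.b2r_cohort <- function(x, ...) {
  tibble(threshold = x$threshold,
         n_H = sum(x$subjects$hl_call == "H"),
         slope = x$regression$effect %||% NA_real_,
         r_squared = x$regression$r_squared %||% NA_real_,
         p_value = x$regression$p_value %||% NA_real_)
}

#' Simulate the serum-transfer incubation experiment
#'
#' Stains one healthy repertoire repeatedly, once per serum, modelling the
#' short cold incubation of healthy B cells in patient or control sera.
#' In-vitro staining under-decorates relative to in vivo exposure
#' (shorter contact, low temperature), captured by a single attenuation
#' scalar on the decoration probability.
#'
#' @param truth Ground-truth cells of the healthy repertoire.
#' @param sera List of [serum_profile()]s (names become serum ids).
#' @param gates A [gate_set()].
#' @param attenuation Decoration-probability multiplier (default 0.5;
#'   1 reproduces full-strength [stain()] exactly).
#' @param seed Optional RNG seed.
#' @return Tibble with one row per serum: `serum_id`, `titer`,
#'   `kl_apparent_pct`, `g4_pct`, `detected_true_kl_pct`.
#' @export
simulate_serum_transfer <- function(truth, sera, gates = gate_set(),
                                    attenuation = 0.5, seed = NULL) {
  if (inherits(sera, "serum_profile")) sera <- list(sera)
  stopifnot(length(sera) >= 1)
  with_seed_if(seed, {
    purrr::imap_dfr(sera, function(serum, nm) {
      ev <- stain(truth, serum, gates, attenuation = attenuation)
      app <- apparent_frequencies(ev, gates)
      tibble(serum_id = if (is.character(nm)) nm else serum$id,
             titer = serum$titer,
             kl_apparent_pct = app$kl_apparent_pct,
             g4_pct = app$g4_pct,
             detected_true_kl_pct = true_kl_summary(ev)$detected_true_kl_pct)
    })
  })
}
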