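#' End-to-end run configuration
#'
#' Bundles the stage configurations for [run_end_to_end()]: one seed that
#' deterministically drives every stage, the repertoire generator
#' configuration, calling parameters, the sera to stain under, gates, and
#' cohort sizes.
#'
#' @param seed Integer root seed; per-stage streams are derived from it so
#'   stages can be re-run independently.
#' @param generator A [generator_config()] for the index sample.
#' @param calling A [calling_params()].
#' @param sera Named list of [serum_profile()]s.
#' @param gates A [gate_set()].
#' @param n_controls,n_patients Cohort sizes for the cohort stage.
#' @param cohort_n_cells Cells per cohort subject (smaller than the index
#'   sample to keep full runs quick).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(n_cells = 5000),
                       calling = calling_params(),
                       sera = list(healthy = healthy_serum(),
                                   sle_high = sleh_serum()),
                       gates = gate_set(),
                       n_controls = 6L, n_patients = 6L,
                       cohort_n_cells = 2000L) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(calling, "calling_params"),
            inherits(gates, "gate_set"),
            all(vapply(sera, inherits, TRUE, "serum_profile")))
  structure(list(seed = as.integer(seed), generator = generator,
                 calling = calling, sera = sera, gates = gates,
                 n_controls = as.integer(n_controls),
                 n_patients = as.integer(n_patients),
                 cohort_n_cells = as.integer(cohort_n_cells)),
            class = "run_config")
}

#' Run the full pipeline and write all outputs
#'
#' Composes the stages into one reproducible run: simulate an index
#' repertoire, write its contigs (10x dialect), assemble and classify
#' clonotypes, summarise the repertoire, stain the index cells under each
#' configured serum, simulate a control/patient cohort, and write a
#' manifest with an MD5 content hash per output file. Identical
#' configuration (including seed) gives byte-identical outputs. Stage
#' progress is logged to standard error via [message()].
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble (`file`, `md5`, `bytes`), invisibly; also
#'   written to `manifest.json` in `out_dir`.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = tempfile("b2r_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  message("stage simulate: ", config$generator$n_cells, " cells")
  gen_cfg <- config$generator
  gen_cfg$seed <- seed
  rep <- generate_repertoire(gen_cfg)
  write_contigs(rep$contigs, emit("contigs.csv"), dialect = "10x")
  readr::write_csv(rep$truth, emit("truth.csv"), na = "")

  message("stage clonotype: ", nrow(rep$contigs), " contigs")
  cells <- assemble_cells(rep$contigs, config$calling)
  write_clonotype_table(cells, emit("clonotypes.csv"))

  message("stage summarize: ", sum(cells$analyzable), " analyzable cells")
  summ <- summarize_repertoire(cells, sample_id = "index")
  jsonlite::write_json(
    list(glance = glance(summ), vh_usage = summ$vh_usage,
         jk_usage = summ$jk_usage,
         lc_class_fractions = summ$lc_class_fractions),
    emit("summary.json"), auto_unbox = TRUE, digits = NA)

  message("stage decorate: ", length(config$sera), " sera")
  transfer <- simulate_serum_transfer(rep$truth, config$sera, config$gates,
                                      attenuation = 1, seed = seed + 1L)
  readr::write_csv(transfer, emit("apparent_frequencies.csv"), na = "")

  message("stage cohort: ", config$n_controls, " controls, ",
          config$n_patients, " patients")
  cohort_cfg <- config$generator
  cohort_cfg$n_cells <- config$cohort_n_cells
  cohort_cfg$seed <- NULL
  cohort <- simulate_cohort(config$n_controls, config$n_patients,
                            cohort_cfg, config$gates, seed = seed + 2L)
  readr::write_csv(tidy(cohort), emit("cohort.csv"), na = "")
  jsonlite::write_json(glance(cohort), emit("cohort_fit.json"),
                       auto_unbox = TRUE, digits = NA)

  config_json <- emit("config.json")
  jsonlite::write_json(serialize_run_config(config), config_json,
                       auto_unbox = TRUE, digits = NA)

  manifest <- tibble(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    bytes = file.size(unlist(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  message("run complete: ", nrow(manifest), " output files in ", out_dir)
  invisible(manifest)
}

# plain-list view of the config for JSON round-tripping alongside outputs
serialize_run_config <- function(config) {
  list(
    seed = config$seed,
    generator = unclass(config$generator),
    calling = unclass(config$calling),
    sera = lapply(config$sera, function(s) {
      s <- unclass(s)
      s$susceptibility <- as.list(s$susceptibility)
      s
    }),
    gates = unclass(config$gates),
    n_controls = config$n_controls,
    n_patients = config$n_patients,
    cohort_n_cells = config$cohort_n_cells
  )
}
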