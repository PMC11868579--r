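#' Run a configured analysis pipeline
#'
#' Executes the task blocks of a YAML (or list) configuration in order and
#' writes per-task CSV/JSON outputs plus a run manifest. The configuration
#' is validated up front — schema version, unknown keys, parameter ranges
#' and referenced input paths — before any task runs; any task failure
#' stops the run with a `FAILED` marker retained next to the partial
#' outputs. Re-running an unchanged configuration on unchanged inputs
#' reproduces byte-identical CSV/JSON payloads (timestamps live only in
#' the manifest).
#'
#' Supported task types: `le` (ligand-efficiency table from
#' compound/Kd/heavy-atom triples), `screen` (CPMG hit calling from a
#' records CSV), `itc_fit` (one-set-of-sites fit of a thermogram CSV),
#' `itc_sim` (simulate a thermogram), `site` / `contacts` (site definition
#' or contact shell from a PDB file), `conserve` (conservation profile
#' from an aligned FASTA), `synth_family`, `synth_deck`,
#' `synth_structure` (synthetic-data generators).
#'
#' @param config Path to a YAML configuration, or an equivalent named list.
#'   Top-level keys: `schema_version` (must be 1), `output_dir`, optional
#'   `seed`, and `tasks` (a list of named task blocks).
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop(sprintf("config file '%s' does not exist", config), call. = FALSE)
    }
    config_path <- config
    config <- yaml::read_yaml(config)
  } else {
    config_path <- NULL
  }
  known_top <- c("schema_version", "output_dir", "seed", "log_level", "tasks")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(config$schema_version), 1L)) {
    stop("config schema_version must be 1", call. = FALSE)
  }
  if (is.null(output_dir)) output_dir <- config$output_dir
  if (is.null(output_dir)) stop("output_dir is required", call. = FALSE)
  tasks <- config$tasks
  if (is.null(tasks) || length(tasks) == 0L) {
    stop("config has no tasks", call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  for (nm in names(tasks)) validate_task(nm, tasks[[nm]])

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "fragsite",
    version = as.character(utils::packageVersion("fragsite")),
    config_hash = config_hash(config),
    seed = seed,
    started = format(Sys.time(), tz = "UTC"),
    tasks = list()
  )
  for (nm in names(tasks)) {
    res <- tryCatch(
      run_task(nm, tasks[[nm]], output_dir, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      writeLines(sprintf("task '%s': %s", nm, conditionMessage(res)),
                 file.path(output_dir, "FAILED"))
      stop(sprintf("pipeline task '%s' failed: %s", nm,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$tasks[[nm]] <- res
  }
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

task_schemas <- list(
  le = list(required = "table", optional = "temperature"),
  screen = list(required = "input", optional = c("tau", "recovery_delta")),
  itc_fit = list(required = c("input", "cell_conc", "syringe_conc"),
                 optional = c("cell_volume", "temperature", "fit_dilution",
                              "discard_first")),
  itc_sim = list(required = c("cell_conc", "syringe_conc", "n_injections",
                              "injection_volume", "n", "Kd", "dH"),
                 optional = c("cell_volume", "temperature", "noise_sd",
                              "q_dil", "seed")),
  site = list(required = c("input", "ligand_chain", "ligand_resname",
                           "ligand_resno"),
              optional = c("k", "chain")),
  contacts = list(required = c("input", "ligand_chain", "ligand_resname",
                               "ligand_resno"),
                  optional = c("cutoff", "chain")),
  conserve = list(required = c("input", "reference_id"),
                  optional = c("sites", "gap_rule")),
  synth_family = list(required = character(0),
                      optional = c("length", "n_orthologs", "p_global",
                                   "p_site", "indel_prob", "seed")),
  synth_deck = list(required = character(0),
                    optional = c("n_library", "n_binders", "tau", "margin",
                                 "frac_site1", "seed")),
  synth_structure = list(required = character(0),
                         optional = c("n_residues", "geometry", "seed"))
)

validate_task <- function(name, block) {
  # a task's type is its block name, or an explicit `type` key when several
  # blocks of one type need distinct names
  type <- if (name %in% names(task_schemas)) name else block$type
  if (is.null(type) || !type %in% names(task_schemas)) {
    stop(sprintf("task '%s': unknown or missing task type", name),
         call. = FALSE)
  }
  schema <- task_schemas[[type]]
  keys <- setdiff(names(block), "type")
  unknown <- setdiff(keys, c(schema$required, schema$optional))
  if (length(unknown)) {
    stop(sprintf("task '%s': unknown key(s): %s", name,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(schema$required, keys)
  if (length(missing)) {
    stop(sprintf("task '%s': missing required key(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if ("input" %in% keys && !file.exists(block$input)) {
    stop(sprintf("task '%s': input path '%s' does not exist", name,
                 block$input), call. = FALSE)
  }
  invisible(type)
}

run_task <- function(name, block, output_dir, seed) {
  type <- validate_task(name, block)
  dir <- file.path(output_dir, name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(type,
    le = {
      tab <- do.call(rbind, lapply(block$table, function(r) {
        le_table(r$compound, r$kd_molar, r$n_heavy,
                 T = block$temperature %||% 298.15)
      }))
      utils::write.csv(tab, file.path(dir, "ligand_efficiency.csv"),
                       row.names = FALSE)
      list(n_compounds = nrow(tab))
    },
    screen = {
      hits <- call_hits(read_screen_csv(block$input),
                        tau = block$tau %||% 0.8,
                        recovery_delta = block$recovery_delta %||% 0.15)
      write_hit_calls(hits, csv = file.path(dir, "hit_calls.csv"),
                      json = file.path(dir, "summary.json"))
      hits$summary
    },
    itc_fit = {
      tg <- read_thermogram_csv(block$input,
                                cell_volume = block$cell_volume %||% 1.4e-3,
                                cell_conc = block$cell_conc,
                                syringe_conc = block$syringe_conc,
                                temperature = block$temperature %||% 298.15)
      fit <- fit_one_set_of_sites(tg,
                                  fit_dilution = block$fit_dilution %||% TRUE,
                                  discard_first = block$discard_first %||% FALSE)
      res <- list(converged = fit$converged, n = fit$params$n,
                  Kd_molar = fit$params$Kd, dH_kcal_mol = fit$params$dH,
                  dG_kcal_mol = fit$dG, minus_TdS_kcal_mol = fit$minus_TdS,
                  c_value = fit$c_value)
      jsonlite::write_json(res, file.path(dir, "fit.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    },
    itc_sim = {
      protocol <- titration_protocol(
        cell_volume = block$cell_volume %||% 1.4e-3,
        cell_conc = block$cell_conc, syringe_conc = block$syringe_conc,
        injection_volumes = rep(block$injection_volume, block$n_injections),
        temperature = block$temperature %||% 298.15)
      tg <- simulate_titration(protocol,
                               binding_params(block$n, block$Kd, block$dH),
                               noise_sd = block$noise_sd %||% 0,
                               q_dil = block$q_dil %||% 0,
                               seed = block$seed %||% seed)
      write_thermogram_csv(tg, file.path(dir, "thermogram.csv"))
      list(n_injections = length(tg$heats))
    },
    site = {
      model <- read_structure(block$input)
      lig <- ligand_selection(block$ligand_chain, block$ligand_resname,
                              block$ligand_resno)
      site <- define_site_by_proximity(model, lig, k = block$k %||% 20,
                                       chain = block$chain)
      write_site(site, csv = file.path(dir, "site.csv"),
                 json = file.path(dir, "site.json"))
      list(n_residues = nrow(site$residues), chain = site$chain)
    },
    contacts = {
      model <- read_structure(block$input)
      lig <- ligand_selection(block$ligand_chain, block$ligand_resname,
                              block$ligand_resno)
      tab <- contact_residues(model, lig, cutoff = block$cutoff %||% 4.0,
                              chain = block$chain)
      write_site(tab, csv = file.path(dir, "contacts.csv"),
                 json = file.path(dir, "contacts.json"))
      list(n_residues = nrow(tab))
    },
    conserve = {
      aln <- read_alignment(block$input, reference_id = block$reference_id)
      sites <- lapply(block$sites %||% list(), function(s) {
        site_definition(s$name, unlist(s$positions), offset = s$offset %||% 0)
      })
      prof <- conservation_profile(aln, sites,
                                   gap_rule = block$gap_rule %||% "reference")
      utils::write.csv(prof, file.path(dir, "conservation.csv"),
                       row.names = FALSE)
      list(n_orthologs = nrow(prof))
    },
    synth_family = {
      fam <- generate_ortholog_family(
        length = block$length %||% 217,
        n_orthologs = block$n_orthologs %||% 30,
        p_global = block$p_global %||% 0.12,
        p_site = block$p_site %||% 0.02,
        indel_prob = block$indel_prob %||% 0,
        seed = block$seed %||% seed)
      writeLines(fam$fasta, file.path(dir, "family_aligned.fasta"))
      jsonlite::write_json(fam$truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      list(n_orthologs = length(fam$alignment$ids) - 1L)
    },
    synth_deck = {
      deck <- generate_screen_deck(
        n_library = block$n_library %||% 1371,
        n_binders = block$n_binders %||% 50,
        tau = block$tau %||% 0.8, margin = block$margin %||% 0.05,
        frac_site1 = block$frac_site1 %||% 0.2,
        seed = block$seed %||% seed)
      utils::write.csv(deck$records, file.path(dir, "deck.csv"),
                       row.names = FALSE)
      utils::write.csv(deck$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
      list(n_library = nrow(deck$records))
    },
    synth_structure = {
      toy <- generate_toy_structure(
        n_residues = block$n_residues %||% 12,
        geometry = block$geometry %||% "line",
        seed = block$seed %||% seed)
      writeLines(toy$pdb, file.path(dir, "structure.pdb"))
      utils::write.csv(toy$truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
      list(n_residues = nrow(toy$truth))
    }
  )
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
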