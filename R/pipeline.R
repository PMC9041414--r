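#' Read a pipeline run configuration
#'
#' @param path YAML file describing a run: global keys `output_dir` and
#'   `seed`, plus one section per requested stage (`simulate_clades`,
#'   `pid`, `place`, `ani`, `modules`, `skew`, `matrix`), each holding that
#'   stage's inputs and parameters.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  yaml::read_yaml(path)
}

# Collect (stage, key, path) triples for every *_path-like input and check
# existence before any stage runs.
validate_config_paths <- function(config) {
  path_keys <- c("alignment", "groups", "genome", "genome_a", "genome_b",
                 "modules", "annotations", "rescue_rules", "panel",
                 "coverage")
  problems <- character(0)
  for (stage in setdiff(names(config), c("output_dir", "seed"))) {
    sec <- config[[stage]]
    if (!is.list(sec)) next
    for (key in intersect(names(sec), path_keys)) {
      p <- sec[[key]]
      if (is.character(p) && length(p) == 1L && !file.exists(p)) {
        problems <- c(problems, paste0(stage, "$", key, ": '", p, "'"))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("missing input path(s):\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the comparative-genomics pipeline from a configuration
#'
#' Wires the package's stages into one seeded, reproducible run: simulation
#' of a clade alignment, PID matrix, rank placement, ANI, module
#' completeness, GC-skew origin prediction and gene presence matrix — each
#' stage present in the configuration runs, writes its outputs under
#' `output_dir`, and contributes a summary to `report.json`. All input
#' paths are validated before any stage runs.
#'
#' @param config A configuration list or a YAML path (see
#'   [read_run_config()]). Must contain `output_dir`; `seed` (default 1)
#'   drives every stochastic stage.
#' @return The report as a named list (also written to
#'   `<output_dir>/report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config), !is.null(config$output_dir))
  validate_config_paths(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  report <- list(schema_version = "1.0",
                 package_version = as.character(utils::packageVersion("gaoscope")),
                 seed = seed, config_hash = rlang::hash(config),
                 stages = list())
  sim <- NULL

  if (!is.null(config$simulate_clades)) {
    args <- config$simulate_clades
    args$seed <- args$seed %||% seed
    sim <- do.call(simulate_clade_alignment, args)
    write_fasta(sim$alignment, file.path(out_dir, "simulated_alignment.afa"))
    readr::write_tsv(sim$groups, file.path(out_dir, "simulated_groups.tsv"),
                     progress = FALSE)
    jsonlite::write_json(sim$truth, file.path(out_dir, "simulated_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$simulate_clades <- sim$truth
  }

  pid <- NULL
  groups <- NULL
  if (!is.null(config$pid) || !is.null(sim)) {
    sec <- config$pid %||% list()
    aln <- if (!is.null(sec$alignment)) read_alignment(sec$alignment)
    else if (!is.null(sim)) sim$alignment
    else NULL
    if (!is.null(aln)) {
      groups <- if (!is.null(sec$groups)) {
        readr::read_tsv(sec$groups, col_types = "cc", progress = FALSE)
      } else if (!is.null(sim)) sim$groups else NULL
      pid <- pid_matrix(aln,
                        count_single_gaps = sec$count_single_gaps %||% TRUE)
      write_pid_matrix(pid, file.path(out_dir, "pid_matrix.tsv"))
      report$stages$pid <- list(n_sequences = length(pid$ids),
                                n_pairs = choose(length(pid$ids), 2L),
                                output = "pid_matrix.tsv")
    }
  }

  if (!is.null(config$place)) {
    sec <- config$place
    if (is.null(pid) || is.null(groups)) {
      stop("place stage needs a pid stage (alignment + groups)", call. = FALSE)
    }
    thr <- if (!is.null(sec$thresholds)) {
      do.call(rank_thresholds, sec$thresholds)
    } else rank_thresholds()
    call <- place_group(pid, groups, sec$query, sec$reference, thr)
    res <- as.list(glance(call))
    jsonlite::write_json(res, file.path(out_dir, "placement.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$place <- res
  }

  if (!is.null(config$ani)) {
    sec <- config$ani
    res <- compute_ani(sec$genome_a, sec$genome_b,
                       fragment_length = sec$fragment_length %||% 1020L)
    g <- as.list(glance(res))
    g$species_call <- classify_species_boundary(res, sec$cutoff %||% 95)
    jsonlite::write_json(g, file.path(out_dir, "ani.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$ani <- g
  }

  if (!is.null(config$modules)) {
    sec <- config$modules
    mods <- read_module_table(sec$modules)
    ann <- read_annotation_table(sec$annotations)
    rules <- if (!is.null(sec$rescue_rules)) {
      readr::read_tsv(sec$rescue_rules, col_types = "ccc", progress = FALSE)
    } else NULL
    calls <- completeness_matrix(mods, ann, rescue_rules = rules)
    readr::write_tsv(calls, file.path(out_dir, "completeness_calls.tsv"),
                     progress = FALSE)
    render_completeness(calls, file.path(out_dir, "completeness_matrix.tsv"))
    report$stages$modules <- list(
      n_modules = length(unique(calls$module_id)),
      n_genomes = length(unique(calls$genome_id)),
      status_counts = as.list(table(calls$status)),
      output = "completeness_matrix.tsv")
  }

  if (!is.null(config$skew)) {
    sec <- config$skew
    profile <- windowed_gc_skew(sec$genome, window = sec$window %||% 5000L)
    pred <- predict_ori_ter(profile)
    readr::write_tsv(tibble::as_tibble(profile),
                     file.path(out_dir, "skew_profile.tsv"), progress = FALSE)
    g <- as.list(glance(pred))
    if (!is.null(sec$annotations)) {
      ann <- read_annotation_table(sec$annotations)
      g$dnaa_distance <- dnaa_proximity(pred, ann)
    }
    jsonlite::write_json(g, file.path(out_dir, "ori_ter.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$skew <- g
  }

  if (!is.null(config$matrix)) {
    sec <- config$matrix
    panel <- readr::read_tsv(sec$panel, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
    ann <- read_annotation_table(sec$annotations)
    pm <- build_presence_matrix(ann, panel,
                                match_mode = sec$match_mode %||%
                                  "symbol_suffix")
    render_presence_matrix(pm, file.path(out_dir, "presence_matrix.tsv"))
    report$stages$matrix <- list(
      n_genes = length(unique(pm$gene_symbol)),
      n_genomes = length(attr(pm, "genomes")),
      n_present = sum(pm$present), output = "presence_matrix.tsv")
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
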