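#' Configuration for a full strain-design run
#'
#' @param model_path SBML (`.xml`/`.xml.gz`) or JSON model file.
#' @param pathway `"builtin:papBAC"`, or a pathway YAML path.
#' @param medium `NULL` (keep the model's bounds), a medium YAML path, or
#'   a shipped preset name such as `"m9_aerobic_glucose"`.
#' @param flux_data_path optional TSV of measured wild-type fluxes.
#' @param thresholds a [design_thresholds()].
#' @param wt_growth_fraction growth floor fraction for the wild-type FVA
#'   (`NULL` for none).
#' @param exclude_pathway_upregulation exclude grafted reactions from the
#'   candidate list (push interventions into native metabolism).
#' @param essentiality_filter drop knockouts of reactions with essential
#'   genes (runs a single-gene deletion scan).
#' @param k_max largest FORCE subset size.
#' @param substrate_exchange_id substrate exchange for yield reporting.
#' @param out_dir output directory (created if missing).
#' @param solver backend name or `NULL` for auto.
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(model_path, pathway = "builtin:papBAC", medium = NULL,
                       flux_data_path = NULL,
                       thresholds = design_thresholds(),
                       wt_growth_fraction = 0.9,
                       exclude_pathway_upregulation = TRUE,
                       essentiality_filter = FALSE, k_max = 4L,
                       substrate_exchange_id = "EX_glc__D_e",
                       out_dir = "fluxforce_out", solver = NULL, seed = 1L) {
  if (!is.character(model_path) || !file.exists(model_path)) {
    stop("configuration error: model_path does not exist: ", model_path)
  }
  if (!is.null(flux_data_path) && !file.exists(flux_data_path)) {
    stop("configuration error: flux_data_path does not exist: ", flux_data_path)
  }
  stopifnot(inherits(thresholds, "design_thresholds"), k_max >= 1L)
  structure(list(model_path = model_path, pathway = pathway, medium = medium,
                 flux_data_path = flux_data_path, thresholds = thresholds,
                 wt_growth_fraction = wt_growth_fraction,
                 exclude_pathway_upregulation = exclude_pathway_upregulation,
                 essentiality_filter = essentiality_filter,
                 k_max = as.integer(k_max),
                 substrate_exchange_id = substrate_exchange_id,
                 out_dir = out_dir, solver = solver, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full strain-design pipeline
#'
#' Stages: load model -> graft pathway -> apply medium -> production
#' envelope -> wild-type and overproducer flux ranges -> MUST
#' classification -> candidate interventions -> FORCE search -> gene
#' mapping -> combination scan. Writes TSV/JSON artifacts plus a YAML run
#' manifest into `config$out_dir`; identical configurations produce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return the result list, invisibly (also serialized to disk).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[fluxforce] ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  host <- stage("load model", {
    if (grepl("\\.json$", config$model_path)) read_json_model(config$model_path)
    else read_sbml(config$model_path)
  })
  pathway <- stage("pathway", {
    if (identical(config$pathway, "builtin:papBAC")) builtin_papbac_pathway()
    else read_pathway_yaml(config$pathway)
  })
  model <- stage("graft", {
    m <- graft_pathway(host, pathway)
    if (!is.null(config$medium)) m <- apply_medium(m, read_medium(config$medium))
    precompute_lp(m)
  })
  solver <- config$solver

  envelope <- stage("production envelope", {
    env <- production_envelope(model, solver = solver)
    write_envelope_tsv(env, file.path(config$out_dir, "envelope.tsv"))
    env
  })
  yield <- stage("theoretical yield", {
    if (config$substrate_exchange_id %in% reaction_ids(model)) {
      theoretical_max_yield(model, product_exchange(model),
                            config$substrate_exchange_id, solver = solver)
    } else NULL
  })
  wt_ranges <- stage("wild-type ranges", {
    fd <- if (!is.null(config$flux_data_path)) read_flux_data(config$flux_data_path)
    wr <- wildtype_ranges(close_pathway(model), fd,
                          growth_fraction = config$wt_growth_fraction,
                          solver = solver)
    write_fva_tsv(wr, file.path(config$out_dir, "wt_ranges.tsv"))
    wr
  })
  ov_ranges <- stage("overproducer ranges", {
    ovr <- overproducer_ranges(model, config$thresholds, solver = solver)
    write_fva_tsv(ovr, file.path(config$out_dir, "ov_ranges.tsv"))
    ovr
  })
  must <- stage("MUST classification", {
    ms <- classify_must_sets(wt_ranges, ov_ranges, config$thresholds$epsilon)
    write_must_tsv(ms, file.path(config$out_dir, "must_sets.tsv"))
    ms
  })
  candidates <- stage("candidate interventions", {
    ess <- if (config$essentiality_filter) {
      single_gene_deletions(model, solver = solver)
    } else NULL
    excl <- if (config$exclude_pathway_upregulation) {
      pathway_reactions(model)
    } else character()
    cand <- candidate_interventions(must, model, essential = ess,
                                    exclude_reactions = excl)
    utils::write.table(cand, file.path(config$out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cand
  })
  force <- stage("FORCE search", {
    fr <- find_force_sets(model, candidates, k_max = config$k_max,
                          thresholds = config$thresholds, solver = solver)
    write_force_tsv(fr, file.path(config$out_dir, "force_sets.tsv"))
    fr
  })
  genes <- stage("gene mapping", {
    gi <- lapply(seq_len(nrow(candidates)), function(i) {
      alts <- reaction_to_gene_interventions(model, candidates[i, ])
      data.frame(reaction_id = candidates$reaction_id[i],
                 kind = candidates$kind[i],
                 alternative = seq_along(alts),
                 genes = vapply(alts, function(a) paste(a$genes, collapse = ","),
                                character(1)),
                 n_genes = vapply(alts, function(a) length(a$genes), integer(1)),
                 stringsAsFactors = FALSE)
    })
    gi <- if (length(gi) > 0) do.call(rbind, gi) else
      data.frame(reaction_id = character(), kind = character(),
                 alternative = integer(), genes = character(),
                 n_genes = integer())
    utils::write.table(gi, file.path(config$out_dir, "gene_interventions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gi
  })
  scan <- stage("combination scan", {
    sc <- combination_scan(model, candidates, max_size = config$k_max,
                           thresholds = config$thresholds, solver = solver)
    utils::write.table(sc, file.path(config$out_dir, "combination_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc
  })

  summary <- list(
    model = model$id,
    n_reactions = length(model$reactions),
    theoretical_max_yield = if (!is.null(yield)) yield$yield else NA,
    n_must_u = nrow(must$must_u), n_must_l = nrow(must$must_l),
    n_must_x = length(must$must_x),
    n_candidates = nrow(candidates),
    minimal_force_sets = force$members[force$minimal],
    best_worst_case_min_product =
      if (any(force$minimal)) max(force$worst_case_min_product[force$minimal]) else 0,
    best_percent_of_max =
      if (any(force$minimal)) max(force$percent_of_max[force$minimal]) else 0)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    package = "fluxforce",
    version = tryCatch(as.character(utils::packageVersion("fluxforce")),
                       error = function(e) "source"),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    solver = resolve_solver(config$solver, length(model$reactions)),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    config = lapply(config[c("model_path", "pathway", "medium",
                             "flux_data_path", "wt_growth_fraction",
                             "exclude_pathway_upregulation",
                             "essentiality_filter", "k_max")],
                    function(x) if (is.null(x)) NA else x),
    wall_time_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(model = model, envelope = envelope, yield = yield,
                 wt_ranges = wt_ranges, ov_ranges = ov_ranges, must = must,
                 candidates = candidates, force = force, genes = genes,
                 scan = scan, summary = summary, manifest = manifest))
}
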