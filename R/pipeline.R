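#' Run the full rearrangement-discovery pipeline
#'
#' Stages, in order: read (optional) -> insert-model estimation ->
#' pair classification -> greedy clustering -> somatic filter cascade
#' (controls, excluded-region proximity, known variants, read support,
#' matched normal) -> anchor-correlation screening -> gene annotation and
#' validation selection. Control and matched-normal call sets are produced
#' by the same classify/cluster path. Any stage error is re-raised with
#' the stage name; partially written outputs are removed.
#'
#' @param records `mate_pairs` table (one or more tumor samples) or a path
#'   to a mate-pair TSV.
#' @param genome A [genome_model()].
#' @param model Optional [insert_size_model()]; estimated from `records`
#'   when `NULL`.
#' @param genes Optional [gene_models()] for annotation.
#' @param known_variants Optional [region_set()] of known variants.
#' @param control_records List of `mate_pairs` tables from healthy
#'   controls.
#' @param matched_normal_records Optional `mate_pairs` from the matched
#'   normal.
#' @param cluster_window Passed to [cluster_events()].
#' @param min_support,proximity_multiple Passed to [filter_config()].
#' @param alpha,min_pairs Passed to [screen_translocations()].
#' @param deep_samples,deep_min_support,require_recurrent Passed to
#'   [select_candidates()].
#' @param out_dir Optional output directory; when given, writes
#'   `calls.bedpe`, `sv_table.tsv`, `filter_report.tsv`,
#'   `circos_links.txt` (somatic pass translocations) and `run_log.txt`.
#' @return list of class `matesv_pipeline`: `model`, `classified`, `calls`
#'   (all clustered calls with flags/verdicts/annotation), `pass_calls`,
#'   `report`, `control_calls`, `normal_calls`, `outputs` (paths or NULL).
#' @export
run_pipeline <- function(records, genome, model = NULL, genes = NULL,
                         known_variants = NULL, control_records = list(),
                         matched_normal_records = NULL,
                         cluster_window = NULL, min_support = 4,
                         proximity_multiple = 2, alpha = 0.05,
                         min_pairs = 4, deep_samples = character(),
                         deep_min_support = 40, require_recurrent = FALSE,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_msg("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  records <- stage("read", {
    if (is.character(records)) read_mate_pairs(records, genome = genome)
    else records
  })
  model <- stage("insert_model", model %||% estimate_insert_model(records))
  classified <- stage("classify", classify_pairs(records, model))
  calls <- stage("cluster", cluster_events(classified, model,
                                           cluster_window = cluster_window))
  call_set <- function(recs) {
    cluster_events(classify_pairs(recs, model), model,
                   cluster_window = cluster_window)
  }
  control_calls <- stage("controls", lapply(control_records, call_set))
  normal_calls <- stage("matched_normal", {
    if (is.null(matched_normal_records)) NULL
    else call_set(matched_normal_records)
  })
  filtered <- stage("filter", apply_filters(calls, genome, model,
    filter_config(proximity_multiple = proximity_multiple,
                  min_support = min_support, control_calls = control_calls,
                  known_variants = known_variants,
                  matched_normal = normal_calls)))
  screened <- stage("correlate",
    screen_translocations(filtered$calls, classified, alpha = alpha,
                          min_pairs = min_pairs))
  annotated <- stage("annotate", {
    if (is.null(genes)) screened
    else select_candidates(annotate_genes(screened, genes, model), model,
                           min_support = min_support,
                           deep_samples = deep_samples,
                           deep_min_support = deep_min_support,
                           require_recurrent = require_recurrent)
  })
  # correlation-based exclusion targets interchromosomal artifacts;
  # insertion calls keep their verdict as annotation only
  pass <- annotated[annotated$pass &
                    !(annotated$type == "translocation" &
                      !is.na(annotated$verdict) &
                      annotated$verdict == "fail"), , drop = FALSE]

  outputs <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    outputs <- file.path(out_dir, c(calls = "calls.bedpe",
                                    sv_table = "sv_table.tsv",
                                    filter_report = "filter_report.tsv",
                                    circos = "circos_links.txt",
                                    log = "run_log.txt"))
    names(outputs) <- c("calls", "sv_table", "filter_report", "circos",
                        "log")
    ok <- FALSE
    on.exit(if (!ok) unlink(outputs), add = TRUE)
    stage("write", {
      write_bedpe(annotated, outputs[["calls"]])
      write_sv_table(annotated, outputs[["sv_table"]])
      write_filter_report(filtered, outputs[["filter_report"]])
      write_circos_links(pass, outputs[["circos"]])
      writeLines(c(
        sprintf("matesv run %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        sprintf("insert model: median %g sigma %g window [%g, %g]",
                model$median, model$sigma, model$lo, model$hi),
        sprintf("pairs: %d (discordant %d)", nrow(classified),
                sum(classified$category != "concordant")),
        sprintf("calls: %d clustered, %d pass filters, %d in final set",
                nrow(annotated), sum(annotated$pass), nrow(pass)),
        sprintf("config: min_support=%d proximity_multiple=%g alpha=%g min_pairs=%d",
                min_support, proximity_multiple, alpha, min_pairs)),
        outputs[["log"]])
      ok <- TRUE
    })
  }
  structure(list(model = model, classified = classified, calls = annotated,
                 pass_calls = pass, report = filtered$report,
                 control_calls = control_calls, normal_calls = normal_calls,
                 outputs = outputs), class = "matesv_pipeline")
}

#' Summarise a pipeline run (and optionally a validation table)
#'
#' Per-sample discordant-pair fractions and call counts by type, plus --
#' when a validation summary table is supplied -- the cohort aggregates
#' from [summarize_validation()].
#'
#' @param result A `matesv_pipeline` object from [run_pipeline()].
#' @param validation Optional validation-count table
#'   ([read_validation_summary()] schema).
#' @return list of class `matesv_summary`: `n_pairs`,
#'   `discordant_fraction`, `pairs_by_category`, `calls_by_type`
#'   (pass set), `n_calls`, `n_pass`, and `validation`
#'   (a [summarize_validation()] result or NULL).
#' @export
report_summary <- function(result, validation = NULL) {
  stopifnot(inherits(result, "matesv_pipeline"))
  cl <- result$classified
  calls <- result$calls
  structure(list(
    n_pairs = nrow(cl),
    discordant_fraction = if (nrow(cl)) mean(cl$category != "concordant")
                          else NA_real_,
    pairs_by_category = table(cl$category),
    calls_by_type = table(result$pass_calls$type),
    n_calls = nrow(calls),
    n_pass = nrow(result$pass_calls),
    validation = if (is.null(validation)) NULL
                 else summarize_validation(validation)),
    class = "matesv_summary")
}

#' @export
print.matesv_summary <- function(x, ...) {
  cat(sprintf("%d mate pairs, %.2f%% discordant\n", x$n_pairs,
              100 * x$discordant_fraction))
  cat(sprintf("%d calls clustered, %d pass filters\n", x$n_calls, x$n_pass))
  if (length(x$calls_by_type)) {
    cat("pass calls by type:\n")
    print(x$calls_by_type)
  }
  if (!is.null(x$validation)) {
    cat(sprintf("validation: attempted %d / validated %d / somatic %d\n",
                x$validation$attempted, x$validation$validated,
                x$validation$somatic))
  }
  invisible(x)
}
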