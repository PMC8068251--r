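#' Validate a pipeline configuration
#'
#' Schema and cross-field checks for a configuration document (JSON or YAML
#' via [jsonlite::read_json()] / list). An empty return value means the
#' configuration is runnable.
#'
#' @param config A configuration list or a path to a JSON document.
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(
      jsonlite::read_json(config, simplifyVector = TRUE),
      error = function(e) stop("cannot parse config: ", conditionMessage(e),
                               call. = FALSE))
  }
  problems <- character()
  need_path <- function(field) {
    p <- config$paths[[field]]
    if (!is.null(p) && !file.exists(p) && !dir.exists(p))
      problems <<- c(problems,
                     paste0("paths$", field, " does not exist: ", p))
  }
  has_expr <- !is.null(config$paths$matrix)
  has_map <- !is.null(config$paths$cellmap)
  has_heatmap <- !is.null(config$paths$heatmap)
  if (!has_expr && !has_map && !has_heatmap)
    problems <- c(problems,
                  "config provides no inputs (paths$matrix, paths$cellmap or paths$heatmap)")
  for (f in c("matrix", "cellmap", "heatmap", "areas")) need_path(f)
  if (!is.null(config$ruleset)) {
    rs <- tryCatch(load_ruleset(config$ruleset), error = function(e) NULL)
    if (is.null(rs)) {
      problems <- c(problems, paste0("ruleset not resolvable: ", config$ruleset))
    } else {
      for (st in names(rs$states)) {
        kf <- rs$states[[st]]$kofn
        if (!is.null(kf) && (kf$k < 1 || kf$k > length(kf$genes)))
          problems <- c(problems,
                        sprintf("state '%s': k-of-n k=%d outside 1..%d",
                                st, kf$k, length(kf$genes)))
      }
    }
  }
  if (!is.null(config$qc)) {
    ok <- tryCatch({ do.call(qc_thresholds, config$qc); TRUE },
                   error = function(e) { problems <<- c(problems,
                     paste0("qc thresholds invalid: ", conditionMessage(e)))
                     FALSE })
  }
  if (!is.null(config$proximity)) {
    tryCatch(do.call(proximity_config, config$proximity),
             error = function(e) problems <<- c(problems,
               paste0("proximity config invalid: ", conditionMessage(e))))
  }
  if (!is.null(config$k_override) && !is.null(config$ruleset)) {
    rs <- tryCatch(load_ruleset(config$ruleset), error = function(e) NULL)
    if (!is.null(rs)) {
      kf <- rs$states$exhausted$kofn
      if (!is.null(kf) && config$k_override > length(kf$genes))
        problems <- c(problems,
                      sprintf("k_override=%d exceeds the %d-gene exhaustion set",
                              config$k_override, length(kf$genes)))
    }
  }
  problems
}

#' Run the full annotation and spatial pipeline
#'
#' Stages run in order: QC filter, normalisation, cluster summaries, CD3
#' gating + lineage + state calls, composition statistics, CyTOF
#' annotation, spatial proximity. A stage is skipped when its input is
#' absent from the configuration. All randomness flows from the single
#' top-level seed.
#'
#' @param config Configuration list or path to JSON. Recognised fields:
#'   `paths` (`matrix` = expression triplet directory, `cellmap` CSV,
#'   `heatmap` TSV, `areas` JSON), `qc` (arguments for [qc_thresholds()]),
#'   `scale` (normalisation scale), `ruleset` (name or path),
#'   `k_override` (exhaustion k), `proximity` (arguments for
#'   [proximity_config()]), `pairs` (list of source/target phenotype
#'   pairs), `out_dir`, `seed`.
#' @return A list of class `run_report`: per-stage results plus
#'   `assumption_flags` recording defaults in force (QC upper-bound
#'   defaults, exhaustion-k variant, heatmap thresholds) and a `config`
#'   echo. Written to `out_dir/run_report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  seed <- config$seed %||% 1
  report <- list(config = config, stages = character(),
                 assumption_flags = list(
                   qc_upper_bounds_default = is.null(config$qc),
                   exhaustion_k = NA_integer_,
                   heatmap_thresholds_default = TRUE
                 ))
  log_stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] in=%s out=%s", name, n_in, n_out))
    report$stages <<- c(report$stages, name)
  }
  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(config$paths$matrix)) {
    expr <- run_stage("read_matrix", read_expression_mtx(config$paths$matrix))
    thr <- if (is.null(config$qc)) qc_thresholds()
           else do.call(qc_thresholds, config$qc)
    qc <- run_stage("qc", qc_filter(expr, thr))
    log_stage("qc", qc$summary$n_in, qc$summary$n_out)
    report$qc <- list(report = qc$report, summary = qc$summary,
                      thresholds = unclass(thr))
    norm <- run_stage("normalize",
                      normalize_counts(qc$expr, config$scale %||% 10000))
    log_stage("normalize", qc$summary$n_out, qc$summary$n_out)
    profiles <- run_stage("summarize", cluster_summaries(norm))
    log_stage("summarize", qc$summary$n_out,
              length(unique(profiles$cluster)))
    rs <- load_ruleset(config$ruleset %||% "peng_rna_v1")
    if (!is.null(config$k_override))
      rs$states$exhausted$kofn$k <- as.integer(config$k_override)
    report$assumption_flags$exhaustion_k <- rs$states$exhausted$kofn$k
    calls <- run_stage("call_states", call_clusters(profiles, rs))
    log_stage("call_states", length(unique(profiles$cluster)), nrow(calls))
    report$profiles <- profiles
    report$calls <- calls
    # composition over lineage x states per sample (cluster-weighted)
    sizes <- norm$cells |> dplyr::count(.data$sample, .data$cluster)
    pop <- calls |>
      dplyr::mutate(population = dplyr::case_when(
        .data$lineage == "non_t" ~ "non_t",
        .data$treg ~ "treg",
        .data$senescent ~ "senescent",
        .data$exhausted ~ "exhausted",
        TRUE ~ .data$lineage
      )) |> dplyr::select("cluster", "population")
    comp_in <- dplyr::inner_join(sizes, pop, by = "cluster")
    report$composition <- run_stage("composition",
      composition_stats(comp_in, sample_col = "sample",
                        population_col = "population", weight_col = "n"))
    log_stage("composition", nrow(comp_in),
              nrow(report$composition$summary))
  }

  if (!is.null(config$paths$heatmap)) {
    hm <- readr::read_tsv(config$paths$heatmap, show_col_types = FALSE)
    rs_p <- load_ruleset(config$cytof_ruleset %||% "cytof_protein_v1")
    report$cytof <- run_stage("annotate_cytof", annotate_cytof(hm, rs_p))
    log_stage("annotate_cytof", nrow(hm), nrow(report$cytof))
  }

  if (!is.null(config$paths$cellmap)) {
    map <- run_stage("read_cellmap", read_cellmap_csv(config$paths$cellmap))
    pc <- if (is.null(config$proximity)) proximity_config()
          else do.call(proximity_config, config$proximity)
    pairs <- config$pairs %||% list(c("cd8", "epithelium"), c("treg", "cd8"))
    if (is.data.frame(pairs))
      pairs <- purrr::pmap(pairs, function(...) unlist(list(...)))
    report$spatial <- run_stage("spatial", proximity_report(map, pairs, pc))
    log_stage("spatial", nrow(map), nrow(report$spatial))
    if (!is.null(config$paths$areas)) {
      areas <- jsonlite::read_json(config$paths$areas, simplifyVector = TRUE)
      report$densities <- run_stage("compartment_density",
                                    compartment_density(map,
                                                        tibble::as_tibble(areas)))
      log_stage("compartment_density", nrow(map),
                nrow(report$densities$densities))
    }
  }

  report$seed <- seed
  report$version <- as.character(utils::packageVersion("tcellgater"))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    write_run_report(report, file.path(config$out_dir, "run_report.json"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages: ", paste(x$stages, collapse = " -> "), "\n",
      sep = "")
  if (!is.null(x$calls)) {
    cat("  lineages:\n")
    print(table(x$calls$lineage))
  }
  if (!is.null(x$spatial)) {
    cat("  spatial pairs x regions: ", nrow(x$spatial), "\n", sep = "")
  }
  invisible(x)
}

#' Write a run report as JSON
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  simplify <- function(x) {
    if (inherits(x, "composition_summary"))
      return(list(frequencies = x$frequencies, summary = x$summary))
    if (is.data.frame(x)) {
      drop <- intersect(c("provenance", "histogram", "fit"), names(x))
      x <- x[setdiff(names(x), drop)]
      if ("states" %in% names(x))
        x$states <- vapply(x$states, paste, "", collapse = ",")
      if ("labels" %in% names(x))
        x$labels <- vapply(x$labels, paste, "", collapse = ",")
      return(x)
    }
    x
  }
  payload <- list(
    version = report$version,
    seed = report$seed,
    stages = report$stages,
    assumption_flags = report$assumption_flags,
    qc = report$qc,
    calls = simplify(report$calls),
    composition = simplify(report$composition),
    cytof = simplify(report$cytof),
    spatial = simplify(report$spatial),
    densities = report$densities,
    config = report$config
  )
  payload <- payload[!vapply(payload, is.null, TRUE)]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}
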