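#' Gate cluster profiles to T-cells
#'
#' Retains clusters where at least one of CD3D, CD3E, CD3G has positive
#' 75th-percentile expression; clusters with no CD3 expression are excluded
#' so only T-cells are analysed.
#'
#' @param profiles Long profile tibble from [cluster_summaries()].
#' @param ruleset A [load_ruleset()] object with a `tcell_gate` block.
#' @return A list with `t_profiles` (retained rows) and `excluded` (a
#'   tibble of excluded clusters with their CD3 q75 values).
#' @export
gate_tcells <- function(profiles, ruleset = load_ruleset("peng_rna_v1")) {
  plist <- profiles_to_list(profiles)
  if (!length(plist)) {
    return(list(t_profiles = profiles,
                excluded = tibble::tibble(cluster = character(),
                                          cd3d_q75 = numeric(),
                                          cd3e_q75 = numeric(),
                                          cd3g_q75 = numeric())))
  }
  missing <- setdiff(c("CD3D", "CD3E", "CD3G"), unique(profiles$gene))
  if (length(missing))
    stop("profile axis is missing CD3 gene(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- vapply(plist, function(p) {
    evaluate_block(ruleset$tcell_gate, p, ruleset)$pass
  }, TRUE)
  excluded <- tibble::tibble(
    cluster = names(plist)[!keep],
    cd3d_q75 = vapply(plist[!keep], function(p) p$q75[["CD3D"]], 0),
    cd3e_q75 = vapply(plist[!keep], function(p) p$q75[["CD3E"]], 0),
    cd3g_q75 = vapply(plist[!keep], function(p) p$q75[["CD3G"]], 0)
  )
  list(t_profiles = profiles[profiles$cluster %in% names(plist)[keep], ],
       excluded = excluded)
}

#' Assign a T-cell lineage to each gated cluster
#'
#' Rules are applied in order -- double-negative, double-positive, CD4
#' (positive mean CD4 among the remaining clusters), CD8 (co-expression of
#' CD8A and CD8B among the remaining) -- and the first match wins, so every
#' cluster receives exactly one lineage (`unassigned` if none fires).
#'
#' @param t_profiles Gated profile tibble (see [gate_tcells()]).
#' @param ruleset A [load_ruleset()] object.
#' @return Tibble: `cluster`, `lineage`, `provenance` (list column of rule
#'   evaluation tibbles).
#' @export
assign_lineage <- function(t_profiles, ruleset = load_ruleset("peng_rna_v1")) {
  plist <- profiles_to_list(t_profiles)
  order <- unlist(ruleset$lineage_order)
  rows <- purrr::imap(plist, function(p, cl) {
    prov <- list()
    lineage <- "unassigned"
    for (ln in order) {
      r <- evaluate_block(ruleset$lineages[[ln]], p, ruleset)
      r$provenance$rule_group <- ln
      prov <- c(prov, list(r$provenance))
      if (r$pass) { lineage <- ln; break }
    }
    tibble::tibble(cluster = cl, lineage = lineage,
                   provenance = list(dplyr::bind_rows(prov)))
  })
  dplyr::bind_rows(rows)
}

#' Flag functional states on gated T-cell clusters
#'
#' Each state filter is applied independently, so a cluster can carry
#' several flags (for example Treg and exhausted). Exhaustion requires the
#' k-of-n signature to hold and TRDC positivity (gamma-delta T-cells) to be
#' absent.
#'
#' @param t_profiles Gated profile tibble.
#' @param ruleset A [load_ruleset()] object.
#' @return Tibble: `cluster`, one logical column per state, `states` (list
#'   column of flagged state names) and `provenance`.
#' @export
call_states <- function(t_profiles, ruleset = load_ruleset("peng_rna_v1")) {
  plist <- profiles_to_list(t_profiles)
  state_names <- names(ruleset$states)
  rows <- purrr::imap(plist, function(p, cl) {
    flags <- stats::setNames(vector("list", length(state_names)), state_names)
    prov <- list()
    for (st in state_names) {
      r <- evaluate_block(ruleset$states[[st]], p, ruleset,
                          state_flags = flags)
      r$provenance$rule_group <- st
      prov <- c(prov, list(r$provenance))
      flags[[st]] <- r$pass
    }
    out <- tibble::tibble(cluster = cl)
    for (st in state_names) out[[st]] <- isTRUE(flags[[st]])
    out$states <- list(state_names[unlist(flags)])
    out$provenance <- list(dplyr::bind_rows(prov))
    out
  })
  dplyr::bind_rows(rows)
}

#' Full cluster annotation: gate, lineage, states
#'
#' Convenience wrapper running [gate_tcells()], [assign_lineage()] and
#' [call_states()]; excluded (non-T) clusters appear with lineage `non_t`
#' and no state flags.
#'
#' @param profiles Long profile tibble from [cluster_summaries()].
#' @param ruleset A [load_ruleset()] object.
#' @return Tibble with one row per input cluster: `cluster`, `lineage`,
#'   state flags, `states`, `provenance`.
#' @export
call_clusters <- function(profiles, ruleset = load_ruleset("peng_rna_v1")) {
  gated <- gate_tcells(profiles, ruleset)
  calls <- if (nrow(gated$t_profiles)) {
    lin <- assign_lineage(gated$t_profiles, ruleset)
    st <- call_states(gated$t_profiles, ruleset)
    joined <- dplyr::left_join(
      lin, st, by = "cluster", suffix = c("_lineage", "_states"))
    joined$provenance <- purrr::map2(
      joined$provenance_lineage, joined$provenance_states, dplyr::bind_rows)
    dplyr::select(joined, -"provenance_lineage", -"provenance_states")
  } else NULL
  state_names <- names(ruleset$states)
  non_t <- if (nrow(gated$excluded)) {
    out <- tibble::tibble(cluster = gated$excluded$cluster,
                          lineage = "non_t")
    for (st in state_names) out[[st]] <- FALSE
    out$states <- rep(list(character()), nrow(out))
    out
  } else NULL
  res <- dplyr::bind_rows(calls, non_t)
  res[match(unique(profiles$cluster), res$cluster), ]
}

#' Annotate CyTOF metaclusters from a 0-1 normalised marker heatmap
#'
#' Applies the marker high/low definitions of a protein ruleset to each
#' metacluster row. All matching labels are reported; a metacluster
#' matching nothing is `unlabeled`.
#'
#' @param heatmap Data frame: first column the metacluster id, remaining
#'   columns per-marker normalised values in \[0, 1\].
#' @param ruleset A protein-kind [load_ruleset()] (default
#'   `"cytof_protein_v1"`).
#' @param high,low Optional overrides of the high/low thresholds.
#' @return Tibble: `metacluster`, one logical column per definition,
#'   `labels` (list column; `"unlabeled"` when empty) and `provenance`.
#' @export
annotate_cytof <- function(heatmap, ruleset = load_ruleset("cytof_protein_v1"),
                           high = NULL, low = NULL) {
  heatmap <- tibble::as_tibble(heatmap)
  vals <- as.matrix(heatmap[-1])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0) || any(vals > 1))
    stop("heatmap values must be numeric in [0, 1]", call. = FALSE)
  if (!is.null(high)) ruleset$thresholds$high <- high
  if (!is.null(low)) ruleset$thresholds$low <- low
  state_names <- names(ruleset$states)
  ids <- heatmap[[1]]
  rows <- purrr::map(seq_len(nrow(heatmap)), function(i) {
    p <- list(heatmap = stats::setNames(vals[i, ], colnames(vals)))
    flags <- stats::setNames(vector("list", length(state_names)), state_names)
    prov <- list()
    for (st in state_names) {
      r <- evaluate_block(ruleset$states[[st]], p, ruleset,
                          state_flags = flags)
      r$provenance$rule_group <- st
      prov <- c(prov, list(r$provenance))
      flags[[st]] <- r$pass
    }
    out <- tibble::tibble(metacluster = ids[i])
    for (st in state_names) out[[st]] <- isTRUE(flags[[st]])
    lab <- state_names[unlist(flags)]
    out$labels <- list(if (length(lab)) lab else "unlabeled")
    out$provenance <- list(dplyr::bind_rows(prov))
    out
  })
  dplyr::bind_rows(rows)
}

#' Per-sample population composition statistics
#'
#' Computes each population's per-sample frequency as a percentage of that
#' sample's total (the parent gate), then summarises across samples with
#' median, mean, sample standard deviation (n - 1 denominator) and
#' CV% = 100 sd / mean. A population absent from a sample contributes a 0%
#' frequency so per-sample frequencies always sum to 100 over the
#' partition.
#'
#' @param assignments Data frame with one row per cell (or per cluster
#'   weighted by `n`), with the sample and population columns named below.
#' @param sample_col,population_col Column names.
#' @param weight_col Optional count column (e.g. cluster sizes); rows count
#'   once when absent.
#' @return An object of class `composition_summary`: a list with
#'   `frequencies` (sample x population % table) and `summary`
#'   (per-population median/mean/sd/CV%, plus `n_samples` and a
#'   `sd_undefined` flag when only one sample is present).
#' @export
composition_stats <- function(assignments, sample_col = "sample",
                              population_col = "population",
                              weight_col = NULL) {
  df <- tibble::as_tibble(assignments)
  stopifnot(sample_col %in% names(df), population_col %in% names(df))
  df$..w <- if (is.null(weight_col)) 1 else df[[weight_col]]
  counts <- df |>
    dplyr::group_by(sample = .data[[sample_col]],
                    population = .data[[population_col]]) |>
    dplyr::summarise(n = sum(.data$..w), .groups = "drop")
  totals <- counts |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  empty <- totals$sample[totals$total == 0]
  if (length(empty)) {
    warning("sample(s) with zero parent cells excluded: ",
            paste(empty, collapse = ", "))
    counts <- counts[!counts$sample %in% empty, ]
    totals <- totals[!totals$sample %in% empty, ]
  }
  freq <- counts |>
    tidyr::complete(.data$sample, .data$population, fill = list(n = 0)) |>
    dplyr::left_join(totals, by = "sample") |>
    dplyr::mutate(frequency_pct = 100 * .data$n / .data$total)
  single <- length(unique(freq$sample)) == 1
  summary <- freq |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      median_pct = stats::median(.data$frequency_pct),
      mean_pct = mean(.data$frequency_pct),
      sd_pct = if (dplyr::n() > 1) stats::sd(.data$frequency_pct) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cv_pct = ifelse(.data$mean_pct > 0, 100 * .data$sd_pct / .data$mean_pct,
                      NA_real_),
      sd_undefined = .data$n_samples < 2
    )
  structure(list(frequencies = freq, summary = summary),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary> ", length(unique(x$frequencies$sample)),
      " sample(s), ", nrow(x$summary), " population(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}
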