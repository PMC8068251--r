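#' Quality-control thresholds for cell filtering
#'
#' Bounds follow the convention that cells strictly outside a bound are
#' excluded, so cells exactly at a bound are retained (fewer than
#' `min_genes` detected genes excludes; a mitochondrial fraction above --
#' not equal to -- `max_mito_frac` excludes).
#'
#' @param min_genes,max_genes Detected-gene bounds (defaults 200 and 2,500).
#' @param min_molecules,max_molecules Total-count bounds (defaults 400 and
#'   100,000; the upper bound is effectively non-binding and kept
#'   permissive).
#' @param max_mito_frac Maximum mitochondrial fraction (default 0.25).
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 2500,
                          min_molecules = 400, max_molecules = 100000,
                          max_mito_frac = 0.25, mito_prefix = "MT-") {
  stopifnot(min_genes < max_genes, min_molecules < max_molecules,
            max_mito_frac > 0, max_mito_frac <= 1)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 min_molecules = min_molecules,
                 max_molecules = max_molecules,
                 max_mito_frac = max_mito_frac, mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality cells from a raw count matrix
#'
#' Retains exactly the cells with `min_genes <= detected genes <= max_genes`,
#' `min_molecules <= total counts <= max_molecules` and mitochondrial
#' fraction `<= max_mito_frac`. A cell failing several criteria is counted
#' against each in the report.
#'
#' @param x An [expr_matrix()] of raw integer counts.
#' @param thresholds A [qc_thresholds()].
#' @return A list with `expr` (the filtered matrix) and `report` (a tibble
#'   with one row per criterion: `criterion`, `n_removed`, plus attributes
#'   `n_in` / `n_out` summarised in `summary`).
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(thresholds, "qc_thresholds"))
  if (x$normalized) stop("qc_filter expects raw counts", call. = FALSE)
  cts <- x$counts
  if (length(cts@x) && any(cts@x != round(cts@x))) {
    stop("counts must be integers; found non-integer values", call. = FALSE)
  }
  n_in <- ncol(cts)
  if (n_in == 0) {
    report <- tibble::tibble(criterion = character(), n_removed = integer())
    return(list(expr = x, report = report,
                summary = tibble::tibble(n_in = 0L, n_out = 0L)))
  }
  detected <- Matrix::colSums(cts > 0)
  total <- Matrix::colSums(cts)
  mito <- startsWith(rownames(cts), thresholds$mito_prefix)
  mito_frac <- if (any(mito)) {
    mf <- Matrix::colSums(cts[mito, , drop = FALSE]) / total
    mf[total == 0] <- 0
    mf
  } else rep(0, n_in)

  fails <- list(
    too_few_genes      = detected < thresholds$min_genes,
    too_many_genes     = detected > thresholds$max_genes,
    too_few_molecules  = total < thresholds$min_molecules,
    too_many_molecules = total > thresholds$max_molecules,
    high_mito          = mito_frac > thresholds$max_mito_frac
  )
  keep <- !Reduce(`|`, fails)
  report <- tibble::tibble(
    criterion = names(fails),
    n_removed = unname(vapply(fails, sum, 0L))
  )
  out <- expr_matrix(cts[, keep, drop = FALSE], x$cells[keep, , drop = FALSE])
  if (sum(keep) == 0) warning("no cells remain after QC filtering")
  list(expr = out, report = report,
       summary = tibble::tibble(n_in = n_in, n_out = sum(keep)))
}

#' Library-size normalise and log-transform counts
#'
#' Each count becomes `log(1 + count / cell_total * scale)`
#' (counts-per-`scale` then natural-log1p). Zeros stay zero, so the sparsity
#' pattern is preserved.
#'
#' @param x An [expr_matrix()] of raw counts; every cell must have a
#'   positive total.
#' @param scale Library-size scale factor (default 10,000).
#' @return A normalised `expr_matrix`.
#' @export
normalize_counts <- function(x, scale = 10000) {
  stopifnot(inherits(x, "expr_matrix"), scale > 0)
  if (x$normalized) stop("matrix is already normalized", call. = FALSE)
  total <- Matrix::colSums(x$counts)
  if (any(total == 0)) {
    bad <- x$cells$cell_id[total == 0]
    stop("cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  m <- x$counts
  # scale each column by scale/total, then log1p on the stored entries only
  m@x <- m@x * rep.int(scale / total, diff(m@p))
  m@x <- log1p(m@x)
  expr_matrix(m, x$cells, normalized = TRUE)
}

# 75th percentile by linear interpolation between order statistics
# (position 1 + p(n-1)), or the lower order statistic (type 1)
q75_stat <- function(sorted_vals, n, quantile_type) {
  if (quantile_type == "interpolated") {
    h <- 1 + 0.75 * (n - 1)
    lo <- sorted_vals[floor(h)]
    hi <- sorted_vals[ceiling(h)]
    lo + (h - floor(h)) * (hi - lo)
  } else {
    sorted_vals[max(1L, ceiling(0.75 * n))]
  }
}

#' Per-cluster mean and 75th-percentile expression profiles
#'
#' The substrate of all gating rules: for every cluster and gene, the
#' arithmetic mean (zeros included) and the 75th percentile of normalised
#' expression.
#'
#' @param x A normalised [expr_matrix()].
#' @param labels Optional cell -> cluster assignment (character vector in
#'   cell order, or named by `cell_id`); defaults to the `cluster` column of
#'   the cell metadata.
#' @param quantile_type `"interpolated"` (linear interpolation between order
#'   statistics at position `1 + 0.75 (n - 1)`) or `"lower"` (lower order
#'   statistic). The choice matters because gates test q75 = 0 vs > 0.
#' @return A tibble with columns `cluster`, `n_cells`, `gene`, `mean_norm`,
#'   `q75_norm` -- one row per cluster x gene.
#' @export
cluster_summaries <- function(x, labels = NULL,
                              quantile_type = c("interpolated", "lower")) {
  stopifnot(inherits(x, "expr_matrix"))
  quantile_type <- match.arg(quantile_type)
  if (is.null(labels)) {
    if (!"cluster" %in% names(x$cells))
      stop("no `labels` given and no `cluster` column in cell metadata",
           call. = FALSE)
    labels <- x$cells$cluster
  } else if (!is.null(names(labels))) {
    labels <- unname(labels[x$cells$cell_id])
  }
  stopifnot(length(labels) == ncol(x$counts))
  if (anyNA(labels)) stop("every cell must be labelled", call. = FALSE)

  gene_names <- rownames(x$counts)
  out <- vector("list", length(unique(labels)))
  i <- 0
  for (cl in unique(labels)) {
    i <- i + 1
    idx <- which(labels == cl)
    n <- length(idx)
    block <- as.matrix(x$counts[, idx, drop = FALSE])
    means <- rowMeans(block)
    q75 <- apply(block, 1, function(v) q75_stat(sort(v), n, quantile_type))
    out[[i]] <- tibble::tibble(
      cluster = cl, n_cells = n, gene = gene_names,
      mean_norm = unname(means), q75_norm = unname(q75)
    )
  }
  dplyr::bind_rows(out)
}

#' Compare pooled cluster-level expression between two tissues
#'
#' Descriptive only: per gene, the pooled median of cluster 75th-percentile
#' values in each profile set and their ratio. Genes absent from either set
#' are reported as missing.
#'
#' @param profiles_tumour,profiles_normal Profile tibbles from
#'   [cluster_summaries()].
#' @param genes_of_interest Genes to compare; defaults to the intersection
#'   plus union bookkeeping of both gene axes.
#' @return A tibble: `gene`, `median_q75_tumour`, `median_q75_normal`,
#'   `ratio`, `status` (`"ok"` or which set the gene is missing from).
#' @export
tissue_compare <- function(profiles_tumour, profiles_normal,
                           genes_of_interest = NULL) {
  g_t <- unique(profiles_tumour$gene)
  g_n <- unique(profiles_normal$gene)
  genes_of_interest <- genes_of_interest %||% sort(union(g_t, g_n))
  med <- function(profiles, g) {
    stats::median(profiles$q75_norm[profiles$gene == g])
  }
  purrr::map_dfr(genes_of_interest, function(g) {
    in_t <- g %in% g_t
    in_n <- g %in% g_n
    if (in_t && in_n) {
      mt <- med(profiles_tumour, g)
      mn <- med(profiles_normal, g)
      tibble::tibble(gene = g, median_q75_tumour = mt,
                     median_q75_normal = mn,
                     ratio = mt / mn, status = "ok")
    } else {
      tibble::tibble(
        gene = g, median_q75_tumour = if (in_t) med(profiles_tumour, g) else NA_real_,
        median_q75_normal = if (in_n) med(profiles_normal, g) else NA_real_,
        ratio = NA_real_,
        status = if (!in_t && !in_n) "missing_both"
                 else if (!in_t) "missing_tumour" else "missing_normal"
      )
    }
  })
}

#' Write cluster profiles as a wide TSV
#'
#' Rows are clusters; columns are `<gene>:mean` and `<gene>:q75`.
#' @param profiles Tibble from [cluster_summaries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  wide <- profiles |>
    tidyr::pivot_longer(c("mean_norm", "q75_norm"),
                        names_to = "stat", values_to = "value") |>
    dplyr::mutate(stat = ifelse(.data$stat == "mean_norm", "mean", "q75"),
                  col = paste0(.data$gene, ":", .data$stat)) |>
    dplyr::select("cluster", "n_cells", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read cluster profiles from a wide TSV
#' @param path TSV written by [write_profiles_tsv()].
#' @return A long profile tibble (`cluster`, `n_cells`, `gene`,
#'   `mean_norm`, `q75_norm`).
#' @export
read_profiles_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  wide |>
    tidyr::pivot_longer(-c("cluster", "n_cells"),
                        names_to = "col", values_to = "value") |>
    tidyr::separate("col", into = c("gene", "stat"), sep = ":") |>
    dplyr::mutate(stat = ifelse(.data$stat == "mean", "mean_norm", "q75_norm")) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    dplyr::mutate(cluster = as.character(.data$cluster))
}
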