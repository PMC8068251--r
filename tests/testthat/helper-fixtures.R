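# shared fixture builders; everything is generated in code

# small raw count matrix with explicit per-cell totals / detected genes
make_counts <- function(mat, gene_names = NULL, cell_ids = NULL) {
  if (is.null(gene_names)) gene_names <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(cell_ids)) cell_ids <- sprintf("c%02d", seq_len(ncol(mat)))
  rownames(mat) <- gene_names
  expr_matrix(Matrix::Matrix(mat, sparse = TRUE),
              tibble::tibble(cell_id = cell_ids))
}

# random integer count matrix including mitochondrial genes
random_counts <- function(n_genes = 50, n_cells = 80, seed = 1,
                          n_mito = 5) {
  set.seed(seed)
  mat <- matrix(rnbinom(n_genes * n_cells, mu = 3, size = 1),
                nrow = n_genes)
  gene_names <- c(sprintf("MT-%d", seq_len(n_mito)),
                  sprintf("G%03d", seq_len(n_genes - n_mito)))
  make_counts(mat, gene_names)
}

# one-cluster profile as the rule engine sees it: named q75/mean vectors
make_profile <- function(q75 = numeric(), mean = numeric()) {
  base <- setNames(rep(0, length(tcellgater:::RULE_GENES)),
                   tcellgater:::RULE_GENES)
  q <- base; q[names(q75)] <- q75
  m <- base; m[names(mean)] <- mean
  list(q75 = q, mean = m)
}

# long-format profile tibble for one or more clusters
make_profiles_tbl <- function(cluster_specs) {
  purrr::imap_dfr(cluster_specs, function(spec, cl) {
    p <- make_profile(spec$q75 %||% numeric(), spec$mean %||% numeric())
    tibble::tibble(cluster = cl, n_cells = spec$n %||% 10L,
                   gene = names(p$q75),
                   mean_norm = unname(p$mean), q75_norm = unname(p$q75))
  })
}

`%||%` <- rlang::`%||%`
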