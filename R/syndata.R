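#' @importFrom rlang %||%
NULL

# Genes referenced by the packaged RNA rulesets; every simulated matrix
# carries all of them so the rule engine never hits a missing symbol.
RULE_GENES <- c(
  "CD3D", "CD3E", "CD3G", "CD4", "CD8A", "CD8B", "FOXP3", "TIGIT", "ICOS",
  "ENTPD1", "CD27", "CD28", "KLRG1", "KLRB1", "B3GAT1", "HCST", "HMGB1",
  "HAVCR2", "PDCD1", "TOX", "LAG3", "CTLA4", "CD38", "TRDC"
)

EXHAUSTION_GENES_8 <- c("HAVCR2", "PDCD1", "TOX", "LAG3", "CTLA4", "TIGIT",
                        "CD38", "ENTPD1")

# run code under a seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default expression programs for planted T-cell states
#'
#' Negative-binomial mean vectors (counts per cell, before dropout and
#' low-capture thinning) for each planted state over the ruleset genes.
#' Genes not named in a program default to mean 0; background genes default
#' to the configured background mean. The programs are deliberately
#' well-separated: positive marker genes have means high enough that more
#' than a quarter of cells detect them (so the 75th-percentile gate fires),
#' and negative markers are exactly 0.
#'
#' @return Named list of named numeric vectors, one per state
#'   (`none`, `treg`, `senescent`, `exhausted`, `non_t`).
#' @export
default_state_programs <- function() {
  tbase <- c(CD3D = 3, CD3E = 3, CD3G = 1.5, CD27 = 2, CD28 = 2)
  list(
    none = tbase,
    treg = c(tbase, FOXP3 = 2, TIGIT = 2, ICOS = 2, ENTPD1 = 1.5),
    senescent = c(CD3D = 3, CD3E = 3, CD3G = 1.5, CD27 = 0, CD28 = 0,
                  KLRG1 = 2, KLRB1 = 1.5, B3GAT1 = 1.5, HCST = 1.5,
                  HMGB1 = 1.5),
    exhausted = c(tbase, HAVCR2 = 2, PDCD1 = 2, TOX = 1.5, LAG3 = 2,
                  CTLA4 = 1.5, TIGIT = 2, CD38 = 1.5, ENTPD1 = 1.5),
    non_t = c(CD3D = 0, CD3E = 0, CD3G = 0)
  )
}

# lineage overlays added on top of the state program
lineage_overlay <- function(lineage) {
  switch(lineage,
    tcell_cd4 = c(CD4 = 2, CD8A = 0, CD8B = 0),
    tcell_cd8 = c(CD8A = 2, CD8B = 2, CD4 = 0),
    tcell_dn  = c(CD4 = 0, CD8A = 0, CD8B = 0),
    tcell_dp  = c(CD4 = 2, CD8A = 2, CD8B = 2),
    non_t     = c(CD4 = 0, CD8A = 0, CD8B = 0),
    stop("unknown lineage: ", lineage, call. = FALSE)
  )
}

default_lineage_for_state <- function(state) {
  switch(state,
    treg = "tcell_cd4",
    senescent = "tcell_cd8",
    exhausted = "tcell_cd8",
    none = "tcell_cd8",
    non_t = "non_t",
    stop("unknown state: ", state, call. = FALSE)
  )
}

#' Configuration for the synthetic expression simulator
#'
#' @param planted_states Named character vector mapping cluster id to planted
#'   state, one of `"none"`, `"treg"`, `"senescent"`, `"exhausted"`,
#'   `"non_t"`.
#' @param cells_per_cluster Cells per cluster: a scalar, a vector with one
#'   entry per cluster, or a length-2 range sampled uniformly per cluster.
#'   Zero is allowed (empty cluster).
#' @param background_genes Number of unstructured background genes added to
#'   the ruleset genes (they provide library size).
#' @param background_mean Negative-binomial mean of background genes.
#' @param program_means Optional named list overriding
#'   [default_state_programs()] entries, per state.
#' @param planted_lineages Optional named character vector cluster ->
#'   lineage; defaults per state (treg -> CD4, senescent/exhausted/none ->
#'   CD8, non_t -> non-T).
#' @param dispersion Negative-binomial size parameter (> 0); larger is
#'   closer to Poisson.
#' @param dropout_rate Probability in \[0,1\] that any single count entry is
#'   zeroed (technical dropout).
#' @param low_capture_genes Genes whose counts are additionally binomially
#'   thinned, emulating poorly captured transcripts (defaults CD4, B3GAT1).
#' @param low_capture_factor Thinning retention probability for
#'   `low_capture_genes`.
#' @param n_samples Number of sample labels cells are cycled through.
#' @param tissue Tissue label stamped on every cell.
#' @param seed Integer seed; the simulation is a pure function of the
#'   configuration including this seed.
#'
#' @return A list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(planted_states,
                                  cells_per_cluster = 200,
                                  background_genes = 30,
                                  background_mean = 1,
                                  program_means = NULL,
                                  planted_lineages = NULL,
                                  dispersion = 2,
                                  dropout_rate = 0.05,
                                  low_capture_genes = c("CD4", "B3GAT1"),
                                  low_capture_factor = 0.1,
                                  n_samples = 1,
                                  tissue = "tumour",
                                  seed = 1) {
  if (is.null(names(planted_states)) || any(names(planted_states) == "")) {
    stop("`planted_states` must be a named vector (cluster id -> state)",
         call. = FALSE)
  }
  bad <- setdiff(planted_states,
                 c("none", "treg", "senescent", "exhausted", "non_t"))
  if (length(bad)) stop("unknown planted state(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(dispersion > 0, dropout_rate >= 0, dropout_rate <= 1,
            low_capture_factor > 0, low_capture_factor <= 1,
            background_genes >= 0)
  programs <- utils::modifyList(default_state_programs(),
                                as.list(program_means %||% list()))
  lineages <- planted_lineages %||%
    stats::setNames(vapply(planted_states, default_lineage_for_state, ""),
                    names(planted_states))
  cfg <- list(
    planted_states = planted_states,
    planted_lineages = lineages,
    cells_per_cluster = cells_per_cluster,
    background_genes = background_genes,
    background_mean = background_mean,
    programs = programs,
    dispersion = dispersion,
    dropout_rate = dropout_rate,
    low_capture_genes = low_capture_genes,
    low_capture_factor = low_capture_factor,
    n_samples = n_samples,
    tissue = tissue,
    seed = as.integer(seed)
  )
  class(cfg) <- "expression_sim_config"
  check_program_consistency(cfg)
  cfg
}

# every planted state's program must be recoverable by the packaged ruleset
check_program_consistency <- function(cfg) {
  p <- cfg$programs
  fail <- function(state, gene, why) {
    stop("program for state '", state, "' is inconsistent with the packaged ",
         "ruleset: gene ", gene, " ", why, call. = FALSE)
  }
  gv <- function(state, gene) {
    v <- unname(p[[state]][gene])
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  if ("treg" %in% cfg$planted_states && gv("treg", "FOXP3") <= 0)
    fail("treg", "FOXP3", "must have positive mean")
  if ("senescent" %in% cfg$planted_states) {
    if (gv("senescent", "CD27") != 0) fail("senescent", "CD27", "must have zero mean")
    if (gv("senescent", "CD28") != 0) fail("senescent", "CD28", "must have zero mean")
    if (gv("senescent", "KLRG1") <= 0) fail("senescent", "KLRG1", "must have positive mean")
    if (gv("senescent", "B3GAT1") <= 0) fail("senescent", "B3GAT1", "must have positive mean")
  }
  if ("exhausted" %in% cfg$planted_states) {
    pos <- sum(vapply(EXHAUSTION_GENES_8, function(x) gv("exhausted", x) > 0, TRUE))
    if (pos < 4) fail("exhausted", paste(EXHAUSTION_GENES_8, collapse = "/"),
                      "fewer than 4 exhaustion genes have positive mean")
    if (gv("exhausted", "TRDC") != 0) fail("exhausted", "TRDC", "must have zero mean")
  }
  if ("non_t" %in% cfg$planted_states) {
    for (cd3 in c("CD3D", "CD3E", "CD3G"))
      if (gv("non_t", cd3) != 0) fail("non_t", cd3, "must have zero mean")
  }
  invisible(cfg)
}

#' Simulate a sparse single-cell count matrix with planted T-cell states
#'
#' Counts are drawn per gene from a negative-binomial with state-program
#' means, then thinned by Bernoulli dropout; low-capture genes are
#' additionally binomially thinned. Identical configurations (including the
#' seed) give bit-identical output.
#'
#' @param config An [expression_sim_config()].
#' @return A list with `expr` (an [expr_matrix()] of raw counts, cells
#'   carrying `sample`, `tissue` and `cluster` labels) and `truth` (a list
#'   with `cluster_states`, a tibble of cluster, planted state and lineage).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  clusters <- names(config$planted_states)
  all_genes <- c(RULE_GENES,
                 if (config$background_genes > 0)
                   sprintf("BG%03d", seq_len(config$background_genes)))

  ncl <- length(clusters)
  sizes <- config$cells_per_cluster
  with_seed(config$seed, {
    n_cells <- if (length(sizes) == 1) rep(sizes, ncl)
      else if (length(sizes) == ncl && ncl != 2) sizes
      else if (length(sizes) == 2 && ncl != 2)
        sample(seq(sizes[1], sizes[2]), ncl, replace = TRUE)
      else sizes
    stopifnot(length(n_cells) == ncl, all(n_cells >= 0))

    blocks <- vector("list", ncl)
    for (i in seq_len(ncl)) {
      st <- config$planted_states[[i]]
      mu <- stats::setNames(rep(0, length(all_genes)), all_genes)
      mu[grepl("^BG", all_genes)] <- config$background_mean
      prog <- config$programs[[st]]
      mu[names(prog)] <- prog
      ov <- lineage_overlay(config$planted_lineages[[i]])
      mu[names(ov)] <- ov
      nc <- n_cells[i]
      if (nc == 0) {
        blocks[[i]] <- matrix(0, nrow = length(all_genes), ncol = 0)
        next
      }
      m <- matrix(
        stats::rnbinom(length(all_genes) * nc,
                       mu = rep(mu, nc), size = config$dispersion),
        nrow = length(all_genes), ncol = nc
      )
      if (config$dropout_rate > 0) {
        keep <- matrix(stats::rbinom(length(m), 1, 1 - config$dropout_rate),
                       nrow = nrow(m))
        m <- m * keep
      }
      lc <- intersect(config$low_capture_genes, all_genes)
      if (length(lc) && config$low_capture_factor < 1) {
        idx <- match(lc, all_genes)
        m[idx, ] <- matrix(
          stats::rbinom(length(idx) * nc, size = as.vector(m[idx, , drop = FALSE]),
                        prob = config$low_capture_factor),
          nrow = length(idx)
        )
      }
      blocks[[i]] <- m
    }
  })

  counts <- do.call(cbind, blocks)
  rownames(counts) <- all_genes
  total <- ncol(counts)
  cells <- tibble::tibble(
    cell_id = sprintf("cell%06d", seq_len(total)),
    sample = if (total)
      sprintf("S%d", ((seq_len(total) - 1) %% config$n_samples) + 1)
      else character(),
    tissue = rep(config$tissue, total),
    cluster = rep(clusters, times = vapply(blocks, ncol, 0L))
  )
  truth <- list(
    cluster_states = tibble::tibble(
      cluster = clusters,
      state = unname(config$planted_states),
      lineage = unname(config$planted_lineages[clusters])
    ),
    seed = config$seed
  )
  list(expr = expr_matrix(Matrix::Matrix(counts, sparse = TRUE), cells),
       truth = truth)
}

#' Configuration for the synthetic tissue-map simulator
#'
#' Epithelium is modelled as a union of random discs ("blobs"); everything
#' outside the discs is stroma. Cells are placed uniformly within their
#' compartment; compartment labels are derived from the final geometry.
#'
#' @param field_size Width and height of the field in micrometres.
#' @param n_epithelial_blobs,blob_radius Number and radius (um) of the
#'   epithelial discs.
#' @param n_epithelium,n_cd8,n_cd4,n_treg Cell counts per phenotype.
#' @param treg_stroma_prob Probability a Treg is placed in stroma (the rest
#'   go into the epithelium discs). Ignored when `planted_within_fraction`
#'   is set.
#' @param region Region label: `"cancer"`, `"pancreatitis"` or `"normal"`.
#' @param planted_within_fraction If set, exactly
#'   `floor(n_treg * fraction + 0.5)` Tregs are placed within
#'   `planted_radius` of a randomly chosen CD8 cell and the rest strictly
#'   farther, so co-localisation fractions are exact by construction.
#' @param planted_radius Radius (um) used by `planted_within_fraction`.
#' @param seed Integer seed.
#'
#' @return A list of class `tissue_sim_config`.
#' @export
tissue_sim_config <- function(field_size = c(2000, 2000),
                              n_epithelial_blobs = 6,
                              blob_radius = 200,
                              n_epithelium = 1500,
                              n_cd8 = 400,
                              n_cd4 = 300,
                              n_treg = 150,
                              treg_stroma_prob = 0.95,
                              region = c("cancer", "pancreatitis", "normal"),
                              planted_within_fraction = NULL,
                              planted_radius = 50,
                              seed = 1) {
  region <- match.arg(region)
  stopifnot(length(field_size) == 2, all(field_size > 0),
            n_epithelial_blobs >= 1, blob_radius > 0,
            n_epithelium >= 0, n_cd8 >= 0, n_cd4 >= 0, n_treg >= 0,
            treg_stroma_prob >= 0, treg_stroma_prob <= 1,
            planted_radius > 0)
  if (!is.null(planted_within_fraction)) {
    stopifnot(planted_within_fraction >= 0, planted_within_fraction <= 1)
    if (n_cd8 == 0 && n_treg > 0) {
      stop("planted_within_fraction requires at least one CD8 cell",
           call. = FALSE)
    }
  }
  structure(list(
    field_size = field_size, n_epithelial_blobs = n_epithelial_blobs,
    blob_radius = blob_radius, n_epithelium = n_epithelium, n_cd8 = n_cd8,
    n_cd4 = n_cd4, n_treg = n_treg, treg_stroma_prob = treg_stroma_prob,
    region = region, planted_within_fraction = planted_within_fraction,
    planted_radius = planted_radius, seed = as.integer(seed)
  ), class = "tissue_sim_config")
}

#' Packaged tissue scenarios
#'
#' `"fig4f_cancer_demo"` is the co-localisation demonstration: 1,000 Tregs
#' and 1,000 CD8 cells on a 6 x 6 mm field with 90% of Tregs planted within
#' 50 um of a CD8 cell. `"stroma_restricted_demo"` plants every Treg in
#' stroma, reproducing stroma-restricted regulatory infiltration.
#'
#' @param name Scenario name.
#' @param seed Seed override.
#' @return A [tissue_sim_config()].
#' @export
tissue_scenario <- function(name = c("fig4f_cancer_demo",
                                     "stroma_restricted_demo"),
                            seed = 7) {
  name <- match.arg(name)
  switch(name,
    fig4f_cancer_demo = tissue_sim_config(
      field_size = c(6000, 6000), n_epithelial_blobs = 8, blob_radius = 300,
      n_epithelium = 500, n_cd8 = 1000, n_cd4 = 300, n_treg = 1000,
      region = "cancer", planted_within_fraction = 0.9, planted_radius = 50,
      seed = seed
    ),
    stroma_restricted_demo = tissue_sim_config(
      field_size = c(2000, 2000), n_epithelial_blobs = 6, blob_radius = 250,
      n_epithelium = 1000, n_cd8 = 300, n_cd4 = 300, n_treg = 200,
      treg_stroma_prob = 1, region = "cancer", seed = seed
    )
  )
}

# uniform point in a disc of radius r about (cx, cy), clipped to the field
runif_disc <- function(n, cx, cy, r, field, max_tries = 10000) {
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      rr <- r * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      x <- cx[i] + rr * cos(th); y <- cy[i] + rr * sin(th)
      if (x >= 0 && x <= field[1] && y >= 0 && y <= field[2]) {
        out[i, ] <- c(x, y); break
      }
    }
    if (is.na(out[i, 1])) stop("disc sampling failed to land inside field")
  }
  out
}

in_any_blob <- function(x, y, blobs) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(blobs))) {
    inside <- inside |
      ((x - blobs$x[i])^2 + (y - blobs$y[i])^2 <= blobs$r[i]^2)
  }
  inside
}

#' Simulate a phenotyped tissue map with planted spatial structure
#'
#' @param config A [tissue_sim_config()].
#' @return A list with `map` (tibble: `cell_id`, `x_um`, `y_um`,
#'   `phenotype`, `region`, `compartment`) and `truth` (blob geometry and,
#'   when planting was requested, the per-Treg planted proximity flag).
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_sim_config"))
  f <- config$field_size
  r <- config$blob_radius

  with_seed(config$seed, {
    blobs <- tibble::tibble(
      x = stats::runif(config$n_epithelial_blobs, r, f[1] - r),
      y = stats::runif(config$n_epithelial_blobs, r, f[2] - r),
      r = r
    )
    place_in_blobs <- function(n) {
      if (n == 0) return(matrix(numeric(), 0, 2))
      b <- sample.int(nrow(blobs), n, replace = TRUE)
      runif_disc(n, blobs$x[b], blobs$y[b], r, f)
    }
    place_in_stroma <- function(n, max_tries = 10000) {
      if (n == 0) return(matrix(numeric(), 0, 2))
      out <- matrix(NA_real_, n, 2)
      for (i in seq_len(n)) {
        for (t in seq_len(max_tries)) {
          x <- stats::runif(1, 0, f[1]); y <- stats::runif(1, 0, f[2])
          if (!in_any_blob(x, y, blobs)) { out[i, ] <- c(x, y); break }
        }
        if (is.na(out[i, 1]))
          stop("stroma sampling failed; epithelium covers the field")
      }
      out
    }
    place_uniform <- function(n) {
      cbind(stats::runif(n, 0, f[1]), stats::runif(n, 0, f[2]))
    }

    epi <- place_in_blobs(config$n_epithelium)
    cd8 <- place_uniform(config$n_cd8)
    cd4 <- place_uniform(config$n_cd4)

    planted_within <- NULL
    if (!is.null(config$planted_within_fraction) && config$n_treg > 0) {
      n_in <- floor(config$n_treg * config$planted_within_fraction + 0.5)
      n_out <- config$n_treg - n_in
      anchors <- sample.int(nrow(cd8), n_in, replace = TRUE)
      near <- runif_disc(n_in, cd8[anchors, 1], cd8[anchors, 2],
                         config$planted_radius, f)
      far <- matrix(NA_real_, n_out, 2)
      for (i in seq_len(n_out)) {
        for (t in seq_len(10000)) {
          x <- stats::runif(1, 0, f[1]); y <- stats::runif(1, 0, f[2])
          d2 <- min((cd8[, 1] - x)^2 + (cd8[, 2] - y)^2)
          if (d2 > config$planted_radius^2) { far[i, ] <- c(x, y); break }
        }
        if (is.na(far[i, 1]))
          stop("cannot place a Treg farther than the planted radius; ",
               "CD8 cells cover the field", call. = FALSE)
      }
      treg <- rbind(near, far)
      planted_within <- c(rep(TRUE, n_in), rep(FALSE, n_out))
    } else {
      in_stroma <- stats::runif(config$n_treg) < config$treg_stroma_prob
      treg <- matrix(NA_real_, config$n_treg, 2)
      if (any(in_stroma)) treg[in_stroma, ] <- place_in_stroma(sum(in_stroma))
      if (any(!in_stroma)) treg[!in_stroma, ] <- place_in_blobs(sum(!in_stroma))
    }
  })

  xy <- rbind(epi, cd8, cd4, treg)
  phenotype <- rep(c("epithelium", "cd8", "cd4", "treg"),
                   c(nrow(epi), nrow(cd8), nrow(cd4), nrow(treg)))
  map <- tibble::tibble(
    cell_id = sprintf("tc%06d", seq_len(nrow(xy))),
    x_um = xy[, 1], y_um = xy[, 2],
    phenotype = phenotype,
    region = config$region,
    compartment = ifelse(in_any_blob(xy[, 1], xy[, 2], blobs),
                         "epithelium", "stroma")
  )
  truth <- list(blobs = blobs, seed = config$seed)
  if (!is.null(planted_within)) {
    truth$planted_within <- tibble::tibble(
      cell_id = map$cell_id[map$phenotype == "treg"],
      within = planted_within,
      radius = config$planted_radius
    )
  }
  list(map = map, truth = truth)
}

#' Sample from a truncated lognormal distance distribution
#'
#' Draws from lognormal(mu = log(geo_mean), sigma = log_sd) conditioned on
#' values at most `truncation`, by inverse-CDF sampling.
#'
#' @param geo_mean Geometric mean (um), > 0.
#' @param log_sd Log-scale standard deviation, > 0.
#' @param truncation Upper truncation point (um), > 0.
#' @param n Number of draws, >= 1.
#' @param seed Integer seed.
#' @return Numeric vector of `n` distances in (0, truncation].
#' @export
sample_truncated_lognormal <- function(geo_mean, log_sd, truncation, n,
                                       seed = 1) {
  if (!is.numeric(geo_mean) || geo_mean <= 0)
    stop("geo_mean must be > 0", call. = FALSE)
  if (!is.numeric(log_sd) || log_sd <= 0)
    stop("log_sd must be > 0", call. = FALSE)
  if (!is.numeric(truncation) || truncation <= 0)
    stop("truncation must be > 0", call. = FALSE)
  stopifnot(n >= 1)
  mu <- log(geo_mean)
  pmax_ <- stats::plnorm(truncation, meanlog = mu, sdlog = log_sd)
  with_seed(seed, {
    u <- stats::runif(n, 0, pmax_)
    stats::qlnorm(u, meanlog = mu, sdlog = log_sd)
  })
}

#' Write a tissue cell map as CSV
#'
#' Header: `cell_id,x_um,y_um,phenotype,region,compartment`.
#' @param map A cell-map tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cellmap_csv <- function(map, path) {
  cols <- c("cell_id", "x_um", "y_um", "phenotype", "region", "compartment")
  stopifnot(all(cols %in% names(map)))
  readr::write_csv(map[cols], path)
  invisible(path)
}

#' Read a tissue cell map CSV
#'
#' Accepts the `epithelium_rich` / `stroma_rich` compartment spellings and
#' normalises them to `epithelium` / `stroma`.
#' @param path CSV path with the [write_cellmap_csv()] header.
#' @return A cell-map tibble.
#' @export
read_cellmap_csv <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE)
  cols <- c("cell_id", "x_um", "y_um", "phenotype", "region", "compartment")
  missing <- setdiff(cols, names(map))
  if (length(missing)) stop("cell map is missing column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  map$compartment <- sub("_rich$", "", map$compartment)
  map
}

#' Write simulation ground truth as JSON
#' @param truth The `truth` element returned by a simulator.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
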