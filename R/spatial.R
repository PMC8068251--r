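#' Nearest-neighbour distances between two phenotype subsets
#'
#' Euclidean distance (um) from every source cell to its nearest target
#' cell. A cell never matches itself: self-pairs are excluded by `cell_id`,
#' so genuinely coincident distinct cells yield distance 0.
#'
#' @param sources,targets Cell-map tibbles (need `cell_id`, `x_um`, `y_um`).
#' @param chunk Internal block size for the cross-distance computation.
#' @return Numeric vector, one distance per source row.
#' @export
nearest_distance <- function(sources, targets, chunk = 2000) {
  if (nrow(targets) == 0) {
    stop("no target cells",
         if (!is.null(attr(targets, "phenotype_pair")))
           paste0(" for pair ", attr(targets, "phenotype_pair")) else "",
         call. = FALSE)
  }
  if (nrow(sources) == 0) return(numeric())
  tx <- targets$x_um; ty <- targets$y_um; tid <- targets$cell_id
  out <- numeric(nrow(sources))
  for (start in seq(1, nrow(sources), by = chunk)) {
    idx <- start:min(start + chunk - 1, nrow(sources))
    dx <- outer(sources$x_um[idx], tx, `-`)
    dy <- outer(sources$y_um[idx], ty, `-`)
    d2 <- dx * dx + dy * dy
    self <- outer(sources$cell_id[idx], tid, `==`)
    d2[self] <- Inf
    mins <- apply(d2, 1, min)
    if (any(!is.finite(mins)))
      stop("a source cell has no valid target (source and target sets ",
           "coincide with a single cell)", call. = FALSE)
    out[idx] <- sqrt(mins)
  }
  out
}

#' Proximity analysis configuration
#'
#' @param radius Cut-off radius in um (default 50).
#' @param n_bands Number of equal-width bands (default 20, i.e. 2.5 um
#'   bands at the default radius).
#' @return List of class `proximity_config`.
#' @export
proximity_config <- function(radius = 50, n_bands = 20) {
  stopifnot(radius > 0, n_bands >= 1)
  structure(list(radius = radius, n_bands = n_bands),
            class = "proximity_config")
}

#' Band distances into a fixed-radius histogram
#'
#' Bands are half-open `[lower, upper)` except the last, which is closed at
#' the radius so an exactly-radius distance is counted. Distances beyond
#' the radius are excluded from the bands but counted in `n_total`.
#'
#' @param distances Non-negative distances (um).
#' @param config A [proximity_config()].
#' @return Object of class `distance_histogram`: list with `bands` (tibble
#'   `band`, `lower`, `upper`, `count`), `edges`, `n_within`, `n_total`,
#'   `radius`, `n_bands`.
#' @export
band_histogram <- function(distances, config = proximity_config()) {
  stopifnot(all(distances >= 0))
  r <- config$radius
  nb <- config$n_bands
  edges <- seq(0, r, length.out = nb + 1)
  within <- distances <= r
  d <- distances[within]
  band <- pmin(findInterval(d, edges, rightmost.closed = FALSE,
                            left.open = FALSE), nb)
  counts <- tabulate(band, nbins = nb)
  structure(list(
    bands = tibble::tibble(band = seq_len(nb),
                           lower = edges[-(nb + 1)], upper = edges[-1],
                           count = counts),
    edges = edges, n_within = sum(within), n_total = length(distances),
    radius = r, n_bands = nb
  ), class = "distance_histogram")
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat("<distance_histogram> ", x$n_bands, " bands to ", x$radius, " um; ",
      x$n_within, "/", x$n_total, " distances within\n", sep = "")
  invisible(x)
}

# truncated-renormalised lognormal band probabilities
band_probs <- function(mu, sigma, edges, radius) {
  p <- stats::plnorm(edges, meanlog = mu, sdlog = sigma)
  diff(p) / stats::plnorm(radius, meanlog = mu, sdlog = sigma)
}

#' Fit a truncated lognormal to banded nearest-neighbour distances
#'
#' The default `binned_ls` method least-squares fits the observed band
#' relative frequencies against the truncation-renormalised lognormal band
#' probabilities and reports `R^2 = 1 - SSE / SStot` about the mean band
#' frequency (it can be negative for a bad fit). The `mle` method maximises
#' the truncated-lognormal likelihood of the raw distances and then
#' computes the same banded `R^2` from the fitted parameters; it serves as
#' the statistical cross-check for the binned fit.
#'
#' @param x A [band_histogram()] object (for `binned_ls`) or a numeric
#'   vector of raw distances (either method; binned via `config`).
#' @param config A [proximity_config()]; used when `x` is raw distances.
#' @param method `"binned_ls"` (default) or `"mle"`.
#' @return Object of class `lognormal_fit`: list with `mu`, `sigma`,
#'   `geo_mean` (= exp(mu), um), `r_squared`, `method`, `n` (distances used)
#'   and `convergence`.
#' @export
fit_lognormal <- function(x, config = proximity_config(),
                          method = c("binned_ls", "mle")) {
  method <- match.arg(method)
  if (inherits(x, "distance_histogram")) {
    hist <- x
    raw <- NULL
  } else {
    raw <- x[x <= config$radius]
    if (method == "mle" && length(raw) < 10)
      stop("mle needs at least 10 distances within the radius", call. = FALSE)
    if (length(raw) && stats::sd(raw) == 0)
      stop("zero variance: all distances are equal", call. = FALSE)
    hist <- band_histogram(x, config)
  }
  if (method == "binned_ls" && is.null(raw)) {
    if (sum(hist$bands$count > 0) < 3)
      stop("binned_ls needs at least 3 occupied bands", call. = FALSE)
  }
  edges <- hist$edges
  radius <- hist$radius
  f_obs <- hist$bands$count / hist$n_within
  if (sum(hist$bands$count > 0) < 3 && method == "binned_ls")
    stop("binned_ls needs at least 3 occupied bands", call. = FALSE)

  # moment start from band midpoints
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  m1 <- sum(f_obs * log(mids))
  v1 <- sum(f_obs * (log(mids) - m1)^2)
  start <- c(mu = m1, log_sigma = log(max(sqrt(v1), 0.05)))

  if (method == "binned_ls") {
    obj <- function(par) {
      p <- band_probs(par[1], exp(par[2]), edges, radius)
      sum((f_obs - p)^2)
    }
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    mu <- opt$par[[1]]; sigma <- exp(opt$par[[2]])
    conv <- opt$convergence
    n_used <- hist$n_within
  } else {
    d <- raw
    nll <- function(par) {
      mu <- par[1]; sigma <- exp(par[2])
      -sum(stats::dlnorm(d, mu, sigma, log = TRUE)) +
        length(d) * stats::plnorm(radius, mu, sigma, log.p = TRUE)
    }
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    mu <- opt$par[[1]]; sigma <- exp(opt$par[[2]])
    conv <- opt$convergence
    n_used <- length(d)
  }
  if (conv != 0) stop("lognormal fit did not converge (optim code ", conv,
                      ")", call. = FALSE)
  p_fit <- band_probs(mu, sigma, edges, radius)
  sse <- sum((f_obs - p_fit)^2)
  sstot <- sum((f_obs - mean(f_obs))^2)
  structure(list(
    mu = mu, sigma = sigma, geo_mean = exp(mu),
    r_squared = 1 - sse / sstot, method = method, n = n_used,
    radius = radius, n_bands = hist$n_bands, convergence = conv
  ), class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("<lognormal_fit> geometric mean ", signif(x$geo_mean, 4), " um, sigma ",
      signif(x$sigma, 3), " (log scale), R2 ", signif(x$r_squared, 3),
      " [", x$method, ", n = ", x$n, "]\n", sep = "")
  invisible(x)
}

#' Fraction of source cells with a target within a radius
#'
#' @param sources,targets Cell-map tibbles.
#' @param radius Radius in um.
#' @return Fraction in \[0, 1\].
#' @export
fraction_within <- function(sources, targets, radius = 50) {
  if (nrow(sources) == 0) stop("no source cells", call. = FALSE)
  d <- nearest_distance(sources, targets)
  mean(d <= radius)
}

#' Cell densities per tissue compartment
#'
#' Cells/mm2 per phenotype, region and compartment, plus each phenotype's
#' stroma-restriction ratio (stroma density / epithelium density; `Inf`
#' when the epithelium density is zero, flagged in `ratio_note`).
#'
#' @param map Cell-map tibble.
#' @param areas Tibble with `region`, `compartment`, `area_mm2` (> 0) for
#'   every populated stratum.
#' @return List with `densities` (phenotype x region x compartment tibble)
#'   and `stroma_ratio` (per phenotype x region).
#' @export
compartment_density <- function(map, areas) {
  areas <- tibble::as_tibble(areas)
  stopifnot(all(c("region", "compartment", "area_mm2") %in% names(areas)))
  if (any(areas$area_mm2 <= 0)) stop("areas must be > 0", call. = FALSE)
  areas$compartment <- sub("_rich$", "", areas$compartment)
  map$compartment <- sub("_rich$", "", map$compartment)
  strata <- unique(map[c("region", "compartment")])
  missing <- dplyr::anti_join(strata, areas, by = c("region", "compartment"))
  if (nrow(missing))
    stop("no area given for populated stratum: ",
         paste(missing$region, missing$compartment, sep = "/",
               collapse = ", "), call. = FALSE)
  counts <- map |>
    dplyr::count(.data$phenotype, .data$region, .data$compartment) |>
    tidyr::complete(.data$phenotype,
                    tidyr::nesting(!!!areas[c("region", "compartment")]),
                    fill = list(n = 0L))
  densities <- counts |>
    dplyr::inner_join(areas, by = c("region", "compartment")) |>
    dplyr::mutate(density_per_mm2 = .data$n / .data$area_mm2)
  wide <- densities |>
    dplyr::select("phenotype", "region", "compartment", "density_per_mm2") |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = "density_per_mm2")
  if (!"stroma" %in% names(wide)) wide$stroma <- NA_real_
  if (!"epithelium" %in% names(wide)) wide$epithelium <- NA_real_
  stroma_ratio <- wide |>
    dplyr::mutate(
      stroma_epithelium_ratio = .data$stroma / .data$epithelium,
      ratio_note = dplyr::case_when(
        is.na(.data$stroma) | is.na(.data$epithelium) ~ "missing_compartment",
        .data$epithelium == 0 & .data$stroma > 0 ~ "infinite",
        .data$epithelium == 0 & .data$stroma == 0 ~ "undefined",
        TRUE ~ "ok"
      )
    )
  list(densities = densities, stroma_ratio = stroma_ratio)
}

#' Per-region proximity report for phenotype pairs
#'
#' For each requested (source, target) phenotype pair and each region
#' present in the map: the banded distance histogram, the truncated
#' lognormal fit and the fraction of sources within the radius. Regions
#' where the fit is impossible (no targets, too few occupied bands) are
#' marked unavailable rather than erroring.
#'
#' @param map Cell-map tibble.
#' @param pairs List of `c(source_phenotype, target_phenotype)` pairs.
#' @param config A [proximity_config()].
#' @param method Fit method passed to [fit_lognormal()].
#' @return Tibble: `source`, `target`, `region`, `n_source`, `n_target`,
#'   `fraction_within`, `geo_mean`, `sigma`, `r_squared`, `status`, with
#'   `histogram` and `fit` list columns.
#' @export
proximity_report <- function(map, pairs = list(c("cd8", "epithelium"),
                                               c("treg", "cd8")),
                             config = proximity_config(),
                             method = "binned_ls") {
  regions <- unique(map$region)
  rows <- purrr::map(pairs, function(pr) {
    purrr::map(regions, function(rg) {
      sub <- map[map$region == rg, ]
      src <- sub[sub$phenotype == pr[1], ]
      tgt <- sub[sub$phenotype == pr[2], ]
      base <- tibble::tibble(source = pr[1], target = pr[2], region = rg,
                             n_source = nrow(src), n_target = nrow(tgt))
      res <- tryCatch({
        d <- nearest_distance(src, tgt)
        hist <- band_histogram(d, config)
        fit <- fit_lognormal(hist, config, method = method)
        dplyr::mutate(base,
          fraction_within = mean(d <= config$radius),
          geo_mean = fit$geo_mean, sigma = fit$sigma,
          r_squared = fit$r_squared, status = "ok",
          histogram = list(hist), fit = list(fit))
      }, error = function(e) {
        dplyr::mutate(base, fraction_within = NA_real_,
                      geo_mean = NA_real_, sigma = NA_real_,
                      r_squared = NA_real_,
                      status = paste0("unavailable: ", conditionMessage(e)),
                      histogram = list(NULL), fit = list(NULL))
      })
      res
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Serialise a proximity report
#'
#' Writes a TSV of the scalar columns and a JSON document including band
#' counts.
#' @param report Tibble from [proximity_report()].
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_proximity_report <- function(report, path_tsv = NULL, path_json = NULL) {
  scalars <- dplyr::select(report, -dplyr::any_of(c("histogram", "fit")))
  if (!is.null(path_tsv)) readr::write_tsv(scalars, path_tsv)
  if (!is.null(path_json)) {
    payload <- purrr::pmap(report, function(...) {
      row <- list(...)
      out <- row[setdiff(names(row), c("histogram", "fit"))]
      if (!is.null(row$histogram)) {
        out$band_counts <- row$histogram$bands$count
        out$band_edges <- row$histogram$edges
      }
      out
    })
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
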