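cells_at <- function(xy, prefix = "s") {
  tibble::tibble(cell_id = sprintf("%s%03d", prefix, seq_len(nrow(xy))),
                 x_um = xy[, 1], y_um = xy[, 2])
}

test_that("nearest distances: 3-4-5 triangle, coincidence, self-exclusion", {
  src <- cells_at(rbind(c(0, 0)))
  tgt <- cells_at(rbind(c(3, 4)), "t")
  expect_equal(nearest_distance(src, tgt), 5.0)

  # coincident but distinct cells are distance 0
  tgt0 <- cells_at(rbind(c(0, 0)), "t")
  expect_equal(nearest_distance(src, tgt0), 0.0)

  # a cell is never its own neighbour when sets overlap
  both <- cells_at(rbind(c(0, 0), c(1, 0)))
  expect_equal(nearest_distance(both, both), c(1, 1))

  expect_error(nearest_distance(src, tgt[0, ]), "target")
})

test_that("nearest distances equal the brute-force all-pairs oracle", {
  set.seed(12)
  src <- cells_at(cbind(runif(500, 0, 1000), runif(500, 0, 1000)))
  tgt <- cells_at(cbind(runif(400, 0, 1000), runif(400, 0, 1000)), "t")
  got <- nearest_distance(src, tgt, chunk = 64)
  oracle <- vapply(seq_len(nrow(src)), function(i) {
    sqrt(min((tgt$x_um - src$x_um[i])^2 + (tgt$y_um - src$y_um[i])^2))
  }, 0)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("band histogram uses half-open bands with a closed last edge", {
  h <- band_histogram(c(1, 2.6, 49.9, 50.0, 51), proximity_config())
  expect_equal(h$bands$count[1], 1L)   # 1 in [0, 2.5)
  expect_equal(h$bands$count[2], 1L)   # 2.6 in [2.5, 5)
  expect_equal(h$bands$count[20], 2L)  # 49.9 and exactly 50
  expect_equal(h$n_within, 4)
  expect_equal(h$n_total, 5)
  expect_equal(sum(h$bands$count), h$n_within)

  # exactly 2.5 falls in band 2 (half-open convention)
  h2 <- band_histogram(2.5)
  expect_equal(h2$bands$count[2], 1L)

  # all beyond the radius: zero counts
  h3 <- band_histogram(c(60, 70))
  expect_true(all(h3$bands$count == 0))
  expect_equal(h3$n_within, 0)
  expect_equal(h3$n_total, 2)
})

test_that("fitting analytic band probabilities recovers parameters with R2 = 1", {
  cfg <- proximity_config()
  edges <- seq(0, 50, length.out = 21)
  for (gm in c(5, 10, 20, 40)) {
    for (sg in c(0.3, 0.5, 0.8)) {
      p <- diff(plnorm(edges, log(gm), sg)) / plnorm(50, log(gm), sg)
      hist <- structure(list(
        bands = tibble::tibble(band = 1:20, lower = edges[-21],
                               upper = edges[-1], count = p * 1e9),
        edges = edges, n_within = 1e9, n_total = 1e9,
        radius = 50, n_bands = 20
      ), class = "distance_histogram")
      fit <- fit_lognormal(hist)
      expect_equal(fit$geo_mean, gm, tolerance = 1e-3)
      expect_equal(fit$sigma, sg, tolerance = 1e-3)
      expect_gt(fit$r_squared, 1 - 1e-8)
    }
  }
})

test_that("binned least-squares and truncated MLE agree on simulated distances", {
  d <- sample_truncated_lognormal(10, 0.5, 50, 1e5, seed = 21)
  ls_fit <- fit_lognormal(band_histogram(d))
  ml_fit <- fit_lognormal(d, method = "mle")
  expect_lt(abs(ls_fit$geo_mean - 10) / 10, 0.02)
  expect_lt(abs(ml_fit$geo_mean - 10) / 10, 0.02)
  expect_lt(abs(ls_fit$geo_mean - ml_fit$geo_mean) / ml_fit$geo_mean, 0.02)
  expect_equal(ls_fit$geo_mean, exp(ls_fit$mu))
})

test_that("the truncated MLE matches the untruncated closed form when truncation is slack", {
  set.seed(5)
  d <- rlnorm(5000, log(12), 0.4)
  d <- d[d <= 1000]
  fit <- fit_lognormal(d, proximity_config(radius = 1000, n_bands = 20),
                       method = "mle")
  # closed-form lognormal MLE (mean/sd of logs), as MASS::fitdistr computes
  expect_equal(fit$mu, mean(log(d)), tolerance = 1e-3)
  expect_equal(fit$sigma, sqrt(mean((log(d) - mean(log(d)))^2)),
               tolerance = 1e-2)
})

test_that("degenerate distance sets are rejected", {
  expect_error(fit_lognormal(rep(7, 50)), "zero variance")
  expect_error(fit_lognormal(c(1, 2), method = "mle"), "at least 10")
})

test_that("fitted geometric mean recovers the truth across seeds", {
  errs <- vapply(1:20, function(s) {
    d <- sample_truncated_lognormal(15, 0.8, 50, 1e4, seed = 100 + s)
    f <- fit_lognormal(band_histogram(d))
    abs(f$geo_mean - 15) / 15
  }, 0)
  expect_lt(median(errs), 0.03)
})

test_that("distances and fits are invariant under rigid motion", {
  set.seed(3)
  src <- cells_at(cbind(runif(200, 0, 500), runif(200, 0, 500)))
  tgt <- cells_at(cbind(runif(150, 0, 500), runif(150, 0, 500)), "t")
  d0 <- nearest_distance(src, tgt)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(df) {
    xy <- as.matrix(df[c("x_um", "y_um")]) %*% R
    df$x_um <- xy[, 1] + 1000; df$y_um <- xy[, 2] - 200
    df
  }
  d1 <- nearest_distance(rot(src), rot(tgt))
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("fraction_within counts sources with a close target", {
  src <- cells_at(rbind(c(0, 0), c(100, 0)))
  tgt <- cells_at(rbind(c(10, 0), c(160, 0)), "t")
  expect_equal(fraction_within(src, tgt, 50), 0.5)
  expect_equal(fraction_within(src, tgt, 1e9), 1.0)
})

test_that("compartment densities and stroma-restriction ratios", {
  map <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:12),
    x_um = 0, y_um = 0,
    phenotype = c(rep("treg", 10), rep("cd8", 2)),
    region = "cancer",
    compartment = c(rep("stroma", 10), "epithelium", "stroma")
  )
  areas <- tibble::tibble(region = "cancer",
                          compartment = c("stroma", "epithelium"),
                          area_mm2 = c(0.5, 0.25))
  cd <- compartment_density(map, areas)
  treg_stroma <- cd$densities[cd$densities$phenotype == "treg" &
                              cd$densities$compartment == "stroma", ]
  expect_equal(treg_stroma$density_per_mm2, 20)   # 10 cells / 0.5 mm2
  ratio <- cd$stroma_ratio[cd$stroma_ratio$phenotype == "treg", ]
  expect_equal(ratio$stroma_epithelium_ratio, Inf)
  expect_equal(ratio$ratio_note, "infinite")

  # missing area for a populated stratum is an error
  expect_error(compartment_density(map, areas[1, ]), "epithelium")
})

test_that("a fully stroma-restricted Treg simulation shows zero epithelial density", {
  sim <- simulate_tissue(tissue_scenario("stroma_restricted_demo", seed = 2))
  # any positive areas give a zero epithelial Treg density
  areas <- tibble::tibble(region = "cancer",
                          compartment = c("stroma", "epithelium"),
                          area_mm2 = c(3, 1))
  cd <- compartment_density(sim$map, areas)
  treg_epi <- cd$densities[cd$densities$phenotype == "treg" &
                           cd$densities$compartment == "epithelium", ]
  expect_equal(treg_epi$density_per_mm2, 0)
})

test_that("the per-region proximity report carries fits and fractions", {
  sim <- simulate_tissue(tissue_sim_config(n_epithelium = 300, n_cd8 = 150,
                                           n_cd4 = 50, n_treg = 80, seed = 4))
  rep1 <- proximity_report(sim$map, list(c("cd8", "epithelium")))
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$status, "ok")
  expect_true(rep1$fraction_within >= 0 && rep1$fraction_within <= 1)
  expect_equal(rep1$geo_mean, exp(rep1$fit[[1]]$mu))

  # duplicated map under a second region label gives identical fits
  map2 <- sim$map
  map2$region <- "normal"
  map2$cell_id <- paste0("dup_", map2$cell_id)
  both <- proximity_report(dplyr::bind_rows(sim$map, map2),
                           list(c("cd8", "epithelium")))
  expect_equal(both$geo_mean[1], both$geo_mean[2], tolerance = 1e-9)

  # region with no target cells is reported unavailable, not an error
  no_tgt <- sim$map[sim$map$phenotype != "epithelium", ]
  rep2 <- proximity_report(no_tgt, list(c("cd8", "epithelium")))
  expect_match(rep2$status, "unavailable")
})
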