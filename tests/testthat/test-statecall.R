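rs <- load_ruleset("peng_rna_v1")
rs3 <- load_ruleset("peng_rna_results_variant")
rs_cytof <- load_ruleset("cytof_protein_v1")

test_that("the CD3 gate keeps any-positive clusters and drops CD3-null ones", {
  profs <- make_profiles_tbl(list(
    nulls = list(q75 = c(CD3D = 0, CD3E = 0, CD3G = 0)),
    e_only = list(q75 = c(CD3E = 0.2)),
    d_only = list(q75 = c(CD3D = 1.1))
  ))
  g <- gate_tcells(profs, rs)
  expect_setequal(unique(g$t_profiles$cluster), c("e_only", "d_only"))
  expect_equal(g$excluded$cluster, "nulls")

  # empty input -> empty outputs
  empty <- gate_tcells(profs[0, ], rs)
  expect_equal(nrow(empty$t_profiles), 0)
  expect_equal(nrow(empty$excluded), 0)

  # missing CD3 gene in the axis is a configuration error
  expect_error(gate_tcells(profs[profs$gene != "CD3E", ], rs), "CD3E")
})

test_that("lineage assignment follows the DN -> DP -> CD4 -> CD8 order", {
  profs <- make_profiles_tbl(list(
    cd8 = list(q75 = c(CD3E = 1, CD8A = 1.2, CD8B = 0.8), mean = c(CD4 = 0.01)),
    dn  = list(q75 = c(CD3E = 1, CD8A = 0, CD8B = 0), mean = c(CD4 = 0.01)),
    dp  = list(q75 = c(CD3E = 1, CD8A = 1, CD8B = 1), mean = c(CD4 = 0.5)),
    cd4 = list(q75 = c(CD3E = 1), mean = c(CD4 = 0.5))
  ))
  got <- assign_lineage(profs, rs)
  expect_equal(got$lineage[match(c("cd8", "dn", "dp", "cd4"), got$cluster)],
               c("tcell_cd8", "tcell_dn", "tcell_dp", "tcell_cd4"))
  # exactly one lineage per cluster, provenance carries evaluated rules
  expect_equal(nrow(got), 4)
  expect_true(all(vapply(got$provenance, nrow, 0L) > 0))

  # CD4-mean-positive wins over CD8 co-expression (rule order as written)
  both <- make_profiles_tbl(list(
    amb = list(q75 = c(CD3E = 1, CD8A = 1, CD8B = 1), mean = c(CD4 = 0.2))))
  # CD8A/CD8B positive + CD4 positive means DP fires first
  expect_equal(assign_lineage(both, rs)$lineage, "tcell_dp")
})

test_that("exhaustion needs k positives and no TRDC; k differs between rulesets", {
  four_pos <- make_profiles_tbl(list(x = list(
    q75 = c(CD3E = 1, HAVCR2 = 0.5, LAG3 = 0.5, TIGIT = 0.5, ENTPD1 = 0.5,
            TRDC = 0))))
  expect_true(call_states(four_pos, rs)$exhausted)

  three_pos <- make_profiles_tbl(list(x = list(
    q75 = c(CD3E = 1, HAVCR2 = 0.5, LAG3 = 0.5, TIGIT = 0.5, TRDC = 0))))
  expect_false(call_states(three_pos, rs)$exhausted)   # k = 4 ruleset
  expect_true(call_states(three_pos, rs3)$exhausted)   # k = 3 variant

  # gamma-delta exclusion: TRDC positivity vetoes exhaustion
  trdc <- make_profiles_tbl(list(x = list(
    q75 = c(CD3E = 1, HAVCR2 = 0.5, PDCD1 = 0.5, LAG3 = 0.5, TIGIT = 0.5,
            CTLA4 = 0.5, TRDC = 0.4))))
  expect_false(call_states(trdc, rs)$exhausted)
})

test_that("Treg and senescent filters follow their conjunctions", {
  profs <- make_profiles_tbl(list(
    treg = list(q75 = c(CD3E = 1, FOXP3 = 0.3)),
    sen  = list(q75 = c(CD3E = 1, CD27 = 0, CD28 = 0, KLRG1 = 0.5),
                mean = c(B3GAT1 = 0.2)),
    sen_fail = list(q75 = c(CD3E = 1, CD27 = 0.4, CD28 = 0, KLRG1 = 0.5),
                    mean = c(B3GAT1 = 0.2))
  ))
  calls <- call_states(profs, rs)
  expect_true(calls$treg[calls$cluster == "treg"])
  expect_true(calls$senescent[calls$cluster == "sen"])
  expect_false(calls$senescent[calls$cluster == "sen_fail"])
  # states are non-exclusive flags; a treg-only cluster has just one
  expect_equal(calls$states[[which(calls$cluster == "treg")]], "treg")
})

test_that("single-rule evaluation reports value, threshold and outcome", {
  p <- make_profile(q75 = c(FOXP3 = 0.3))
  r <- evaluate_rule(gate_rule("FOXP3", "q75", "positive"), p, rs)
  expect_true(r$pass)
  expect_equal(r$provenance$value, 0.3)
  expect_equal(r$provenance$threshold, 0)

  # boundary: "negative" means <= threshold, so exactly 0 passes
  r0 <- evaluate_rule(gate_rule("CD27", "q75", "negative"), p, rs)
  expect_true(r0$pass)

  expect_error(evaluate_rule(gate_rule("NOPE", "q75", "positive"), p, rs),
               "NOPE")
})

test_that("k-of-n equals brute-force counting over all positivity patterns", {
  genes8 <- c("HAVCR2", "PDCD1", "TOX", "LAG3", "CTLA4", "TIGIT", "CD38",
              "ENTPD1")
  for (k in c(1, 4, 8)) {
    rule <- kofn_rule(genes8, k)
    for (pattern in 0:(2^8 - 1)) {
      bits <- as.integer(intToBits(pattern))[1:8]
      p <- make_profile(q75 = setNames(bits * 0.5, genes8))
      got <- evaluate_rule(rule, p, rs)$pass
      expect_identical(got, sum(bits) >= k)
    }
  }
  # k = |set| is the conjunction of the individual positives
  expect_error(kofn_rule(genes8, 9), "k must satisfy")
})

test_that("raising an exhaustion gene's q75 never un-flags exhaustion", {
  set.seed(31)
  genes8 <- c("HAVCR2", "PDCD1", "TOX", "LAG3", "CTLA4", "TIGIT", "CD38",
              "ENTPD1")
  for (i in 1:20) {
    q <- setNames(round(runif(8), 2), genes8)
    base <- make_profiles_tbl(list(x = list(q75 = c(CD3E = 1, q, TRDC = 0))))
    was <- call_states(base, rs)$exhausted
    j <- sample(genes8, 1)
    q[j] <- q[j] + runif(1, 0.1, 2)
    more <- make_profiles_tbl(list(x = list(q75 = c(CD3E = 1, q, TRDC = 0))))
    now <- call_states(more, rs)$exhausted
    expect_true(!was || now)
  }
})

test_that("calls are invariant to cluster order", {
  profs <- make_profiles_tbl(list(
    a = list(q75 = c(CD3E = 1, FOXP3 = 0.4)),
    b = list(q75 = c(CD3E = 1, CD8A = 1, CD8B = 1)),
    c = list(q75 = c(CD3D = 0, CD3E = 0, CD3G = 0))
  ))
  shuffled <- profs[order(rev(seq_len(nrow(profs)))), ]
  c1 <- call_clusters(profs, rs)
  c2 <- call_clusters(shuffled, rs)
  c2 <- c2[match(c1$cluster, c2$cluster), ]
  expect_equal(c1$lineage, c2$lineage)
  expect_equal(c1$treg, c2$treg)
})

test_that("CyTOF metacluster annotation matches the marker definitions", {
  markers <- c("CD57", "CD27", "CD28", "CD45RA", "4-1BB", "HLA-DR", "CCR7",
               "CD4", "FOXP3", "TIGIT", "ICOS", "CD39", "PD-1", "TIM-3",
               "LAG-3")
  row_of <- function(...) {
    v <- setNames(rep(0, length(markers)), markers)
    o <- c(...); v[names(o)] <- o
    tibble::as_tibble(as.list(c(metacluster = NA, v)))[-1] |>
      dplyr::mutate(metacluster = "m", .before = 1)
  }
  sen <- annotate_cytof(row_of(CD57 = 0.9, CD27 = 0.05, CD28 = 0.05), rs_cytof)
  expect_true(sen$senescent)
  expect_true("senescent" %in% sen$labels[[1]])

  naive <- annotate_cytof(row_of(CCR7 = 0.8, CD45RA = 0.9), rs_cytof)
  expect_true(naive$naive)
  none <- annotate_cytof(row_of(), rs_cytof)
  expect_equal(none$labels[[1]], "unlabeled")

  # activated Treg requires the Treg definition as well
  atreg <- annotate_cytof(row_of(CD4 = 0.9, FOXP3 = 0.8, TIGIT = 0.9,
                                 ICOS = 0.7, CD39 = 0.6), rs_cytof)
  expect_true(atreg$treg && atreg$activated_treg)
  not_treg <- annotate_cytof(row_of(TIGIT = 0.9, ICOS = 0.7, CD39 = 0.6),
                             rs_cytof)
  expect_false(not_treg$activated_treg)

  # protein exhaustion is 3-of-5 high
  exh <- annotate_cytof(row_of(`PD-1` = 0.6, TIGIT = 0.7, CD39 = 0.8),
                        rs_cytof)
  expect_true(exh$exhausted_protein)

  expect_error(annotate_cytof(row_of(CD57 = 1.2), rs_cytof), "\\[0, 1\\]")
})

test_that("composition statistics match hand computation", {
  df <- tibble::tibble(
    sample = rep(c("s1", "s2", "s3"), each = 100),
    population = c(rep("x", 1), rep("y", 99),
                   rep("x", 2), rep("y", 98),
                   rep("x", 3), rep("y", 97))
  )
  cs <- composition_stats(df)
  x <- cs$summary[cs$summary$population == "x", ]
  expect_equal(x$median_pct, 2)
  expect_equal(x$mean_pct, 2)
  expect_equal(x$sd_pct, 1)            # n-1 denominator
  expect_equal(x$cv_pct, 50)
  # frequencies sum to 100 per sample
  sums <- tapply(cs$frequencies$frequency_pct, cs$frequencies$sample, sum)
  expect_equal(as.numeric(sums), rep(100, 3))

  # single sample: sd reported as 0 with a flag
  one <- composition_stats(df[df$sample == "s1", ])
  expect_true(all(one$summary$sd_undefined))
  expect_equal(one$summary$sd_pct, c(0, 0))

  # identical frequencies -> CV 0
  same <- tibble::tibble(sample = rep(c("s1", "s2"), each = 10),
                         population = rep(c("x", "y"), 10))
  expect_equal(composition_stats(same)$summary$cv_pct, c(0, 0))
})
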