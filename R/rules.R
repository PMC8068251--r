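#' Construct a single gate rule
#'
#' A gate rule compares one statistic of one gene or marker against a
#' threshold. Comparator semantics: `positive` is strictly greater than the
#' threshold (normalised counts of undetected genes are exactly zero, so
#' "positive expression" means > 0 at the default threshold); `negative` is
#' less than or equal; `high` is greater than or equal (heatmap scale);
#' `low` is less than or equal.
#'
#' @param symbol Gene symbol or CyTOF marker name.
#' @param statistic One of `"q75"`, `"mean"`, `"heatmap"`.
#' @param comparator One of `"positive"`, `"negative"`, `"high"`, `"low"`.
#' @param threshold Optional numeric threshold; when `NULL` the ruleset's
#'   default for the statistic/comparator applies.
#' @return A list of class `gate_rule`.
#' @export
gate_rule <- function(symbol,
                      statistic = c("q75", "mean", "heatmap"),
                      comparator = c("positive", "negative", "high", "low"),
                      threshold = NULL) {
  statistic <- match.arg(statistic)
  comparator <- match.arg(comparator)
  if (statistic == "heatmap" && !comparator %in% c("high", "low"))
    stop("heatmap rules use the high/low comparators", call. = FALSE)
  if (statistic != "heatmap" && comparator %in% c("high", "low"))
    stop("high/low comparators are for heatmap rules", call. = FALSE)
  if (!is.null(threshold) && threshold < 0)
    stop("threshold must be >= 0", call. = FALSE)
  structure(list(symbol = symbol, statistic = statistic,
                 comparator = comparator, threshold = threshold),
            class = "gate_rule")
}

#' Construct a k-of-n positivity rule
#'
#' True when at least `k` of the named genes are positive (or `high`) for
#' the given statistic.
#'
#' @param genes Character vector of gene symbols or markers.
#' @param k Minimum number that must be positive; `1 <= k <= length(genes)`.
#' @param statistic Statistic each member rule tests (default `"q75"`).
#' @param comparator Comparator for each member (default `"positive"`).
#' @param threshold Optional shared threshold override.
#' @return A list of class `kofn_rule`.
#' @export
kofn_rule <- function(genes, k, statistic = "q75", comparator = "positive",
                      threshold = NULL) {
  if (k < 1 || k > length(genes))
    stop("k must satisfy 1 <= k <= length(genes); got k = ", k, " with ",
         length(genes), " genes", call. = FALSE)
  structure(list(genes = genes, k = as.integer(k), statistic = statistic,
                 comparator = comparator, threshold = threshold),
            class = "kofn_rule")
}

as_gate_rule <- function(x) {
  gate_rule(x$symbol, x$statistic, x$comparator, x$threshold %||% NULL)
}

#' Load a packaged or on-disk gating ruleset
#'
#' Packaged rulesets: `"peng_rna_v1"` (75th-percentile/mean gating with the
#' 4-of-8 exhaustion signature and gamma-delta exclusion),
#' `"peng_rna_results_variant"` (3-of-6 exhaustion variant) and
#' `"cytof_protein_v1"` (marker high/low annotations for 0-1 normalised
#' metacluster heatmaps).
#'
#' @param name_or_path A packaged ruleset name or a path to a ruleset JSON
#'   document with the same schema.
#' @return A list of class `gate_ruleset`.
#' @export
load_ruleset <- function(name_or_path = "peng_rna_v1") {
  path <- if (file.exists(name_or_path)) name_or_path else {
    p <- system.file("extdata", "rulesets",
                     paste0(name_or_path, ".json"), package = "tcellgater")
    if (p == "") stop("unknown ruleset: ", name_or_path, call. = FALSE)
    p
  }
  rs <- jsonlite::read_json(path, simplifyVector = FALSE)
  rs$thresholds <- lapply(rs$thresholds, as.numeric)
  rs$aliases <- lapply(rs$aliases, as.character)
  structure(rs, class = "gate_ruleset")
}

#' @export
print.gate_ruleset <- function(x, ...) {
  cat("<gate_ruleset> ", x$name, " (", x$kind, ")\n", sep = "")
  cat("  states: ", paste(names(x$states), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# default threshold for a rule under a ruleset
rule_threshold <- function(rule, ruleset) {
  if (!is.null(rule$threshold)) return(rule$threshold)
  th <- ruleset$thresholds
  switch(rule$comparator,
    positive = ,
    negative = th[[rule$statistic]] %||% 0,
    high = th[["high"]] %||% 0.5,
    low  = th[["low"]] %||% 0.25
  )
}

# find a rule symbol in the profile axis, trying the ruleset alias table
# in both directions
resolve_symbol <- function(symbol, axis, ruleset) {
  if (symbol %in% axis) return(symbol)
  fwd <- ruleset$aliases[[symbol]]
  if (!is.null(fwd) && fwd %in% axis) return(fwd)
  rev_hit <- names(ruleset$aliases)[
    vapply(ruleset$aliases, identical, TRUE, y = symbol)]
  rev_hit <- intersect(rev_hit, axis)
  if (length(rev_hit)) return(rev_hit[[1]])
  NA_character_
}

# profile: list(q75 = named numeric, mean = named numeric) or
# (heatmap = named numeric)
profile_value <- function(profile, statistic, symbol, ruleset) {
  vals <- profile[[statistic]]
  if (is.null(vals)) stop("profile carries no '", statistic, "' statistic",
                          call. = FALSE)
  sym <- resolve_symbol(symbol, names(vals), ruleset)
  if (is.na(sym)) stop("symbol not in profile axis: ", symbol, call. = FALSE)
  unname(vals[[sym]])
}

#' Evaluate a single gate or k-of-n rule against a cluster profile
#'
#' @param rule A [gate_rule()] or [kofn_rule()].
#' @param profile A named list of statistics for one cluster or metacluster,
#'   e.g. `list(q75 = c(FOXP3 = 0.3, ...), mean = c(CD4 = 0.1, ...))` or
#'   `list(heatmap = c(CD57 = 0.9, ...))`.
#' @param ruleset Ruleset providing default thresholds and symbol aliases.
#' @return A list with `pass` (logical) and `provenance` (a tibble of every
#'   symbol compared, its value, threshold, comparator and outcome).
#' @export
evaluate_rule <- function(rule, profile, ruleset = load_ruleset()) {
  if (inherits(rule, "kofn_rule")) {
    tau <- rule_threshold(rule, ruleset)
    member <- purrr::map(rule$genes, function(g) {
      v <- profile_value(profile, rule$statistic, g, ruleset)
      pass <- compare_value(v, rule$comparator, tau)
      tibble::tibble(symbol = g, statistic = rule$statistic,
                     comparator = rule$comparator, value = v,
                     threshold = tau, pass = pass)
    })
    prov <- dplyr::bind_rows(member)
    n_pos <- sum(prov$pass)
    prov$rule <- sprintf("kofn(k=%d, n=%d; %d positive)", rule$k,
                         length(rule$genes), n_pos)
    return(list(pass = n_pos >= rule$k, provenance = prov))
  }
  if (!inherits(rule, "gate_rule")) rule <- as_gate_rule(rule)
  tau <- rule_threshold(rule, ruleset)
  v <- profile_value(profile, rule$statistic, rule$symbol, ruleset)
  pass <- compare_value(v, rule$comparator, tau)
  prov <- tibble::tibble(symbol = rule$symbol, statistic = rule$statistic,
                         comparator = rule$comparator, value = v,
                         threshold = tau, pass = pass, rule = "gate")
  list(pass = pass, provenance = prov)
}

compare_value <- function(value, comparator, threshold) {
  switch(comparator,
    positive = value > threshold,
    negative = value <= threshold,
    high = value >= threshold,
    low  = value <= threshold,
    stop("unknown comparator: ", comparator, call. = FALSE)
  )
}

# evaluate a state/lineage block: conjunction of `all` gates, optional
# `any` disjunction, optional kofn, optional `exclude` gates (must NOT fire),
# optional `requires` (another state that must already hold)
evaluate_block <- function(block, profile, ruleset, state_flags = list()) {
  prov <- list()
  pass <- TRUE
  if (!is.null(block$requires)) {
    req <- isTRUE(state_flags[[block$requires]])
    prov <- c(prov, list(tibble::tibble(
      symbol = block$requires, statistic = "state", comparator = "requires",
      value = as.numeric(req), threshold = NA_real_, pass = req,
      rule = "requires")))
    pass <- pass && req
  }
  for (g in block$all %||% list()) {
    r <- evaluate_rule(as_gate_rule(g), profile, ruleset)
    prov <- c(prov, list(r$provenance))
    pass <- pass && r$pass
  }
  if (!is.null(block$any)) {
    any_res <- purrr::map(block$any,
                          ~ evaluate_rule(as_gate_rule(.x), profile, ruleset))
    prov <- c(prov, purrr::map(any_res, "provenance"))
    pass <- pass && any(purrr::map_lgl(any_res, "pass"))
  }
  if (!is.null(block$kofn)) {
    kf <- block$kofn
    missing <- kf$genes[vapply(kf$genes, function(g) {
      is.na(resolve_symbol(g, names(profile[[kf$statistic]]), ruleset))
    }, TRUE)]
    if (length(missing))
      stop("k-of-n rule references genes absent from the profile axis: ",
           paste(unlist(missing), collapse = ", "), call. = FALSE)
    r <- evaluate_rule(
      kofn_rule(unlist(kf$genes), kf$k, kf$statistic,
                kf$comparator %||% "positive", kf$threshold %||% NULL),
      profile, ruleset)
    prov <- c(prov, list(r$provenance))
    pass <- pass && r$pass
  }
  for (g in block$exclude %||% list()) {
    r <- evaluate_rule(as_gate_rule(g), profile, ruleset)
    p <- r$provenance
    p$rule <- "exclude"
    p$pass <- !r$pass
    prov <- c(prov, list(p))
    pass <- pass && !r$pass
  }
  list(pass = pass, provenance = dplyr::bind_rows(prov))
}

# long profile tibble -> named list of per-cluster stat vectors
profiles_to_list <- function(profiles) {
  split(profiles, profiles$cluster) |>
    lapply(function(d) list(
      q75 = stats::setNames(d$q75_norm, d$gene),
      mean = stats::setNames(d$mean_norm, d$gene)
    ))
}
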