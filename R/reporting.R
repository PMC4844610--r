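# Percent-activity normalization and food-intake classification: the
# analysis works with response patterns, so unit responses are expressed as
# percentages of their maximal responses over the reachable set.

#' Percent-activity configuration table
#'
#' Expresses every state's unit responses (and food intake) as a percentage
#' of the per-unit maximum over the reachable set, and attaches the
#' food-intake class.  Columns whose maximum is 0 are reported as all-zero
#' and flagged.
#'
#' @param reachable a `reachable_set`.
#' @param idx state indices to tabulate (default: all states).
#' @return data.frame (class `configuration_table`) with one row per state:
#'   `state` (index), `layer`, `terminal`, one percent column per unit,
#'   and `fi_class`; attribute `zero_max` names any all-zero columns.
#' @export
percent_activity <- function(reachable, idx = seq_len(nrow(reachable$resp))) {
  resp <- reachable$resp
  mx <- apply(resp, 2, max)
  zero_max <- colnames(resp)[mx <= 0]
  scale <- ifelse(mx > 0, mx, 1)
  pct <- sweep(resp[idx, , drop = FALSE], 2, scale, "/") * 100
  pct[pct > 100] <- 100   # guard float round-off at the per-column maximum
  fi <- reachable$model$spec$fi
  out <- data.frame(state = idx, layer = reachable$layer[idx],
                    terminal = reachable$terminal[idx],
                    pct, check.names = FALSE)
  if (!is.na(fi) && !(fi %in% zero_max)) {
    out$fi_class <- classify_fi(pct[, fi])
  }
  attr(out, "zero_max") <- zero_max
  class(out) <- c("configuration_table", "data.frame")
  out
}

#' Classify percent-of-maximum food intake
#'
#' Low for 0-43, medium for 44-80, high for 81-100 percent of the maximal
#' food intake achieved by the model, with the integer break points extended
#' to the reals as low <= 43 and high >= 81.
#'
#' @param fi_percent numeric in `[0, 100]`.
#' @return character vector in `{"low","medium","high"}`.
#' @export
classify_fi <- function(fi_percent) {
  if (any(fi_percent < 0 | fi_percent > 100)) {
    stop("fi_percent must lie in [0, 100]")
  }
  ifelse(fi_percent <= 43, "low", ifelse(fi_percent >= 81, "high", "medium"))
}

#' Column-wise summary of a configuration table
#'
#' Mean, median, interquartile range and full range of each unit's percent
#' activity over the selected configurations (the data behind box-plot
#' style summaries of configuration families).
#'
#' @param table a `configuration_table` (or any data.frame of numeric
#'   percent columns).
#' @return data.frame with one row per unit column: `mean`, `median`, `q1`,
#'   `q3`, `min`, `max`.
#' @export
summarize_configurations <- function(table) {
  cols <- vapply(table, is.numeric, TRUE)
  cols[names(cols) %in% c("state", "layer")] <- FALSE
  m <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(m) == 0L) stop("empty configuration table")
  data.frame(
    unit = colnames(m),
    mean = colMeans(m),
    median = apply(m, 2, median),
    q1 = apply(m, 2, quantile, 0.25, names = FALSE),
    q3 = apply(m, 2, quantile, 0.75, names = FALSE),
    min = apply(m, 2, min),
    max = apply(m, 2, max),
    row.names = NULL)
}

#' Export an analysis report
#'
#' Writes the configuration matrices behind the two paradox analyses
#' (AgRP/POMC and LH-GABAergic) as CSV, plus a JSON bundle with the
#' configuration counts, invariant-suite booleans and run metadata.
#'
#' @param reachable a `reachable_set` enumerated from the normal initial
#'   state under a zero-error parameterization.
#' @param dir output directory (created if needed).
#' @param label parameterization label recorded in the bundle.
#' @return the bundle, invisibly (list with counts and suite results).
#' @export
export_report <- function(reachable, dir, label = "calibrated") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- terminal_and_baseline(reachable)$baseline
  fi <- reachable$model$spec$fi
  mx <- apply(reachable$resp, 2, max)
  pct <- percent_activity(reachable)

  agrp_pomc <- list(
    expected_high = search_states(reachable, function(r)
      r[, "AgRP"] > base[["AgRP"]] & r[, "POMC"] < base[["POMC"]] &
        r[, fi] > 1.3 * base[[fi]]),
    anomalous_high = search_states(reachable, function(r)
      r[, "AgRP"] <= reachable$tol & r[, "POMC"] > base[["POMC"]] &
        r[, fi] > 1.3 * base[[fi]]),
    expected_low = search_states(reachable, function(r)
      r[, "AgRP"] <= reachable$tol & r[, "POMC"] > base[["POMC"]] &
        r[, fi] < 0.7 * base[[fi]]))
  lh_active <- function(r) {
    r[, "MCH"] > reachable$tol & r[, "LHGal"] > reachable$tol &
      r[, "NT"] > reachable$tol
  }
  fi_cls <- classify_fi(pmin(100, pmax(0, 100 * reachable$resp[, fi] / mx[[fi]])))
  lh_gaba <- list(
    low = search_states(reachable, function(r) lh_active(r) & fi_cls == "low"),
    medium = search_states(reachable, function(r)
      lh_active(r) & fi_cls == "medium"),
    high = search_states(reachable, function(r) lh_active(r) & fi_cls == "high"))

  for (nm in names(agrp_pomc)) {
    write.csv(percent_activity(reachable, agrp_pomc[[nm]]$idx),
              file.path(dir, paste0("agrp_pomc_", nm, ".csv")),
              row.names = FALSE)
  }
  for (nm in names(lh_gaba)) {
    write.csv(percent_activity(reachable, lh_gaba[[nm]]$idx),
              file.path(dir, paste0("lh_gaba_fi_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(pct, file.path(dir, "all_states.csv"), row.names = FALSE)

  t3 <- run_table3_suite(reachable)
  t4 <- run_table4_suite(reachable)
  bundle <- list(
    label = label,
    n_states = nrow(reachable$resp),
    max_terminal_layer = max_terminal_layer(reachable),
    counts = list(
      agrp_pomc = lapply(agrp_pomc, `[[`, "count"),
      lh_gaba = lapply(lh_gaba, `[[`, "count")),
    table3 = t3$holds, table4 = t4$holds)
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(bundle)
}
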