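#' Bundle a network spec with a parameter vector
#'
#' A `feeding_model` is the unit of analysis for everything downstream:
#' fixed-point simulation, truth-table evaluation, state-space enumeration,
#' search and invariant checking.
#'
#' @param spec a `network_spec` (default: [canonical_network()]).
#' @param params named parameter vector over [param_names()] (default: all
#'   zeros - the silent network).
#' @param stim_level magnitude (model units) added to a unit's net input by
#'   photo/chemogenetic soma stimulation, and the level delivered by
#'   projection stimulation (default 5).
#' @return An object of class `feeding_model`.
#' @export
feeding_model <- function(spec = canonical_network(),
                          params = make_params(spec), stim_level = 5) {
  params <- .check_params(spec, params)
  structure(
    list(spec = spec, params = params,
         theta = matrix(params, nrow = 1),
         plan = compile_plan(spec),
         stim_level = stim_level),
    class = "feeding_model")
}

#' @export
print.feeding_model <- function(x, ...) {
  cat("Feeding-circuit model:", length(x$params), "parameters,",
      length(x$plan$rule_ids), "rule units /",
      length(x$plan$forced_ids), "forced units\n")
  if (all(x$params == 0)) {
    cat("  (all parameters zero - silent network)\n")
  } else {
    cat("  |params| =", format(param_distance(x$params), digits = 5),
        " (Euclidean distance from the zero vector)\n")
  }
  invisible(x)
}

#' @export
coef.feeding_model <- function(object, ...) object$params

#' Baseline configuration of a model
#'
#' The unique terminal state reached from the normal initial state; its unit
#' responses are the baselines against which the 30 percent change criterion
#' is applied.
#'
#' @param model a [feeding_model()].
#' @return the terminal `model_state`.
#' @export
baseline_state <- function(model) {
  run_to_fixed_point(model, make_initial_state(model$spec))
}

#' Simulate the model to its terminal configuration
#'
#' Runs the network to its fixed point, optionally under a truth-table
#' experiment or an explicit manipulation list.  The model is deterministic,
#' so `nsim`/`seed` (part of the generic's signature) are ignored.
#'
#' @param object a [feeding_model()].
#' @param nsim,seed ignored (deterministic model).
#' @param experiment an `experiment_spec`, a list of manipulations, or
#'   `NULL` for the unmanipulated network.
#' @param ... unused.
#' @return the terminal `model_state`.
#' @export
simulate.feeding_model <- function(object, nsim = 1, seed = NULL,
                                   experiment = NULL, ...) {
  if (is.null(experiment)) return(baseline_state(object))
  inst <- apply_manipulations(object, experiment)
  run_to_fixed_point(inst$model, inst$state)
}

#' Classify truth-table outcomes under a model
#'
#' Runs each experiment to its terminal configuration and classifies the
#' simulated food intake (and, where observed, POMC/AgRP/OXT responses)
#' against the unmanipulated baseline using the 30 percent criterion.
#'
#' @param object a [feeding_model()].
#' @param experiments list of `experiment_spec` (default: the full truth
#'   table).
#' @param ... unused.
#' @return data.frame with one row per scored observation: experiment id,
#'   label, element, simulated value, baseline, expected and simulated
#'   category, and a `match` flag.
#' @export
predict.feeding_model <- function(object, experiments = load_truth_table(),
                                  ...) {
  if (inherits(experiments, "experiment_spec")) experiments <- list(experiments)
  base <- baseline_state(object)
  out <- list()
  for (ex in experiments) {
    term <- simulate(object, experiment = ex)
    for (el in names(ex$expected)) {
      expct <- ex$expected[[el]]
      if (expct == "na") next
      v <- term$resp[[el]]
      b <- base$resp[[el]]
      out[[length(out) + 1L]] <- data.frame(
        id = ex$id, label = ex$label, element = el,
        value = v, baseline = b,
        expected = expct,
        simulated = classify_change(v, b),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$match <- res$expected == res$simulated
  rownames(res) <- NULL
  res
}
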