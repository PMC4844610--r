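# Small synthetic networks with hand-enumerable behavior, plus a brute-force
# enumeration oracle.  Toys exercise the update semantics, not the biology.

#' Linear toy chain network
#'
#' `n_units` rule units in an excitatory chain driven by a single external
#' substance (`input`, level 1) with unit strength into the first unit;
#' `weights[k]` is the signed strength of the link into unit k (the first
#' entry weights the external input).  Negative weights make the link
#' inhibitory.  All biases are zero.
#'
#' @param n_units chain length, 2 to 4.
#' @param weights numeric length `n_units`; signs go into the wiring,
#'   magnitudes into the parameter vector.
#' @return list with `spec` (a `network_spec`) and `params`.
#' @export
make_toy_chain <- function(n_units, weights = rep(1, n_units)) {
  stopifnot(n_units >= 2L, n_units <= 4L, length(weights) == n_units)
  ids <- paste0("U", seq_len(n_units))
  units <- data.frame(id = ids, rule = TRUE, stringsAsFactors = FALSE)
  recs <- lapply(seq_len(n_units), function(k) {
    list(unit = ids[k], receptor = "R", sign = if (weights[k] < 0) -1 else 1,
         hook = "none",
         sources = if (k == 1L) "substance:input" else
           paste0("unit:", ids[k - 1L], ":T"))
  })
  receptors <- data.frame(
    unit = vapply(recs, `[[`, "", "unit"),
    receptor = vapply(recs, `[[`, "", "receptor"),
    sign = vapply(recs, `[[`, 0, "sign"),
    hook = vapply(recs, `[[`, "", "hook"), stringsAsFactors = FALSE)
  receptors$sources <- lapply(recs, `[[`, "sources")
  releases <- setNames(as.list(rep("T", n_units)), ids)
  spec <- network_spec(units = units, receptors = receptors,
                       releases = releases,
                       output_stage_order = character(0),
                       substances = "input")
  params <- make_params(spec)
  params[paste0(ids, ".R")] <- abs(weights)
  list(spec = spec, params = params)
}

#' Random acyclic toy network
#'
#' 2-4 rule units with random feedforward wiring: unit k receives from a
#' random nonempty subset of {external input, earlier units}, with random
#' excitatory/inhibitory signs, strengths drawn uniformly in `[0, 2]` and
#' biases in `[-1, 1]`.  Seeded for replay.
#'
#' @param n_units number of units (2-4).
#' @param seed RNG seed.
#' @return list with `spec` and `params`.
#' @export
random_toy <- function(n_units = sample(2:4, 1), seed = 1L) {
  set.seed(seed)
  n_units <- n_units  # force before further draws
  stopifnot(n_units >= 2L, n_units <= 4L)
  ids <- paste0("U", seq_len(n_units))
  units <- data.frame(id = ids, rule = TRUE, stringsAsFactors = FALSE)
  rec_list <- list()
  for (k in seq_len(n_units)) {
    pool <- c("substance:input",
              if (k > 1L) paste0("unit:", ids[seq_len(k - 1L)], ":T"))
    take <- pool[runif(length(pool)) < 0.7]
    if (!length(take)) take <- sample(pool, 1L)
    for (j in seq_along(take)) {
      rec_list[[length(rec_list) + 1L]] <- list(
        unit = ids[k], receptor = paste0("R", j),
        sign = sample(c(-1, 1), 1L), hook = "none", sources = take[j])
    }
  }
  receptors <- data.frame(
    unit = vapply(rec_list, `[[`, "", "unit"),
    receptor = vapply(rec_list, `[[`, "", "receptor"),
    sign = vapply(rec_list, `[[`, 0, "sign"),
    hook = vapply(rec_list, `[[`, "", "hook"), stringsAsFactors = FALSE)
  receptors$sources <- lapply(rec_list, `[[`, "sources")
  spec <- network_spec(units = units, receptors = receptors,
                       releases = setNames(as.list(rep("T", n_units)), ids),
                       output_stage_order = character(0),
                       substances = "input")
  ns <- nrow(receptors)
  params <- make_params(spec, c(runif(ns, 0, 2), runif(n_units, -1, 1)))
  list(spec = spec, params = params)
}

#' Brute-force state enumeration oracle
#'
#' Exhaustive recursion over all rule firing orders, without deduplication,
#' then set-collapse of the visited states.  Independent reference for
#' [enumerate_states()] on small networks (at most 4 rule units).
#'
#' @param model a [feeding_model()].
#' @param init initial `model_state` (default: the normal initial state).
#' @param tol dedup/applicability tolerance.
#' @param max_nodes recursion guard.
#' @return list with `keys` (sorted unique state keys), `terminal_keys`,
#'   `min_depth` (named by key: shallowest firing sequence reaching the
#'   state) and `n_visits` (tree nodes visited, pre-collapse).
#' @export
brute_force_enumerate <- function(model, init = NULL, tol = 1e-9,
                                  max_nodes = 2e5) {
  plan <- model$plan
  if (length(plan$rule_ids) > 4L) {
    stop("brute-force oracle is limited to 4 rule units")
  }
  if (is.null(init)) init <- make_initial_state(model$spec)
  init <- propagate_output_stage(init, model)
  rule_idx <- match(plan$rule_ids, plan$ids)
  depth_env <- new.env(hash = TRUE, parent = emptyenv())
  term_env <- new.env(hash = TRUE, parent = emptyenv())
  visits <- 0L
  rec <- function(state, d) {
    visits <<- visits + 1L
    if (visits > max_nodes) stop("brute-force node guard exceeded")
    key <- .state_key(state$net, state$resp, rule_idx, tol)
    prev <- depth_env[[key]]
    if (is.null(prev) || d < prev) depth_env[[key]] <- d
    # set-collapse applied on the fly: a revisit at no-smaller depth adds
    # neither new states nor better depths, so its subtree can be skipped
    # without changing the collapsed result
    if (!is.null(prev) && d >= prev) return(invisible(NULL))
    appl <- applicable_rules(state, model, tol)
    if (!length(appl)) {
      term_env[[key]] <- TRUE
      return(invisible(NULL))
    }
    for (u in appl) rec(step(state, u, model, tol), d + 1L)
    invisible(NULL)
  }
  rec(init, 0L)
  keys <- sort(ls(depth_env))
  list(keys = keys,
       terminal_keys = sort(ls(term_env)),
       min_depth = setNames(vapply(keys, function(k) depth_env[[k]], 0L),
                            keys),
       n_visits = visits)
}
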