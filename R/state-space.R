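# Nondeterministic update semantics: each hypothalamic (rule) unit MAY update
# whenever doing so would change its net input; output-stage units and FI
# MUST update immediately after any rule fires.  Enumerating all rule orders
# from an initial state yields the state-transition tree; states are
# deduplicated at tolerance, so the tree becomes a DAG over distinct
# response configurations.

.fresh_rule_nets <- function(plan, theta, resp_row, ctx) {
  rm1 <- rbind(resp_row)
  vapply(plan$rule_ids, function(id) {
    pu <- plan$units[[id]]
    .unit_net(pu, theta, rm1, ctx$sub, ctx$drug, ctx$ov)[1]
  }, numeric(1))
}

.state_key <- function(net, resp, rule_idx, tol = 1e-9) {
  paste(sprintf("%.9f", round(c(net[rule_idx], resp[rule_idx]) / tol) * tol),
        collapse = "|")
}

#' Rule units applicable in a state
#'
#' A rule (hypothalamic-unit update) is applicable iff the unit's freshly
#' computed net input differs from its stored net input by more than `tol`:
#' conditional rules execute only if they would change the state.
#'
#' @param state an elaborated `model_state` (output stage current).
#' @param model a [feeding_model()].
#' @param tol net-input change tolerance.
#' @return character vector of applicable rule-unit ids (empty for a
#'   terminal state).
#' @export
applicable_rules <- function(state, model, tol = 1e-9) {
  plan <- model$plan
  fresh <- .fresh_rule_nets(plan, model$theta, state$resp, .state_ctx(state))
  plan$rule_ids[abs(fresh - state$net[plan$rule_ids]) > tol]
}

#' Fire one rule: update a single hypothalamic unit
#'
#' Recomputes the unit's net input and response (its released transmitters
#' equal its response), then elaborates the output stage.  All other
#' hypothalamic units are untouched.  Stepping a non-applicable unit is an
#' error.
#'
#' @param state an elaborated `model_state`.
#' @param unit a rule-unit id from [applicable_rules()].
#' @param model a [feeding_model()].
#' @param tol net-input change tolerance.
#' @return the successor `model_state`.
#' @export
step <- function(state, unit, model, tol = 1e-9) {
  plan <- model$plan
  if (!unit %in% plan$rule_ids) stop(unit, " is not a rule unit")
  ctx <- .state_ctx(state)
  pu <- plan$units[[unit]]
  nn <- .unit_net(pu, model$theta, rbind(state$resp), ctx$sub, ctx$drug,
                  ctx$ov)[1]
  if (abs(nn - state$net[[pu$idx]]) <= tol) {
    stop("rule for ", unit, " is not applicable in this state")
  }
  state$net[[pu$idx]] <- nn
  state$resp[[pu$idx]] <- ctx$live[[pu$idx]] * max(0, nn + ctx$stim[[pu$idx]])
  propagate_output_stage(state, model)
}

#' Enumerate the deduplicated state-transition tree
#'
#' Breadth-first enumeration from an initial state: the elaborated initial
#' state is the root (layer 0); every applicable rule branches to a
#' successor; states indistinguishable at tolerance are merged (the
#' first-reached layer is recorded).  Complete: every state reachable by
#' some rule order is present.
#'
#' @param model a [feeding_model()].
#' @param init initial `model_state` (default: the normal initial state).
#' @param tol dedup/applicability tolerance.
#' @param max_states safety cap; exceeding it is an error.
#' @return An object of class `reachable_set`: a list with `resp`/`net`
#'   (state x unit matrices), `layer`, `terminal`, `pending` (state x
#'   rule-unit applicability), `transitions` (from, unit, to index triples),
#'   `keys`, and the generating `model`/`init`.
#' @export
enumerate_states <- function(model, init = NULL, tol = 1e-9,
                             max_states = 1e6) {
  plan <- model$plan
  if (is.null(init)) init <- make_initial_state(model$spec)
  ctx <- .state_ctx(init)
  init <- propagate_output_stage(init, model)
  nU <- length(plan$ids)
  rule_idx <- match(plan$rule_ids, plan$ids)
  nR <- length(rule_idx)

  resp <- matrix(NA_real_, 256L, nU)
  net <- matrix(NA_real_, 256L, nU)
  layer <- integer(256L)
  pending <- matrix(FALSE, 256L, nR)
  index <- new.env(hash = TRUE, parent = emptyenv())
  trans_from <- integer(0)
  trans_unit <- integer(0)
  trans_to <- integer(0)

  grow <- function(m, k) {
    if (is.matrix(m)) rbind(m, matrix(NA, k, ncol(m))) else c(m, integer(k))
  }
  n_states <- 0L
  add_state <- function(nt, rs, lay) {
    key <- .state_key(nt, rs, rule_idx, tol)
    i <- index[[key]]
    if (!is.null(i)) return(c(i, 0L))
    n_states <<- n_states + 1L
    if (n_states > max_states) stop("state-space cap exceeded (", max_states, ")")
    if (n_states > nrow(resp)) {
      resp <<- grow(resp, nrow(resp))
      net <<- grow(net, nrow(net))
      pending <<- rbind(pending, matrix(FALSE, nrow(pending), nR))
      layer <<- c(layer, integer(length(layer)))
    }
    resp[n_states, ] <<- rs
    net[n_states, ] <<- nt
    layer[n_states] <<- lay
    index[[key]] <- n_states
    c(n_states, 1L)
  }

  add_state(init$net, init$resp, 0L)
  queue <- 1L
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    st <- init
    st$net <- setNames(net[i, ], plan$ids)
    st$resp <- setNames(resp[i, ], plan$ids)
    fresh <- .fresh_rule_nets(plan, model$theta, st$resp, ctx)
    appl <- which(abs(fresh - st$net[plan$rule_ids]) > tol)
    pending[i, appl] <- TRUE
    for (a in appl) {
      uid <- plan$rule_ids[a]
      s2 <- st
      ui <- rule_idx[a]
      s2$net[[ui]] <- fresh[a]
      s2$resp[[ui]] <- ctx$live[[ui]] * max(0, fresh[a] + ctx$stim[[ui]])
      s2 <- propagate_output_stage(s2, model)
      r <- add_state(s2$net, s2$resp, layer[i] + 1L)
      trans_from <- c(trans_from, i)
      trans_unit <- c(trans_unit, ui)
      trans_to <- c(trans_to, r[1])
      if (r[2] == 1L) queue <- c(queue, r[1])
    }
  }
  keep <- seq_len(n_states)
  resp <- resp[keep, , drop = FALSE]
  net <- net[keep, , drop = FALSE]
  colnames(resp) <- colnames(net) <- plan$ids
  pending <- pending[keep, , drop = FALSE]
  colnames(pending) <- plan$rule_ids
  structure(
    list(resp = resp, net = net, layer = layer[keep],
         terminal = rowSums(pending) == 0L,
         pending = pending,
         transitions = cbind(from = trans_from, unit = trans_unit,
                             to = trans_to),
         keys = vapply(keep, function(i) .state_key(net[i, ], resp[i, ],
                                                    rule_idx, tol), ""),
         model = model, init = init, tol = tol),
    class = "reachable_set")
}

#' @export
print.reachable_set <- function(x, ...) {
  cat("Reachable set:", nrow(x$resp), "distinct states,",
      sum(x$terminal), "terminal, max BFS layer", max(x$layer), "\n")
  invisible(x)
}

#' Terminal states and the baseline configuration
#'
#' Extracts all terminal states of an enumeration, asserts confluence (a
#' single terminal) when requested, and cross-checks the enumerated terminal
#' against the imperative fixed point of [run_to_fixed_point()] - the
#' declarative and imperative semantics must agree.
#'
#' @param reachable a `reachable_set` enumerated from the normal initial
#'   state (or any initial state).
#' @param require_confluence error if more than one terminal state exists.
#' @return list with `terminal_idx`, `baseline` (named response vector of
#'   the unique terminal; `NULL` if not unique) and `agrees_with_fixed_point`.
#' @export
terminal_and_baseline <- function(reachable, require_confluence = TRUE) {
  ti <- which(reachable$terminal)
  if (require_confluence && length(ti) != 1L) {
    stop("confluence violation: ", length(ti), " terminal states")
  }
  baseline <- NULL
  agrees <- NA
  if (length(ti) == 1L) {
    baseline <- reachable$resp[ti, ]
    fp <- run_to_fixed_point(reachable$model, reachable$init,
                             tol = reachable$tol)
    agrees <- max(abs(fp$resp - baseline)) <= reachable$tol &&
      max(abs(fp$net - reachable$net[ti, ])) <= reachable$tol
  }
  list(terminal_idx = ti, baseline = baseline,
       agrees_with_fixed_point = agrees)
}

#' Layer by which the terminal state is reached on every branch
#'
#' The exploration depth of the deduplicated state-transition tree: the
#' deepest layer at which a new configuration is first reached.  Branches of
#' the tree end either at the terminal state or by merging into an
#' already-enumerated configuration, so past this layer no branch can visit
#' anything new and the unique terminal has been reached along every branch.
#' (This is the quantity the declarative engine's breadth-first search
#' reports; the undeduplicated tree is factorially deeper because downstream
#' units can refire after each upstream update order.)
#'
#' @param reachable a `reachable_set`.
#' @return integer layer (0 if the initial state is terminal).
#' @export
max_terminal_layer <- function(reachable) {
  max(reachable$layer)
}

# ---------------------------------------------------------------------------
# Predicate search over configurations

.parse_atom <- function(s) {
  s <- gsub(" ", "", s)
  m <- regmatches(s, regexec(
    "^([A-Za-z0-9]+)(==|>=|<=|>|<)(baseline|1\\.3\\*baseline|[0-9.]+%|[0-9.eE+-]+)$",
    s))[[1]]
  if (length(m) != 4L) stop("cannot parse predicate atom: ", s)
  list(unit = m[2], op = m[3], rhs = m[4])
}

#' Search the reachable set for states meeting conditions
#'
#' Conditions are a conjunction of atomic comparisons on unit responses or
#' food intake.  `predicate` is either a function taking the matrix of
#' responses (returning a logical vector) or a comma-separated string of
#' atoms such as `"AgRP==0, POMC>baseline, FI>1.3*baseline"`; `baseline`
#' resolves against the unique terminal state and `k%` against k percent of
#' the unit's maximum response over the reachable set.  Matching follows the
#' one-or-more-rewrites search mode: the elaborated initial state is
#' excluded unless `include_init = TRUE`.
#'
#' @param reachable a `reachable_set`.
#' @param predicate function or DSL string (see above).
#' @param include_init include the elaborated initial state.
#' @return list with `idx` (matching state indices), `count` (number of
#'   distinct matching states) and `resp` (their response matrix).
#' @export
search_states <- function(reachable, predicate, include_init = FALSE) {
  resp <- reachable$resp
  if (is.character(predicate)) {
    atoms <- lapply(strsplit(predicate, ",", fixed = TRUE)[[1]], .parse_atom)
    base <- terminal_and_baseline(reachable)$baseline
    mx <- apply(resp, 2, max)
    sel <- rep(TRUE, nrow(resp))
    for (a in atoms) {
      if (!a$unit %in% colnames(resp)) stop("unknown unit in predicate: ", a$unit)
      v <- resp[, a$unit]
      rhs <- if (a$rhs == "baseline") {
        base[[a$unit]]
      } else if (a$rhs == "1.3*baseline") {
        1.3 * base[[a$unit]]
      } else if (grepl("%$", a$rhs)) {
        as.numeric(sub("%$", "", a$rhs)) / 100 * mx[[a$unit]]
      } else {
        as.numeric(a$rhs)
      }
      sel <- sel & switch(a$op,
        "==" = abs(v - rhs) <= reachable$tol,
        ">" = v > rhs, "<" = v < rhs, ">=" = v >= rhs, "<=" = v <= rhs)
    }
  } else {
    sel <- predicate(resp)
    if (!is.logical(sel) || length(sel) != nrow(resp)) {
      stop("predicate function must return one logical per state")
    }
  }
  if (!include_init) sel[1] <- FALSE
  idx <- which(sel)
  list(idx = idx, count = length(idx), resp = resp[idx, , drop = FALSE])
}
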