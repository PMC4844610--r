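# Core update equations.  All paths (scalar ops, the fixed-point runner, the
# population-vectorized GA evaluator and the state-space enumerator) go
# through .unit_net(), which evaluates one unit's net input for P parameter
# vectors at once: TH is a P x n_params matrix and resp a P x n_units
# response matrix; substance/drug levels, lesion/stim vectors and projection
# overrides are shared scalars (they come from the experimental context, not
# from the genome).

.unit_net <- function(pu, TH, resp, sub, drug, ov) {
  msum <- 0
  gate_term <- NULL
  gate_lig <- NULL
  gate_strength <- NULL
  for (r in pu$receptors) {
    lig <- 0
    for (j in seq_along(r$src_kind)) {
      lev <- switch(r$src_kind[[j]],
        substance = sub[[r$src_idx[[j]]]],
        drug      = drug[[r$src_idx[[j]]]],
        unit = {
          key <- paste0(r$src_name[[j]], "->", pu$id)
          o <- ov[[key]]
          if (is.null(o)) resp[, r$src_idx[[j]]] else o
        })
      lig <- lig + r$src_mult[[j]] * lev
    }
    s <- TH[, r$ipar]
    if (r$hook == "risperidone_halving") {
      s <- pmax(0, s - drug[["risperidone"]] / 2)
    }
    term <- r$sign * s * lig
    if (r$hook == "ntsca_cck_gate") {
      # CCK sensitization gate: the CCK term only enters when the modulator
      # sum is positive and both the CCK level and receptor strength are > 0.
      gate_term <- term
      gate_lig <- lig
      gate_strength <- s
    } else {
      msum <- msum + term
    }
  }
  net <- TH[, pu$ibias] + msum
  if (!is.null(gate_term)) {
    open <- (msum > 0) & (gate_lig > 0) & (gate_strength > 0)
    net <- net + open * gate_term
  }
  net
}

# Single topological sweep over all units: for a feedforward network this
# reaches the fixed point directly.  Returns P x n_units net and response
# matrices.
.eval_terminal <- function(plan, TH, ctx) {
  P <- nrow(TH)
  nU <- length(plan$ids)
  resp <- matrix(0, P, nU)
  net <- matrix(0, P, nU)
  for (pu in plan$units) {
    nn <- .unit_net(pu, TH, resp, ctx$sub, ctx$drug, ctx$ov)
    net[, pu$idx] <- nn
    resp[, pu$idx] <- ctx$live[[pu$idx]] * pmax(0, nn + ctx$stim[[pu$idx]])
  }
  list(net = net, resp = resp)
}

#' Net input to a unit
#'
#' The sum over the unit's receptors of sign x effective strength x (summed
#' cognate ligand levels), plus the unit's intrinsic bias.  Ligands of the
#' same receptor are summed before weighting; the 5HT2C receptor strength is
#' reduced by half the risperidone level (clamped at zero); the AgRP peptide
#' is subtracted from the melanocortin ligand sum; the NTSCA CCK term obeys
#' the sensitization gate (see [gated_net_input_ntsca()]); projection
#' overrides replace the transmitter level delivered by the affected
#' source unit.
#'
#' @param unit unit id.
#' @param state a `model_state`.
#' @param model a [feeding_model()].
#' @return the net input, a single real number.
#' @export
compute_net_input <- function(unit, state, model) {
  plan <- model$plan
  pu <- plan$units[[unit]]
  if (is.null(pu)) stop("unknown unit: ", unit)
  ctx <- .state_ctx(state)
  unname(.unit_net(pu, model$theta, rbind(state$resp), ctx$sub, ctx$drug,
                   ctx$ov)[1])
}

#' Gated net input to the NTSCA unit
#'
#' The catecholaminergic NTS unit's CCK receptor is sensitized by leptin and
#' oxytocin and desensitized by ghrelin and orexin: the CCK term enters the
#' net input only when the modulator sum (+LepRB x leptin - GHSR x ghrelin -
#' OXR x OX + OXTR x OXT) is positive and both the CCK level and the CCK
#' receptor strength are positive; otherwise the net input is the modulator
#' sum plus bias alone.
#'
#' @inheritParams compute_net_input
#' @return the NTSCA net input, a single real number.
#' @export
gated_net_input_ntsca <- function(state, model) {
  compute_net_input("NTSCA", state, model)
}

#' Response of a unit
#'
#' `live * max(0, net + stim)`: net input plus somatic stimulation, bounded
#' at zero (firing rates cannot be negative), and forced to zero for a
#' lesioned unit.
#'
#' @param net net input (real).
#' @param live 0/1 lesion flag.
#' @param stim nonnegative stimulation magnitude added to net input.
#' @return the response, a nonnegative real.
#' @export
unit_response <- function(net, live = 1, stim = 0) {
  stopifnot(all(live %in% c(0, 1)), all(stim >= 0))
  live * pmax(0, net + stim)
}

#' Elaborate the output stage of a state
#'
#' Recomputes the forced-update units (for the canonical network: NTSCA,
#' NTSGLP1, VTA, NAc, then FI), once each in their fixed feedforward order.
#' These units update by equations - whenever a hypothalamic unit updates,
#' the effect on the output stage and on food intake registers immediately.
#' A second application changes nothing.
#'
#' @param state a `model_state`.
#' @param model a [feeding_model()].
#' @return the elaborated `model_state`.
#' @export
propagate_output_stage <- function(state, model) {
  plan <- model$plan
  ctx <- .state_ctx(state)
  resp <- rbind(state$resp)
  for (id in plan$forced_ids) {
    pu <- plan$units[[id]]
    nn <- .unit_net(pu, model$theta, resp, ctx$sub, ctx$drug, ctx$ov)[1]
    state$net[[pu$idx]] <- nn
    state$resp[[pu$idx]] <- ctx$live[[pu$idx]] * max(0, nn + ctx$stim[[pu$idx]])
    resp[1, pu$idx] <- state$resp[[pu$idx]]
  }
  state
}

#' Run the network to its fixed point (imperative semantics)
#'
#' Repeatedly updates every unit (in declaration order) until no unit's net
#' input changes by more than `tol`.  For an acyclic spec this converges
#' within `n_units + 1` sweeps; non-convergence is reported as an acyclicity
#' violation.  The terminal configuration reached from the normal initial
#' state defines the baseline responses of all units.
#'
#' @param model a [feeding_model()].
#' @param state initial `model_state` with any manipulations already applied
#'   (default: the normal initial state).
#' @param tol net-input change tolerance (default 1e-9).
#' @return the terminal `model_state`.
#' @export
run_to_fixed_point <- function(model, state = NULL, tol = 1e-9) {
  plan <- model$plan
  if (is.null(state)) state <- make_initial_state(model$spec)
  ctx <- .state_ctx(state)
  ids <- plan$ids
  net <- state$net
  resp <- state$resp
  max_sweeps <- length(ids) + 1L
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    rm1 <- rbind(resp)
    for (id in ids) {
      pu <- plan$units[[id]]
      nn <- .unit_net(pu, model$theta, rm1, ctx$sub, ctx$drug, ctx$ov)[1]
      if (abs(nn - net[[pu$idx]]) > tol) changed <- TRUE
      net[[pu$idx]] <- nn
      rr <- ctx$live[[pu$idx]] * max(0, nn + ctx$stim[[pu$idx]])
      resp[[pu$idx]] <- rr
      rm1[1, pu$idx] <- rr
    }
    if (!changed) {
      state$net <- net
      state$resp <- resp
      return(state)
    }
  }
  stop("no fixed point within ", max_sweeps,
       " sweeps: spec is not feedforward")
}
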