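# A model state is one node of the transition system: per-unit net inputs and
# responses (transmitter output equals response), lesion flags, somatic
# stimulation, substance/drug levels and projection overrides.

#' Construct the initial model state
#'
#' All unit net inputs and responses start at 0 (a not-yet-updated unit is
#' silent), every unit is alive and unstimulated, and there are no
#' projection overrides.  The normal initial state has every endogenous
#' substance at level 1.0 (arbitrary units) and every drug at 0; it is the
#' state from which the baseline configuration is derived.
#'
#' @param spec a `network_spec`.
#' @param substances,drugs optional named numeric vectors of nonnegative
#'   levels; unnamed entries of the declared vocabulary keep their defaults.
#' @return An object of class `model_state`.
#' @export
make_initial_state <- function(spec, substances = NULL, drugs = NULL) {
  sub <- setNames(rep(1, length(spec$substances)), spec$substances)
  drg <- setNames(rep(0, length(spec$drugs)), spec$drugs)
  if (!is.null(substances)) {
    if (!all(names(substances) %in% spec$substances)) {
      stop("unknown substance in: ", paste(names(substances), collapse = ", "))
    }
    sub[names(substances)] <- substances
  }
  if (!is.null(drugs)) {
    if (!all(names(drugs) %in% spec$drugs)) {
      stop("unknown drug in: ", paste(names(drugs), collapse = ", "))
    }
    drg[names(drugs)] <- drugs
  }
  if (any(sub < 0) || any(drg < 0)) stop("substance/drug levels must be nonnegative")
  ids <- spec$units$id
  z <- setNames(numeric(length(ids)), ids)
  structure(
    list(net = z, resp = z,
         live = setNames(rep(1, length(ids)), ids),
         stim = z,
         substances = sub, drugs = drg,
         overrides = list()),
    class = "model_state")
}

#' @export
print.model_state <- function(x, digits = 4, ...) {
  cat("Model state\n")
  cat("  responses:\n")
  print(round(x$resp, digits))
  man <- character(0)
  if (any(x$live == 0)) {
    man <- c(man, paste0("lesioned: ", paste(names(x$live)[x$live == 0],
                                             collapse = ", ")))
  }
  if (any(x$stim > 0)) {
    man <- c(man, paste0("stimulated: ",
                         paste(names(x$stim)[x$stim > 0], collapse = ", ")))
  }
  if (length(x$overrides)) {
    man <- c(man, paste0("projection overrides: ",
                         paste(names(x$overrides), unlist(x$overrides),
                               sep = "=", collapse = ", ")))
  }
  if (length(man)) cat(" ", paste(man, collapse = "; "), "\n")
  cat("  substances:", paste(names(x$substances), x$substances, sep = "=",
                             collapse = " "), "\n")
  if (any(x$drugs > 0)) {
    cat("  drugs:", paste(names(x$drugs)[x$drugs > 0],
                          x$drugs[x$drugs > 0], sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# evaluation context: the parts of a state that stay fixed during updates
.state_ctx <- function(state) {
  list(sub = state$substances, drug = state$drugs, live = state$live,
       stim = state$stim, ov = state$overrides)
}
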