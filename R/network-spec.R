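# Ligand-source grammar used in receptor tables:
#   "substance:leptin"    level of an endogenous substance
#   "drug:FHT2Cag"        level of an exogenous drug
#   "unit:AgRP:GABA"      transmitter delivered by a unit (level = its response,
#                         or a projection override for that source->owner pair)
# A leading "-" subtracts the source from the receptor's ligand sum (used for
# the AgRP inverse agonism of the melanocortin receptors on OXT).

.fc_hooks <- c("none", "risperidone_halving", "melanocortin_inverse_agonism",
               "ntsca_cck_gate")

#' Construct a network wiring specification
#'
#' A `network_spec` declares the units of a feedforward food-intake control
#' network, their receptors (sign, ligand sources, modulation hooks), the
#' transmitters each unit releases, and the order in which the forced-update
#' (output-stage) units are elaborated.  Receptor strengths and unit biases
#' are *not* part of the spec; they are supplied separately as a parameter
#' vector (see [param_names()]).
#'
#' @param units data.frame with columns `id` (character) and `rule` (logical;
#'   `TRUE` for optional-update hypothalamic units, `FALSE` for forced-update
#'   output-stage units and the food-intake element).
#' @param receptors data.frame with columns `unit`, `receptor`, `sign`
#'   (+1/-1), `hook` (one of `"none"`, `"risperidone_halving"`,
#'   `"melanocortin_inverse_agonism"`, `"ntsca_cck_gate"`) and a list column
#'   `sources` of character vectors in the ligand-source grammar (see
#'   Details in the package vignette).
#' @param releases named list, unit id -> character vector of ligand ids.
#' @param output_stage_order character vector of the non-rule unit ids in
#'   forced-update order; if the network has a food-intake element its id
#'   must come last.
#' @param substances,drugs character vectors of declared substance/drug ids.
#' @param fi id of the food-intake element, or `NA` for toy networks
#'   without one.
#' @param n_params optional declared parameter-count checksum; validation
#'   fails if the actual count differs.
#' @return An object of class `network_spec`.
#' @seealso [canonical_network()], [read_network_spec()]
#' @export
network_spec <- function(units, receptors, releases, output_stage_order,
                         substances, drugs = character(0), fi = NA_character_,
                         n_params = NULL) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  receptors <- as.data.frame(receptors, stringsAsFactors = FALSE)
  spec <- structure(
    list(units = units, receptors = receptors, releases = releases,
         output_stage_order = output_stage_order,
         substances = substances, drugs = drugs, fi = fi,
         n_params = n_params),
    class = "network_spec")
  validate_network_spec(spec)
  spec
}

#' Validate a network specification
#'
#' Checks id uniqueness, that every ligand source is declared, that the
#' unit-to-unit ligand-flow graph is acyclic (the network is feedforward),
#' that the rule/forced partition is consistent with the output-stage order,
#' and, when a checksum is declared, that the optimizable parameter count
#' (receptor strengths + unit biases) equals it.
#'
#' @param spec a `network_spec`.
#' @return `spec`, invisibly; stops with an informative error otherwise.
#' @export
validate_network_spec <- function(spec) {
  u <- spec$units
  stopifnot(is.data.frame(u), all(c("id", "rule") %in% names(u)))
  if (anyDuplicated(u$id)) stop("duplicate unit ids")
  rc <- spec$receptors
  stopifnot(all(c("unit", "receptor", "sign", "hook", "sources") %in% names(rc)))
  if (!all(rc$unit %in% u$id)) stop("receptor owner not a declared unit")
  if (!all(rc$sign %in% c(-1, 1))) stop("receptor sign must be +1 or -1")
  if (!all(rc$hook %in% .fc_hooks)) stop("unknown modulation hook")
  if (anyDuplicated(paste(rc$unit, rc$receptor))) {
    stop("duplicate (unit, receptor) pair")
  }
  for (i in seq_len(nrow(rc))) {
    for (s in rc$sources[[i]]) {
      p <- .parse_source(s)
      ok <- switch(p$kind,
        substance = p$name %in% spec$substances,
        drug      = p$name %in% spec$drugs,
        unit      = p$name %in% u$id)
      if (!ok) stop("undeclared ligand source: ", s)
    }
  }
  nonrule <- u$id[!u$rule]
  if (!setequal(spec$output_stage_order, nonrule)) {
    stop("output_stage_order must list exactly the non-rule units")
  }
  if (!is.na(spec$fi)) {
    n <- length(spec$output_stage_order)
    if (n == 0L || spec$output_stage_order[n] != spec$fi) {
      stop("the food-intake element must be last in output_stage_order")
    }
  }
  .topo_order(spec)  # errors if cyclic
  if (!is.null(spec$n_params) && length(param_names(spec)) != spec$n_params) {
    stop("parameter count is ", length(param_names(spec)),
         ", declared checksum is ", spec$n_params)
  }
  invisible(spec)
}

.parse_source <- function(s) {
  mult <- 1
  if (startsWith(s, "-")) {
    mult <- -1
    s <- substring(s, 2L)
  }
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (!kind %in% c("substance", "drug", "unit")) {
    stop("bad ligand source kind in: ", s)
  }
  list(kind = kind, name = parts[2],
       ligand = if (length(parts) > 2) parts[3] else NA_character_,
       mult = mult)
}

# Kahn topological sort of units over unit->unit ligand edges.
.topo_order <- function(spec) {
  ids <- spec$units$id
  n <- length(ids)
  dep <- lapply(ids, function(id) character(0))
  names(dep) <- ids
  rc <- spec$receptors
  for (i in seq_len(nrow(rc))) {
    for (s in rc$sources[[i]]) {
      p <- .parse_source(s)
      if (p$kind == "unit") dep[[rc$unit[i]]] <- c(dep[[rc$unit[i]]], p$name)
    }
  }
  indeg <- vapply(dep, length, 1L)
  order <- character(0)
  avail <- ids[indeg == 0L]
  done <- character(0)
  while (length(avail)) {
    x <- avail[1]
    avail <- avail[-1]
    order <- c(order, x)
    done <- c(done, x)
    for (id in setdiff(ids, done)) {
      if (!id %in% avail && all(dep[[id]] %in% done)) avail <- c(avail, id)
    }
  }
  if (length(order) != n) stop("unit ligand-flow graph is not acyclic")
  order
}

#' Names of the optimizable parameters of a network
#'
#' One strength per (unit, receptor) pair, named `"<unit>.<receptor>"`, plus
#' one bias per unit, named `"<unit>.Bias"`.  For the canonical food-intake
#' network this is 38 strengths + 13 biases = 51 parameters.
#'
#' @param spec a `network_spec`.
#' @return character vector of parameter names (strengths first).
#' @export
param_names <- function(spec) {
  rc <- spec$receptors
  c(paste(rc$unit, rc$receptor, sep = "."),
    paste(spec$units$id, "Bias", sep = "."))
}

#' The canonical food-intake control network
#'
#' Builds the wiring of the 12-unit hypothalamic food-intake control model:
#' 8 hypothalamic rule units (AgRP, POMC, NGABA, OXT, MCH, OX, LHGal, NT),
#' 4 forced-update output-stage units (NTSCA, NTSGLP1, VTA, NAc) and the
#' food-intake element FI, driven by 5 substances (leptin, ghrelin, CCK,
#' serotonin/FHT, glucose) and 5 drugs (risperidone, 5HT2C and 5HT1B
#' agonists, exogenous alpha-MSH, exogenous GLP-1).  The 51 optimizable
#' parameters are the 38 receptor strengths and 13 unit biases.
#'
#' Three modulations depart from plain weighted summation: the strength of
#' the 5HT2C receptor on POMC is reduced by half the risperidone level
#' (clamped at zero); the AgRP peptide is an inverse agonist at the
#' melanocortin receptors on OXT (its delivered level is subtracted from the
#' alpha-MSH ligand sum before weighting); and the CCK receptor on NTSCA
#' only contributes when the remaining (sensitizing) net input is positive
#' and both CCK and the CCK receptor strength are positive.
#'
#' @return A validated `network_spec` with a declared 51-parameter checksum.
#' @export
canonical_network <- function() {
  units <- data.frame(
    id   = c("AgRP", "POMC", "NGABA", "OXT", "MCH", "OX", "LHGal", "NT",
             "NTSCA", "NTSGLP1", "VTA", "NAc", "FI"),
    rule = c(rep(TRUE, 8), rep(FALSE, 5)),
    stringsAsFactors = FALSE)

  R <- function(unit, receptor, sign, sources, hook = "none") {
    list(unit = unit, receptor = receptor, sign = sign, hook = hook,
         sources = sources)
  }
  defs <- list(
    ## Arc -----------------------------------------------------------------
    R("AgRP", "LepRB",  -1, "substance:leptin"),
    R("AgRP", "GHSR",   +1, "substance:ghrelin"),
    R("AgRP", "FHT1BR", -1, c("substance:FHT", "drug:FHT1Bag")),
    R("POMC", "LepRB",  +1, "substance:leptin"),
    R("POMC", "Y1R",    -1, "unit:AgRP:NPY"),
    R("POMC", "GABAR",  -1, c("unit:AgRP:GABA", "unit:NGABA:GABA")),
    R("POMC", "FHT2CR", +1, c("substance:FHT", "drug:FHT2Cag"),
      hook = "risperidone_halving"),
    R("NGABA", "LepRB", -1, "substance:leptin"),
    ## PVH -----------------------------------------------------------------
    R("OXT", "MCR", +1, c("unit:POMC:aMSH", "drug:aMSHx", "-unit:AgRP:AgRP"),
      hook = "melanocortin_inverse_agonism"),
    R("OXT", "GABAR", -1, "unit:AgRP:GABA"),
    R("OXT", "Y1R",   -1, "unit:AgRP:NPY"),
    R("OXT", "MCHR",  -1, "unit:MCH:MCH"),
    ## LH ------------------------------------------------------------------
    R("MCH", "GLUR", +1, "substance:glucose"),
    R("OX",  "GLUR", -1, "substance:glucose"),
    R("OX",  "GHSR", +1, "substance:ghrelin"),
    R("OX",  "GalR", -1, "unit:LHGal:Gal"),
    R("OX",  "AgRPR", +1, "unit:AgRP:AgRP"),
    R("OX",  "POMCR", -1, c("unit:POMC:aMSH", "drug:aMSHx")),
    R("LHGal", "LepRB", +1, "substance:leptin"),
    R("NT",    "LepRB", +1, "substance:leptin"),
    ## NTS -----------------------------------------------------------------
    R("NTSCA", "LepRB", +1, "substance:leptin"),
    R("NTSCA", "GHSR",  -1, "substance:ghrelin"),
    R("NTSCA", "OXR",   -1, "unit:OX:OX"),
    R("NTSCA", "OXTR",  +1, "unit:OXT:OXT"),
    R("NTSCA", "CCKR",  +1, "substance:CCK", hook = "ntsca_cck_gate"),
    R("NTSGLP1", "LepRB", +1, "substance:leptin"),
    R("NTSGLP1", "AR",    +1, "unit:NTSCA:CA"),
    ## VTA / NAc -----------------------------------------------------------
    R("VTA", "LepRB", -1, "substance:leptin"),
    R("VTA", "GHSR",  +1, "substance:ghrelin"),
    R("VTA", "OXR",   +1, "unit:OX:OX"),
    R("VTA", "NTR",   +1, "unit:NT:NT"),
    R("VTA", "GLP1R", -1, c("unit:NTSGLP1:GLP1", "drug:GLP1x")),
    R("NAc", "DR",    -1, "unit:VTA:DA"),
    R("NAc", "Y1R",   -1, "unit:AgRP:NPY"),
    R("NAc", "MCHR",  -1, "unit:MCH:MCH"),
    R("NAc", "GLP1R", +1, c("unit:NTSGLP1:GLP1", "drug:GLP1x")),
    ## food intake ---------------------------------------------------------
    R("FI", "NAcR", -1, "unit:NAc:NAc"),
    R("FI", "NTSCAR", -1, "unit:NTSCA:CA")
  )
  receptors <- data.frame(
    unit = vapply(defs, `[[`, "", "unit"),
    receptor = vapply(defs, `[[`, "", "receptor"),
    sign = vapply(defs, `[[`, 0, "sign"),
    hook = vapply(defs, `[[`, "", "hook"),
    stringsAsFactors = FALSE)
  receptors$sources <- lapply(defs, `[[`, "sources")

  releases <- list(
    AgRP = c("AgRP", "NPY", "GABA"), POMC = "aMSH", NGABA = "GABA",
    OXT = "OXT", MCH = "MCH", OX = "OX", LHGal = "Gal", NT = "NT",
    NTSCA = "CA", NTSGLP1 = "GLP1", VTA = "DA", NAc = "NAc")

  network_spec(
    units = units, receptors = receptors, releases = releases,
    output_stage_order = c("NTSCA", "NTSGLP1", "VTA", "NAc", "FI"),
    substances = c("leptin", "ghrelin", "CCK", "FHT", "glucose"),
    drugs = c("risperidone", "FHT2Cag", "FHT1Bag", "aMSHx", "GLP1x"),
    fi = "FI", n_params = 51L)
}

#' Test whether a spec is structurally the canonical food-intake network
#'
#' @param spec a `network_spec`.
#' @return `TRUE` iff the spec has 12 neural units plus a food-intake
#'   element, 8 of them rule units, 5 substances, and 51 parameters.
#' @export
is_canonical_network <- function(spec) {
  neural <- setdiff(spec$units$id, spec$fi)
  length(neural) == 12L &&
    sum(spec$units$rule) == 8L &&
    !is.na(spec$fi) &&
    length(spec$substances) == 5L &&
    length(param_names(spec)) == 51L
}

# ---------------------------------------------------------------------------
# Compiled evaluation plan: integer-indexed receptor terms in topological
# order, shared by the scalar engine, the population engine and the
# state-space enumerator.

compile_plan <- function(spec) {
  ids <- spec$units$id
  topo <- .topo_order(spec)
  pn <- param_names(spec)
  rc <- spec$receptors
  nU <- length(ids)
  sub_ids <- spec$substances
  drug_ids <- spec$drugs
  unit_plans <- lapply(topo, function(id) {
    rows <- which(rc$unit == id)
    recs <- lapply(rows, function(i) {
      srcs <- lapply(rc$sources[[i]], .parse_source)
      list(
        name = rc$receptor[i],
        ipar = match(paste(id, rc$receptor[i], sep = "."), pn),
        sign = rc$sign[i],
        hook = rc$hook[i],
        src_kind = vapply(srcs, `[[`, "", "kind"),
        src_idx = mapply(function(p) switch(p$kind,
          substance = match(p$name, sub_ids),
          drug = match(p$name, drug_ids),
          unit = match(p$name, ids)), srcs),
        src_name = vapply(srcs, `[[`, "", "name"),
        src_mult = vapply(srcs, `[[`, 0, "mult"))
    })
    list(id = id, idx = match(id, ids),
         ibias = match(paste(id, "Bias", sep = "."), pn),
         rule = spec$units$rule[match(id, ids)],
         gated = vapply(recs, function(r) r$hook == "ntsca_cck_gate", TRUE),
         receptors = recs)
  })
  names(unit_plans) <- topo
  list(units = unit_plans, topo = topo, ids = ids,
       rule_ids = ids[spec$units$rule],
       forced_ids = spec$output_stage_order,
       fi = spec$fi, n_params = length(pn), param_names = pn,
       substances = sub_ids, drugs = drug_ids)
}

#' @export
print.network_spec <- function(x, ...) {
  nr <- sum(x$units$rule)
  cat("Network spec:", nrow(x$units), "units (", nr, "rule,",
      nrow(x$units) - nr, "forced ),",
      nrow(x$receptors), "receptors,",
      length(param_names(x)), "parameters\n")
  cat("  substances:", paste(x$substances, collapse = ", "), "\n")
  if (length(x$drugs)) cat("  drugs:     ", paste(x$drugs, collapse = ", "), "\n")
  if (!is.na(x$fi)) cat("  food-intake element:", x$fi, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# JSON serialization

#' Write / read a network spec as structured JSON
#'
#' @param spec a `network_spec`.
#' @param path file path.
#' @return `read_network_spec` returns a validated `network_spec`;
#'   `write_network_spec` returns `path` invisibly.
#' @export
write_network_spec <- function(spec, path) {
  rc <- spec$receptors
  obj <- list(
    format = "feedcircuit-network", version = 1L,
    units = spec$units,
    receptors = data.frame(unit = rc$unit, receptor = rc$receptor,
                           sign = rc$sign, hook = rc$hook,
                           sources = vapply(rc$sources, paste, "",
                                            collapse = " "),
                           stringsAsFactors = FALSE),
    releases = spec$releases,
    output_stage_order = spec$output_stage_order,
    substances = spec$substances, drugs = spec$drugs,
    fi = spec$fi, n_params = spec$n_params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "feedcircuit-network")) {
    stop("not a feedcircuit network file: ", path)
  }
  rc <- obj$receptors
  rc$sign <- as.numeric(rc$sign)
  rc$sources <- strsplit(rc$sources, " ", fixed = TRUE)
  network_spec(
    units = obj$units, receptors = rc,
    releases = obj$releases,
    output_stage_order = obj$output_stage_order,
    substances = obj$substances,
    drugs = if (length(obj$drugs)) obj$drugs else character(0),
    fi = if (is.null(obj$fi)) NA_character_ else obj$fi,
    n_params = obj$n_params)
}
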