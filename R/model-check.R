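# "Whenever p then q" invariant checking over the reachable set.  An
# implication holds iff every enumerated state satisfying the context and
# antecedent also satisfies the consequent; a false result carries a
# counterexample witness (the lexicographically smallest state key among
# violations, for reproducibility).

#' Atomic propositions over response configurations
#'
#' Vocabulary used by the invariant suites:
#' \describe{
#'   \item{`prop_zero(u)`}{unit response equals 0 (at tolerance).}
#'   \item{`prop_pos(u)`}{response strictly positive.}
#'   \item{`prop_gt_baseline(u)`}{response above the unit's baseline.}
#'   \item{`prop_high(u)`}{response more than 30 percent above baseline.}
#'   \item{`prop_gt_pct(u, pct)`}{response above `pct` percent of the unit's
#'     maximum over the reachable set.}
#'   \item{`prop_fully_active(u)`}{the unit has updated (its rule is not
#'     pending) and its equation-determined response is positive.}
#'   \item{`prop_fi_class(cls)`}{food intake in the low (<= 43), medium or
#'     high (>= 81) percent-of-maximum class.}
#'   \item{`prop_nc()`}{no condition (always true).}
#' }
#'
#' @param unit unit id.
#' @param pct percent of the unit's maximum response.
#' @param cls one of `"low"`, `"medium"`, `"high"`.
#' @return a `proposition` object.
#' @name propositions
NULL

.prop <- function(kind, unit = NA_character_, value = NA_real_,
                  label = kind) {
  structure(list(kind = kind, unit = unit, value = value, label = label),
            class = "proposition")
}

#' @rdname propositions
#' @export
prop_zero <- function(unit) .prop("zero", unit, label = paste0(unit, " = 0"))

#' @rdname propositions
#' @export
prop_pos <- function(unit) .prop("pos", unit, label = paste0(unit, " > 0"))

#' @rdname propositions
#' @export
prop_gt_baseline <- function(unit) {
  .prop("gt_baseline", unit, label = paste0(unit, " > baseline"))
}

#' @rdname propositions
#' @export
prop_high <- function(unit) {
  .prop("high", unit, label = paste0(unit, " = high"))
}

#' @rdname propositions
#' @export
prop_gt_pct <- function(unit, pct) {
  .prop("gt_pct", unit, pct, label = paste0(unit, " > ", pct, "%"))
}

#' @rdname propositions
#' @export
prop_fully_active <- function(unit) {
  .prop("fully_active", unit, label = paste0(unit, " fully active"))
}

#' @rdname propositions
#' @export
prop_fi_class <- function(cls = c("low", "medium", "high")) {
  cls <- match.arg(cls)
  .prop("fi_class", value = match(cls, c("low", "medium", "high")),
        label = paste0("FI = ", cls))
}

#' @rdname propositions
#' @export
prop_nc <- function() .prop("nc", label = "NC")

#' @export
print.proposition <- function(x, ...) {
  cat("<proposition>", x$label, "\n")
  invisible(x)
}

# threshold environment shared by all propositions of one analysis
.prop_env <- function(reachable) {
  list(baseline = terminal_and_baseline(reachable)$baseline,
       max = apply(reachable$resp, 2, max),
       fi = reachable$model$spec$fi,
       tol = reachable$tol)
}

.prop_eval <- function(p, reachable, env) {
  if (p$kind == "nc") return(rep(TRUE, nrow(reachable$resp)))
  if (p$kind == "fi_class") {
    fi <- reachable$resp[, env$fi]
    if (env$max[[env$fi]] <= 0) stop("unresolvable threshold: max FI is 0")
    pct <- pmin(100, pmax(0, 100 * fi / env$max[[env$fi]]))
    cls <- classify_fi(pct)
    return(cls == c("low", "medium", "high")[p$value])
  }
  v <- reachable$resp[, p$unit]
  switch(p$kind,
    zero = abs(v) <= env$tol,
    pos = v > env$tol,
    gt_baseline = v > env$baseline[[p$unit]],
    high = v > 1.3 * env$baseline[[p$unit]],
    gt_pct = {
      if (env$max[[p$unit]] <= 0) {
        stop("unresolvable threshold: max ", p$unit, " is 0")
      }
      v > (p$value / 100) * env$max[[p$unit]]
    },
    fully_active = {
      up_to_date <- !reachable$pending[, p$unit]
      up_to_date & v > env$tol
    },
    stop("unknown proposition kind: ", p$kind))
}

.prop_all <- function(props, reachable, env) {
  if (inherits(props, "proposition")) props <- list(props)
  sel <- rep(TRUE, nrow(reachable$resp))
  for (p in props) sel <- sel & .prop_eval(p, reachable, env)
  sel
}

#' Check a "whenever antecedent then consequent" invariant
#'
#' True iff every enumerated state satisfying the context and antecedent
#' also satisfies the consequent.  Quantification covers all enumerated
#' states including the elaborated initial state (the checker starts from
#' the initial state).  An invariant whose context/antecedent is satisfied
#' by no state is vacuously true and flagged.
#'
#' @param reachable a `reachable_set`.
#' @param context proposition or list of propositions fixing the analysis
#'   frame (e.g. AgRP = 0 and POMC > baseline).
#' @param antecedent proposition(s); use [prop_nc()] for no condition.
#' @param consequent a single proposition.
#' @return list with `holds` (logical), `vacuous`, `witness` (index of one
#'   counterexample state, lexicographically smallest key; `NA` if true)
#'   and `n_checked` (states satisfying context and antecedent).
#' @export
check_invariant <- function(reachable, context, antecedent, consequent) {
  env <- .prop_env(reachable)
  sel <- .prop_all(context, reachable, env) &
    .prop_all(antecedent, reachable, env)
  good <- .prop_all(consequent, reachable, env)
  viol <- which(sel & !good)
  witness <- if (length(viol)) viol[order(reachable$keys[viol])][1] else NA_integer_
  list(holds = length(viol) == 0L, vacuous = !any(sel),
       witness = witness, n_checked = sum(sel))
}

#' Invariant suite for the AgRP/POMC paradox analysis
#'
#' Thirteen implications evaluated in the context AgRP = 0 and
#' POMC > baseline: the antecedents combine conditions on NT (> 0 or none),
#' OX (> 0, > 20 percent of maximum, or none) and OXT (= 0 or none); the
#' consequent is FI = high (row 2: FI = low).  Under a valid
#' parameterization only the strongest antecedent (NT > 0, OX > 20%,
#' OXT = 0) forces high food intake.
#'
#' @param reachable a `reachable_set` enumerated from the normal initial
#'   state.
#' @return data.frame with columns `row`, `antecedent`, `consequent`,
#'   `holds`, `vacuous`, `witness`.
#' @export
run_table3_suite <- function(reachable) {
  ctx <- list(prop_zero("AgRP"), prop_gt_baseline("POMC"))
  nt <- prop_pos("NT")
  ox0 <- prop_pos("OX")
  ox20 <- prop_gt_pct("OX", 20)
  oxt <- prop_zero("OXT")
  nc <- prop_nc()
  rows <- list(
    list(list(nc), "high"),            # 1
    list(list(nc), "low"),             # 2
    list(list(nt), "high"),            # 3
    list(list(ox0), "high"),           # 4
    list(list(oxt), "high"),           # 5
    list(list(nt, ox0), "high"),       # 6
    list(list(ox0, oxt), "high"),      # 7
    list(list(nt, oxt), "high"),       # 8
    list(list(nt, ox0, oxt), "high"),  # 9
    list(list(ox20), "high"),          # 10
    list(list(nt, ox20), "high"),      # 11
    list(list(ox20, oxt), "high"),     # 12
    list(list(nt, ox20, oxt), "high")) # 13
  .run_suite(reachable, ctx, rows)
}

#' Invariant suite for the LH-GABAergic paradox analysis
#'
#' Eight implications evaluated in the context MCH, LHGal and NT fully
#' active: antecedents are conditions on OX and OXT (high = more than 30
#' percent above baseline, = 0, or none); consequents are FI = high (rows
#' 1-4) or FI = low (rows 5-8).  Under a valid parameterization high food
#' intake is forced exactly by OX high with OXT silent (row 4), and low
#' food intake by OX silent with OXT high (row 8).
#'
#' @inheritParams run_table3_suite
#' @return data.frame as in [run_table3_suite()].
#' @export
run_table4_suite <- function(reachable) {
  ctx <- list(prop_fully_active("MCH"), prop_fully_active("LHGal"),
              prop_fully_active("NT"))
  nc <- prop_nc()
  oxh <- prop_high("OX")
  ox0 <- prop_zero("OX")
  oxth <- prop_high("OXT")
  oxt0 <- prop_zero("OXT")
  rows <- list(
    list(list(nc), "high"),          # 1
    list(list(oxt0), "high"),        # 2
    list(list(oxh), "high"),         # 3
    list(list(oxh, oxt0), "high"),   # 4
    list(list(nc), "low"),           # 5
    list(list(ox0), "low"),          # 6
    list(list(oxth), "low"),         # 7
    list(list(ox0, oxth), "low"))    # 8
  .run_suite(reachable, ctx, rows)
}

.run_suite <- function(reachable, ctx, rows) {
  out <- lapply(seq_along(rows), function(i) {
    ante <- rows[[i]][[1]]
    cons <- prop_fi_class(rows[[i]][[2]])
    r <- check_invariant(reachable, ctx, ante, cons)
    data.frame(
      row = i,
      antecedent = paste(vapply(ante, `[[`, "", "label"), collapse = " and "),
      consequent = cons$label,
      holds = r$holds, vacuous = r$vacuous,
      witness = r$witness,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
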