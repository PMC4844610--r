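# Parameter vectors are plain named numeric vectors over param_names(spec):
# receptor strengths (nonnegative) first, unit biases last.

#' Build a parameter vector for a network
#'
#' @param spec a `network_spec`.
#' @param values numeric; either a single value recycled over all
#'   parameters, or a full vector (named vectors are matched by name).
#' @return named numeric vector over [param_names()].
#' @export
make_params <- function(spec, values = 0) {
  pn <- param_names(spec)
  if (length(values) == 1L && is.null(names(values))) {
    out <- rep(as.numeric(values), length(pn))
    names(out) <- pn
    return(out)
  }
  if (!is.null(names(values))) {
    if (!setequal(names(values), pn)) {
      stop("parameter names do not match the spec (",
           length(setdiff(pn, names(values))), " missing)")
    }
    return(as.numeric(values[pn]) |> setNames(pn))
  }
  if (length(values) != length(pn)) stop("wrong parameter vector length")
  setNames(as.numeric(values), pn)
}

.check_params <- function(spec, params) {
  pn <- param_names(spec)
  if (is.null(names(params)) || !setequal(names(params), pn)) {
    stop("params must be named over param_names(spec)")
  }
  params <- params[pn]
  ns <- nrow(spec$receptors)
  if (any(params[seq_len(ns)] < 0)) stop("receptor strengths must be nonnegative")
  params
}

#' Euclidean distance of parameter vectors from the zero vector
#'
#' The ordering key used to arrange archived zero-error solutions.
#'
#' @param params a named parameter vector, or a matrix / data.frame with one
#'   vector per row.
#' @return numeric distance(s).
#' @export
param_distance <- function(params) {
  if (is.null(dim(params))) return(sqrt(sum(params^2)))
  sqrt(rowSums(as.matrix(params)^2))
}

#' Read and write parameter vectors
#'
#' Flat `name,value` CSV (or a JSON object name -> value).  `read_params`
#' also accepts a supplementary-table-shaped CSV with columns
#' `unit,receptor,value`, where `receptor` is a receptor abbreviation or
#' `"Bias"`.
#'
#' @param spec a `network_spec` used to check completeness.
#' @param path file path; format chosen by extension (`.json` vs `.csv`).
#' @param params named parameter vector.
#' @return `read_params`: a named parameter vector; `write_params`: `path`,
#'   invisibly.
#' @export
read_params <- function(spec, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
    return(make_params(spec, v))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("unit", "receptor", "value") %in% names(df))) {
    v <- setNames(df$value, paste(df$unit, df$receptor, sep = "."))
  } else if (all(c("name", "value") %in% names(df))) {
    v <- setNames(df$value, df$name)
  } else {
    stop("unrecognized parameter file layout: ", path)
  }
  make_params(spec, v)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(params), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    write.csv(data.frame(name = names(params), value = unname(params)),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Random parameter vector within bounds
#'
#' Strengths are drawn uniformly in `[0, strength_max]`, biases in
#' `[-bias_max, bias_max]`.  Used to seed the genetic algorithm.
#'
#' @param spec a `network_spec`.
#' @param strength_max,bias_max bounds (defaults 5).
#' @return named parameter vector.
#' @export
random_params <- function(spec, strength_max = 5, bias_max = 5) {
  pn <- param_names(spec)
  ns <- nrow(spec$receptors)
  v <- c(runif(ns, 0, strength_max),
         runif(length(pn) - ns, -bias_max, bias_max))
  setNames(v, pn)
}
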