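#' Load a survey instrument definition
#'
#' An instrument is an ordered hierarchy of dimensions, each holding an
#' ordered list of criteria (items).  The order is significant: it defines
#' the adjacent-pair comparison chains used for weight elicitation, i.e.
#' dimension d with k criteria is judged through the k-1 pairs
#' (1,2), (2,3), ..., (k-1,k), and the dimensions themselves through one
#' chain over their own order.
#'
#' The file format is YAML (JSON, being a YAML subset, also parses): a
#' top-level `name` and `dimensions`, each dimension with `id`, `label` and
#' `criteria`, each criterion with `id`, `label` and an optional
#' `reverse_worded` flag (default `FALSE`) marking negatively worded items.
#'
#' @param path path to a YAML/JSON instrument file.
#' @return An object of class `instrument`: a list with `name` and
#'   `dimensions`; each dimension is a list with `id`, `label`, `criteria`.
#' @seealso [load_hhnjs()] for the bundled 30-item HHNJS instrument.
#' @export
load_instrument <- function(path) {
  if (!file.exists(path)) stop_input("instrument file not found: ", path)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_input("instrument file failed to parse: ", conditionMessage(e))
  )
  as_instrument(raw)
}

#' Load the bundled HHNJS instrument
#'
#' The Home Healthcare Nurse Job Satisfaction Scale: 30 items in eight
#' dimensions (relationship with patients, peers, physicians and the
#' organization; professional pride; salary and benefit; autonomy and
#' control; stress and workload), each item rated on a 5-point Likert scale.
#'
#' @return An `instrument` with 8 dimensions and 30 criteria.
#' @export
load_hhnjs <- function() {
  load_instrument(system.file("extdata", "hhnjs.yaml", package = "cfpripa", mustWork = TRUE))
}

#' Construct and validate an instrument from a plain list
#'
#' @param x list with `name` and `dimensions` as described in
#'   [load_instrument()].
#' @return validated `instrument` object.
#' @export
as_instrument <- function(x) {
  if (!is.list(x)) stop_input("instrument: expected a list")
  name <- x$name
  if (is.null(name) || !is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("instrument: field 'name' must be a non-empty string")
  }
  dims <- x$dimensions
  if (is.null(dims) || !is.list(dims) || length(dims) == 0L) {
    stop_input("instrument: field 'dimensions' must be a non-empty list")
  }
  dims <- lapply(seq_along(dims), function(i) {
    d <- dims[[i]]
    if (is.null(d$id) || !nzchar(d$id %||% "")) {
      stop_input("instrument: dimension ", i, " is missing field 'id'")
    }
    if (is.null(d$criteria) || length(d$criteria) == 0L) {
      stop_input("instrument: dimension '", d$id, "' has no criteria")
    }
    crit <- lapply(seq_along(d$criteria), function(j) {
      cr <- d$criteria[[j]]
      if (is.null(cr$id) || !nzchar(cr$id %||% "")) {
        stop_input("instrument: dimension '", d$id, "' criterion ", j,
                   " is missing field 'id'")
      }
      list(id = as.character(cr$id),
           label = as.character(cr$label %||% cr$id),
           reverse_worded = isTRUE(cr$reverse_worded))
    })
    list(id = as.character(d$id), label = as.character(d$label %||% d$id),
         criteria = crit)
  })
  ids <- c(vapply(dims, `[[`, "", "id"),
           unlist(lapply(dims, function(d) vapply(d$criteria, `[[`, "", "id"))))
  if (anyDuplicated(ids)) {
    stop_input("instrument: duplicate id(s): ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(name = name, dimensions = dims), class = "instrument")
}

#' Serialize an instrument back to YAML
#'
#' Writing then re-loading an instrument reproduces it field for field.
#'
#' @param instrument an `instrument`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "instrument"))
  yaml::write_yaml(unclass(instrument), path)
  invisible(path)
}

#' @export
print.instrument <- function(x, ...) {
  cat("<instrument> ", x$name, "\n", sep = "")
  cat("  ", length(x$dimensions), " dimensions, ",
      length(criterion_ids(x)), " criteria\n", sep = "")
  for (d in x$dimensions) {
    cat("  ", d$id, " (", length(d$criteria), " items): ", d$label, "\n", sep = "")
  }
  invisible(x)
}

#' Instrument accessors
#'
#' `dimension_ids()` and `criterion_ids()` return ids in instrument
#' (elicitation-chain) order; `criterion_ids()` optionally restricts to one
#' dimension.  `reverse_worded_ids()` returns the ids of negatively worded
#' items.  `group_ids()` returns the id of every comparison group: `"DIMS"`
#' for the chain over dimensions, then one group per dimension.
#'
#' @param instrument an `instrument`.
#' @param dimension optional dimension id.
#' @return character vector of ids.
#' @export
dimension_ids <- function(instrument) {
  vapply(instrument$dimensions, `[[`, "", "id")
}

#' @rdname dimension_ids
#' @export
criterion_ids <- function(instrument, dimension = NULL) {
  dims <- instrument$dimensions
  if (!is.null(dimension)) {
    dims <- dims[dimension_ids(instrument) == dimension]
    if (length(dims) == 0L) stop_input("unknown dimension id: ", dimension)
  }
  unlist(lapply(dims, function(d) vapply(d$criteria, `[[`, "", "id")))
}

#' @rdname dimension_ids
#' @export
reverse_worded_ids <- function(instrument) {
  unlist(lapply(instrument$dimensions, function(d) {
    ids <- vapply(d$criteria, `[[`, "", "id")
    ids[vapply(d$criteria, `[[`, NA, "reverse_worded")]
  }))
}

#' @rdname dimension_ids
#' @export
group_ids <- function(instrument) c("DIMS", dimension_ids(instrument))

# ordered member ids of one comparison group
group_members <- function(instrument, group_id) {
  if (identical(group_id, "DIMS")) dimension_ids(instrument)
  else criterion_ids(instrument, dimension = group_id)
}
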