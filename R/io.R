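#' Read and write outcome tables
#'
#' Outcome tables are CSVs with one row per subject and columns
#' `subject_id`, `y`, and `z_<region_id>` with values in `{-1, +1}`
#' (`y` empty for unlabeled subjects).
#'
#' @param outcomes Outcome tibble.
#' @param path CSV path.
#' @return `read_outcomes()` returns the tibble; `write_outcomes()` returns
#'   `path` invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}

#' @rdname write_outcomes
#' @export
read_outcomes <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$subject_id <- as.character(out$subject_id)
  for (cn in grep("^z_", names(out), value = TRUE)) {
    out[[cn]] <- as.integer(out[[cn]])
  }
  if ("y" %in% names(out)) out$y <- as.integer(out$y)
  outcome_matrix(out)  # validates +/-1
  out
}

#' Serialize a fitted network to JSON
#'
#' Nodes, directed augmenting edges, the class prior and every conditional
#' table (`p(z = +1 | config)`, row-major over parent configurations with
#' the class bit most significant) are written with full double precision so
#' the model round-trips exactly.
#'
#' @param model An `sc_bn`.
#' @param path JSON path.
#' @return `path` / the model, invisibly.
#' @export
write_network_json <- function(model, path) {
  st <- model$structure
  obj <- list(
    region_ids = st$region_ids,
    max_parents = st$max_parents,
    edges = tidy(st),
    prior_pos = model$prior_pos,
    smoothing = model$smoothing,
    n = model$n,
    cpts = lapply(seq_along(model$cpts), function(j) {
      cp <- model$cpts[[j]]
      list(region_id = st$region_ids[j],
           parents = st$region_ids[cp$parents],
           p_pos = cp$p1)
    })
  )
  # 17 significant digits guarantee exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  regs <- vapply(obj$region_ids, as.integer, integer(1))
  edges <- if (length(obj$edges) > 0) {
    data.frame(from = vapply(obj$edges, function(e) as.integer(e$from), integer(1)),
               to = vapply(obj$edges, function(e) as.integer(e$to), integer(1)))
  }
  st <- bn_structure(regs, edges = edges, max_parents = obj$max_parents)
  cpt_ids <- vapply(obj$cpts, function(cp) as.integer(cp$region_id), integer(1))
  p1 <- lapply(obj$cpts[match(regs, cpt_ids)], function(cp) {
    vapply(cp$p_pos, as.numeric, numeric(1))
  })
  model <- bn_model(st, obj$prior_pos, p1)
  model$smoothing <- obj$smoothing %||% NA_real_
  model$n <- obj$n %||% NA_integer_
  model
}

#' Export a structure as Graphviz DOT
#'
#' @param structure A [bn_structure()].
#' @param path Optional file path; omitted, the DOT source is returned.
#' @param region_names Optional named vector (region id -> display name).
#' @return The DOT source string, invisibly if written to a file.
#' @export
to_dot <- function(structure, path = NULL, region_names = NULL) {
  nm <- function(id) {
    lbl <- if (!is.null(region_names) && as.character(id) %in% names(region_names))
      region_names[[as.character(id)]] else paste0("z_", id)
    lbl
  }
  lines <- c("digraph scbnet {", "  y [shape=doublecircle];")
  for (id in structure$region_ids) {
    lines <- c(lines, sprintf("  \"%s\";", nm(id)),
               sprintf("  y -> \"%s\";", nm(id)))
  }
  e <- tidy(structure)
  for (r in seq_len(nrow(e))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", nm(e$from[r]), nm(e$to[r])))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}

#' Write the structure-search trace
#'
#' @param search An `sc_bn_search`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(search, path) {
  readr::write_csv(search$trace, path)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with any of: `regions`, `tissue`, `kind`, `cost`, `smoothing`,
#' `n_iter`, `burn_in`, `max_parents`, `validation_fraction`, `seed`, plus
#' phantom settings under `phantom:`. Missing entries take the package
#' defaults.
#'
#' @param path YAML path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads bare keys y/n as booleans; restore them as field names
  fix_names <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) {
      nm[nm == "TRUE"] <- "y"
      nm[nm == "FALSE"] <- "n"
      names(x) <- nm
    }
    lapply(x, fix_names)
  }
  cfg <- fix_names(cfg)
  if (!is.null(cfg$validation_fraction)) {
    stopifnot(cfg$validation_fraction > 0, cfg$validation_fraction < 1)
  }
  for (fld in c("cost", "smoothing", "n_iter", "burn_in", "max_parents")) {
    if (!is.null(cfg[[fld]])) stopifnot(cfg[[fld]] >= 0)
  }
  cfg
}

#' Write evaluation reports as JSON
#'
#' @param reports Report tibble (e.g. `tidy()` of a pipeline result).
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_reports_json <- function(reports, path) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
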