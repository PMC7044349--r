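ounet_version <- function() {
  as.character(utils::packageVersion("ounet"))
}

provenance_lines <- function(seed = NULL, config = NULL) {
  cfg <- if (is.null(config)) "" else
    paste0(" config=", jsonlite::toJSON(config, auto_unbox = TRUE))
  paste0("# ounet ", ounet_version(),
         if (!is.null(seed)) paste0(" seed=", seed) else "", cfg)
}

#' Write / read a trajectory CSV
#'
#' Plain-text format: optional `#` provenance comment lines, then a header
#' `tick,v_<name>...,i_<name>...`, one row per tick, values to 6 decimal
#' places, mask entries 0/1, tick 0-based. Round-trips losslessly at that
#' precision.
#'
#' @param traj An `ou_trajectory`.
#' @param path File path.
#' @param seed,config Optional provenance recorded as comment lines.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns an `ou_trajectory`.
#' @export
write_trajectory <- function(traj, path, seed = NULL, config = NULL) {
  vars <- traj$variables
  header <- paste(c("tick", paste0("v_", vars), paste0("i_", vars)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(traj$values)), function(t) {
    paste(c(t - 1L, sprintf("%.6f", traj$values[t, ]), traj$mask[t, ]),
          collapse = ",")
  }, "")
  writeLines(c(provenance_lines(seed, config), header, rows), path)
  invisible(path)
}

#' @param bounds Bounds the values must respect. Default `c(-100, 100)`.
#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, bounds = c(-100, 100)) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) stop_contract("no header found in ", path)
  df <- utils::read.csv(text = lines[body], check.names = FALSE)
  cn <- names(df)
  if (cn[1] != "tick") stop_contract("first column must be 'tick' in ", path)
  vcols <- grep("^v_", cn, value = TRUE)
  icols <- grep("^i_", cn, value = TRUE)
  vars <- sub("^v_", "", vcols)
  missing_i <- setdiff(paste0("i_", vars), icols)
  if (length(missing_i) || !length(vcols)) {
    stop_contract("missing mask column(s): ",
                  paste(missing_i, collapse = ", "), " in ", path)
  }
  off <- body[1] + 1L # first data line number in the file
  for (col in c(vcols, icols)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[col]])))))
    if (length(bad)) {
      stop_contract("non-numeric value in column ", col, " at line ",
                    off + bad[1] - 1L, " of ", path)
    }
  }
  values <- as.matrix(df[vcols]); colnames(values) <- vars
  mask <- as.matrix(df[paste0("i_", vars)]); colnames(mask) <- vars
  oob <- which(values < bounds[1] | values > bounds[2], arr.ind = TRUE)
  if (nrow(oob)) {
    stop_contract("value out of bounds at line ", off + oob[1, 1] - 1L,
                  " of ", path)
  }
  if (!all(mask %in% c(0, 1))) stop_contract("mask entries must be 0/1 in ", path)
  trajectory(values, mask, vars, bounds)
}

#' Write / read a causal graph JSON
#'
#' Format: `{"variables": [...], "edges": {"X->Y": 1, ...}}` with every
#' ordered pair present and labels in `{-1, 0, 1}`; an optional `"magnitude"`
#' field carries the strength scale.
#'
#' @param graph A `causal_graph`.
#' @param path File path.
#' @param magnitude Optional strength magnitude stored alongside the labels.
#' @return `write_graph()` returns `path` invisibly; `read_graph()` returns a
#'   `causal_graph` (with attribute `magnitude` if present in the file).
#' @export
write_graph <- function(graph, path, magnitude = NULL) {
  obj <- list(variables = graph_variables(graph),
              edges = as.list(setNames(as.integer(graph), names(graph))))
  if (!is.null(magnitude)) obj$magnitude <- magnitude
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  vars <- unlist(obj$variables)
  edges <- unlist(obj$edges)
  pairs <- graph_pairs(vars)
  self <- grep("^([^>]+)->\\1$", names(edges))
  if (length(self)) stop_contract("self-edge ", names(edges)[self[1]], " in ", path)
  missing <- setdiff(pairs, names(edges))
  if (length(missing)) {
    stop_contract("missing pair(s): ", paste(missing, collapse = ", "),
                  " in ", path)
  }
  g <- causal_graph(vars, edges)
  if (!is.null(obj$magnitude)) attr(g, "magnitude") <- obj$magnitude
  g
}

#' Write / read a judgment dataset
#'
#' JSON-lines with one trial record per line:
#' `{"participant": id, "trial": k, "true_graph": {...}, "trajectory_file":
#' path, "judgment": {"X->Y": 1, ...}}`; trajectory CSVs live under
#' `trajectories/` next to the JSON-lines file.
#'
#' @param records List of trial records (as produced by [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns the JSON-lines path invisibly;
#'   `read_dataset()` returns the list of records.
#' @export
write_dataset <- function(records, dir) {
  dir.create(file.path(dir, "trajectories"), recursive = TRUE,
             showWarnings = FALSE)
  lines <- character(length(records))
  for (k in seq_along(records)) {
    r <- records[[k]]
    rel <- file.path("trajectories",
                     sprintf("p%03d_t%03d.csv", as.integer(r$participant),
                             as.integer(r$trial)))
    write_trajectory(r$trajectory, file.path(dir, rel))
    lines[k] <- jsonlite::toJSON(list(
      participant = r$participant, trial = r$trial,
      network = r$network %||% NA,
      true_graph = list(variables = graph_variables(r$graph),
                        edges = as.list(setNames(as.integer(r$graph),
                                                 names(r$graph)))),
      trajectory_file = rel,
      judgment = as.list(setNames(as.integer(r$judgment), names(r$judgment)))
    ), auto_unbox = TRUE, null = "null")
  }
  path <- file.path(dir, "dataset.jsonl")
  writeLines(lines, path)
  invisible(path)
}

#' @param path Path to a `dataset.jsonl` file.
#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dir <- dirname(path)
  lapply(readLines(path), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    vars <- unlist(obj$true_graph$variables)
    list(
      participant = obj$participant,
      trial = obj$trial,
      network = obj$network,
      graph = causal_graph(vars, unlist(obj$true_graph$edges)),
      trajectory = read_trajectory(file.path(dir, obj$trajectory_file)),
      judgment = causal_graph(vars, unlist(obj$judgment))
    )
  })
}

#' Write a graph posterior as TSV
#'
#' Columns: `graph_index` (1-based canonical index), `edges` (label string
#' `"X->Y:+1;..."`), `log_marginal`, `posterior`, sorted by canonical order.
#'
#' @param post A `graph_posterior`.
#' @param path File path.
#' @param seed,config Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_posterior_tsv <- function(post, path, seed = NULL, config = NULL) {
  labs <- enumerate_graph_labels(post$variables)
  edge_str <- apply(labs, 1L, function(r) {
    paste(paste0(colnames(labs), ":", ifelse(r > 0, "+1", r)), collapse = ";")
  })
  lines <- c(provenance_lines(seed, config),
             "graph_index\tedges\tlog_marginal\tposterior",
             sprintf("%d\t%s\t%.8g\t%.8g", seq_len(nrow(labs)), edge_str,
                     post$log_marginal, post$posterior))
  writeLines(lines, path)
  invisible(path)
}

#' Write an edge posterior as JSON
#'
#' One object per ordered pair: `{"X->Y": {"inverse": p, "none": p,
#' "regular": p}, ...}`.
#'
#' @param post An `edge_posterior`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_edge_posterior_json <- function(post, path) {
  obj <- lapply(seq_len(nrow(post)), function(k) {
    as.list(setNames(as.numeric(post[k, ]), colnames(post)))
  })
  names(obj) <- rownames(post)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
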