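#' Ordered variable pairs of a causal graph
#'
#' Every ordered pair (source, target) with source != target, in the canonical
#' lexicographic order by (source index, target index). This order indexes
#' edge labels everywhere in the package (enumeration, serialisation,
#' posteriors, judgments).
#'
#' @param variables Character vector of unique variable names.
#' @return Character vector of pair keys `"SRC->TGT"`.
#' @examples
#' graph_pairs(c("X", "Y", "Z"))
#' @export
graph_pairs <- function(variables) {
  n <- length(variables)
  if (n < 1L || anyDuplicated(variables)) {
    stop_contract("variables must be a non-empty vector of unique names")
  }
  out <- character(0)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j) out <- c(out, paste0(variables[j], "->", variables[i]))
    }
  }
  out
}

pair_matrix <- function(variables) {
  # integer matrix with columns (source, target), rows in canonical order
  n <- length(variables)
  src <- rep(seq_len(n), each = n)
  tgt <- rep(seq_len(n), times = n)
  keep <- src != tgt
  cbind(source = src[keep], target = tgt[keep])
}

#' Construct a causal graph over named variables
#'
#' A causal graph assigns every ordered pair of distinct variables one of three
#' edge labels: `-1` (inverse connection, negative causal strength), `0` (no
#' connection) or `+1` (regular connection, positive strength). Self edges are
#' not part of the hypothesis space.
#'
#' @param variables Character vector of unique variable names.
#' @param labels Either a named integer vector over pair keys (see
#'   [graph_pairs()]); or an unnamed vector in canonical pair order; or `NULL`
#'   for the empty (all-`none`) graph. Values must be in `{-1, 0, 1}`.
#' @return An object of class `causal_graph`: a named integer label vector
#'   with attribute `variables`.
#' @examples
#' chain <- causal_graph(c("X", "Y", "Z"), c("X->Y" = 1, "Y->Z" = 1))
#' @export
causal_graph <- function(variables, labels = NULL) {
  variables <- default_variables(variables)
  pairs <- graph_pairs(variables)
  lab <- setNames(integer(length(pairs)), pairs)
  if (!is.null(labels)) {
    if (is.null(names(labels))) {
      if (length(labels) != length(pairs)) {
        stop_contract("unnamed labels must cover all ", length(pairs), " ordered pairs")
      }
      lab[] <- as.integer(labels)
    } else {
      bad <- setdiff(names(labels), pairs)
      if (length(bad)) {
        stop_contract("unknown or self-edge pair(s): ", paste(bad, collapse = ", "))
      }
      lab[names(labels)] <- as.integer(labels)
    }
  }
  if (!all(lab %in% c(-1L, 0L, 1L))) {
    stop_contract("edge labels must be -1 (inverse), 0 (none) or 1 (regular)")
  }
  structure(lab, variables = variables, class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  vars <- attr(x, "variables")
  cat("causal_graph over {", paste(vars, collapse = ", "), "}: ",
      sum(x != 0), " link(s)\n", sep = "")
  nz <- x[x != 0]
  if (length(nz)) {
    lbl <- c("inverse", "", "regular")[nz + 2L]
    cat(paste0("  ", names(nz), "  ", ifelse(nz > 0, "+1", "-1"),
               " (", lbl, ")", collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.causal_graph <- function(x, ...) {
  paste(paste0(names(x), ":", ifelse(x > 0, "+1", x)), collapse = ";")
}

graph_variables <- function(graph) attr(graph, "variables")

#' Enumerate the graph hypothesis space
#'
#' All `3^(n(n-1))` edge-labelled graphs over `n` variables, in a deterministic
#' canonical order: a ternary counter over the canonical pair order, with the
#' first pair as the most significant digit and labels counted in the order
#' `-1, 0, +1`. Index 0 is therefore the all-inverse graph and the empty graph
#' sits exactly in the middle. For three variables the space contains 729
#' graphs.
#'
#' @param variables Character vector of variable names, or a single integer
#'   `n` (variables are then named `V1..Vn`, or `X,Y,Z` for `n = 3`).
#' @param max_graphs Refuse enumeration beyond this many graphs (guards
#'   against combinatorial blow-up). Default 60000 admits up to `n = 3`.
#' @return List of `causal_graph` objects of length `3^(n(n-1))`.
#' @examples
#' length(enumerate_graphs(3)) # 729
#' @export
enumerate_graphs <- function(variables, max_graphs = 60000) {
  variables <- default_variables(variables)
  labs <- enumerate_graph_labels(variables, max_graphs = max_graphs)
  lapply(seq_len(nrow(labs)), function(k) {
    structure(setNames(labs[k, ], colnames(labs)),
              variables = variables, class = "causal_graph")
  })
}

default_variables <- function(variables) {
  if (is.numeric(variables) && length(variables) == 1L) {
    n <- as.integer(variables)
    if (n < 1L) stop_contract("need at least one variable")
    variables <- if (n == 3L) c("X", "Y", "Z") else paste0("V", seq_len(n))
  }
  variables
}

# Compact enumeration: G x n_pairs integer label matrix in canonical order.
enumerate_graph_labels <- function(variables, max_graphs = 60000) {
  pairs <- graph_pairs(variables)
  m <- length(pairs)
  total <- 3^m
  if (total > max_graphs) {
    stop_contract("hypothesis space has ", total, " graphs, above the cap of ",
                  max_graphs, " (combinatorial blow-up)")
  }
  g <- as.integer(total)
  labs <- matrix(0L, nrow = g, ncol = m, dimnames = list(NULL, pairs))
  idx <- 0:(g - 1L)
  for (p in seq_len(m)) {
    digit <- (idx %/% 3^(m - p)) %% 3
    labs[, p] <- as.integer(digit) - 1L
  }
  labs
}

#' Canonical index of a graph in the enumeration order
#'
#' @param graph A `causal_graph` (or named label vector over canonical pairs).
#' @return 1-based index into [enumerate_graphs()] output.
#' @export
graph_index <- function(graph) {
  lab <- as.integer(graph) + 1L # digits 0..2
  m <- length(lab)
  as.integer(sum(lab * 3^(m - seq_len(m)))) + 1L
}

#' Convert a labelled graph to a strength matrix
#'
#' @param graph A `causal_graph`.
#' @param magnitude Positive causal strength applied to every link;
#'   `theta[j, i] = label(j->i) * magnitude`.
#' @return Square numeric matrix (rows = sources, columns = targets) with a
#'   zero diagonal, dimnames set to the variable names.
#' @examples
#' graph_to_theta(causal_graph(c("X", "Y"), c("X->Y" = -1)), magnitude = 1)
#' @export
graph_to_theta <- function(graph, magnitude = 1) {
  if (!is.numeric(magnitude) || magnitude <= 0) {
    stop_contract("magnitude must be a positive number")
  }
  vars <- graph_variables(graph)
  n <- length(vars)
  theta <- matrix(0, n, n, dimnames = list(vars, vars))
  pm <- pair_matrix(vars)
  for (k in seq_len(nrow(pm))) {
    theta[pm[k, 1L], pm[k, 2L]] <- as.numeric(graph[k]) * magnitude
  }
  theta
}

# labels of edges into variable i (in order of the other variables)
parents_of <- function(graph, i) {
  vars <- graph_variables(graph)
  others <- setdiff(seq_along(vars), i)
  setNames(as.integer(graph[paste0(vars[others], "->", vars[i])]), vars[others])
}
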