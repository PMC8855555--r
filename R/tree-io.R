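# Tree serialisation (JSON, DOT) and printing.

condition_text <- function(node, side, unit = c("g_week", "g_day")) {
  unit <- match.arg(unit)
  if (node$kind == "subset") {
    cats <- if (side == "left") node$left_subset else NULL
    verb <- if (side == "left") "category in" else "category not in"
    set <- if (side == "left") node$left_subset else node$left_subset
    return(sprintf("%s {%s}", verb, paste(set, collapse = ", ")))
  }
  rel <- if (side == "left") "<=" else ">"
  if (node$attribute == "bw") {
    sprintf("body weight %s %.4g kg", rel, node$threshold)
  } else if (unit == "g_week") {
    sprintf("intake %s %.4g g/week", rel, node$threshold * 7)
  } else {
    sprintf("intake %s %.4g g/day", rel, node$threshold)
  }
}

#' @export
print.hazard_tree <- function(x, ...) {
  metal <- attr(x, "metal")
  cat("Hazard decision tree",
      if (!is.null(metal)) paste0("(", metal, ")"), "\n")
  print_node(x, indent = "")
  invisible(x)
}

print_node <- function(node, indent) {
  if (node$type == "leaf") {
    if (isTRUE(node$empty)) {
      cat(indent, "* leaf: no evaluation cases\n", sep = "")
    } else {
      cat(sprintf("%s* leaf: n=%d, hazardous=%d, risk=%s%%\n",
                  indent, node$n, node$k_hazard,
                  formatC(node$risk_pct, format = "fg")))
    }
    return(invisible())
  }
  cat(sprintf("%s[%s] gain ratio %.4f (n=%d)\n", indent,
              condition_text(node, "left"), node$gain_ratio, node$n))
  print_node(node$left, paste0(indent, "  "))
  cat(sprintf("%s[%s]\n", indent, condition_text(node, "right")))
  print_node(node$right, paste0(indent, "  "))
}

node_to_list <- function(node) {
  if (node$type == "leaf") {
    out <- list(type = "leaf", depth = node$depth, n = node$n,
                k_hazard = node$k_hazard, risk_pct = node$risk_pct,
                majority = node$majority)
    if (isTRUE(node$empty)) out$empty <- TRUE
    return(out)
  }
  out <- list(type = "internal", depth = node$depth, n = node$n,
              attribute = node$attribute, kind = node$kind)
  if (node$kind == "threshold") {
    out$threshold <- node$threshold
  } else {
    out$left_subset <- as.list(node$left_subset)
  }
  out$gain <- node$gain
  out$split_info <- node$split_info
  out$gain_ratio <- node$gain_ratio
  out$left <- node_to_list(node$left)
  out$right <- node_to_list(node$right)
  out
}

#' Serialise a hazard tree to JSON
#'
#' Stable key order (type, depth, counts, split, children) so that repeated
#' runs diff cleanly. The inverse is [tree_from_json()].
#'
#' @param tree A `hazard_tree`.
#' @param path Optional file path; when `NULL` the JSON text is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
tree_to_json <- function(tree, path = NULL) {
  if (!inherits(tree, "hazard_tree")) {
    stop_field("tree", "must be a hazard_tree")
  }
  payload <- list(
    metal = attr(tree, "metal"),
    categories = as.list(attr(tree, "categories")),
    root = node_to_list(tree)
  )
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                          digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

list_to_node <- function(x) {
  if (x$type == "leaf") {
    out <- list(type = "leaf", depth = as.integer(x$depth),
                n = as.integer(x$n), k_hazard = as.integer(x$k_hazard),
                risk_pct = if (is.null(x$risk_pct)) NA_real_
                           else as.numeric(x$risk_pct),
                majority = if (is.null(x$majority)) NA else x$majority)
    if (isTRUE(x$empty)) out$empty <- TRUE
    return(out)
  }
  out <- list(type = "internal", depth = as.integer(x$depth),
              n = as.integer(x$n), attribute = x$attribute, kind = x$kind)
  if (x$kind == "threshold") {
    out$threshold <- as.numeric(x$threshold)
    out$left_subset <- NULL
  } else {
    out$left_subset <- as.character(unlist(x$left_subset))
  }
  out$gain <- as.numeric(x$gain)
  out$split_info <- as.numeric(x$split_info)
  out$gain_ratio <- as.numeric(x$gain_ratio)
  out$left <- list_to_node(x$left)
  out$right <- list_to_node(x$right)
  out
}

#' Read a hazard tree from JSON
#'
#' @param path File path or JSON string produced by [tree_to_json()].
#' @return A `hazard_tree`.
#' @export
tree_from_json <- function(path) {
  raw <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    jsonlite::parse_json(path, simplifyVector = FALSE)
  }
  structure(list_to_node(raw$root),
            class = "hazard_tree",
            metal = raw$metal,
            categories = as.character(unlist(raw$categories)),
            config = NULL)
}

#' Export a hazard tree in Graphviz DOT format
#'
#' Internal nodes are labelled with their split condition; leaves with
#' their counts and risk percentage. Left edges carry the "yes" answer to
#' the condition (`<=` threshold / category in subset).
#'
#' @param tree A `hazard_tree`.
#' @param path Optional file path; when `NULL` the DOT text is returned.
#' @param intake_unit `"g_week"` (default, mirrors the report sentences) or
#'   `"g_day"` for intake thresholds.
#' @return The DOT string (invisibly when written to `path`).
#' @export
tree_to_dot <- function(tree, path = NULL, intake_unit = c("g_week", "g_day")) {
  intake_unit <- match.arg(intake_unit)
  if (!inherits(tree, "hazard_tree")) {
    stop_field("tree", "must be a hazard_tree")
  }
  lines <- c("digraph hazard_tree {", "  node [shape=box];")
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  emit <- function(node) {
    counter$i <- counter$i + 1L
    id <- sprintf("n%d", counter$i)
    if (node$type == "leaf") {
      label <- if (isTRUE(node$empty)) {
        "no cases"
      } else {
        sprintf("n=%d\\nhazardous=%d\\nrisk=%s%%", node$n, node$k_hazard,
                formatC(node$risk_pct, format = "fg"))
      }
      lines <<- c(lines, sprintf("  %s [label=\"%s\", shape=ellipse];",
                                 id, label))
      return(id)
    }
    cond <- gsub("\"", "'", condition_text(node, "left", intake_unit))
    lines <<- c(lines, sprintf("  %s [label=\"%s\"];", id, cond))
    left_id <- emit(node$left)
    right_id <- emit(node$right)
    lines <<- c(lines,
                sprintf("  %s -> %s [label=\"yes\"];", id, left_id),
                sprintf("  %s -> %s [label=\"no\"];", id, right_id))
    id
  }
  emit(tree)
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
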