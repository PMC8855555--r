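# Hazard decision tree: candidate enumeration, growth, routing, two-stage
# leaf evaluation.

#' Tree-growth configuration
#'
#' @param max_depth Maximum tree depth (root = depth 0). The study's trees
#'   are shallow; the default of 3 matches that scale.
#' @param min_leaf Minimum leaf size; a node with fewer than `2 * min_leaf`
#'   instances is not split.
#' @param min_gain_ratio Smallest criterion value worth splitting on.
#' @param attribute_order Fixed attribute order used to break criterion
#'   ties deterministically.
#' @param criterion `"gain_ratio"` (default) or plain `"gain"`.
#' @param seed Integer seed recorded with the config (the learner itself is
#'   deterministic; the seed travels with the config for provenance).
#' @return A `tree_config` object.
#' @export
tree_config <- function(max_depth = 3L,
                        min_leaf = 5L,
                        min_gain_ratio = 1e-4,
                        attribute_order = c("category", "bw", "intake"),
                        criterion = c("gain_ratio", "gain"),
                        seed = 1L) {
  criterion <- match.arg(criterion)
  check_scalar_number(max_depth, "max_depth", nonneg = TRUE)
  check_scalar_number(min_leaf, "min_leaf", positive = TRUE)
  check_scalar_number(min_gain_ratio, "min_gain_ratio", nonneg = TRUE)
  if (!setequal(attribute_order, c("category", "bw", "intake"))) {
    stop_field("attribute_order",
               "must be a permutation of category, bw, intake")
  }
  structure(
    list(max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
         min_gain_ratio = min_gain_ratio, attribute_order = attribute_order,
         criterion = criterion, seed = as.integer(seed)),
    class = "tree_config"
  )
}

#' Leaf risk percentage
#'
#' `100 * k / n` rounded half-up to one decimal, the statistic printed at
#' every leaf: the share of subjects routed there whose hazard quotient
#' exceeds 1. Integer arithmetic makes the half-up rounding exact.
#'
#' @param k_hazard Number of hazardous instances at the leaf (0 <= k <= n).
#' @param n Number of instances at the leaf (>= 1).
#' @return Percentage with one decimal. Vectorised.
#' @examples
#' leaf_risk(90, 212)   # 42.5
#' leaf_risk(0, 301)    # 0
#' @export
leaf_risk <- function(k_hazard, n) {
  if (any(!is.finite(n)) || any(n < 1) || any(n != as.integer(n))) {
    stop_field("n", "must be whole numbers >= 1")
  }
  if (any(!is.finite(k_hazard)) || any(k_hazard < 0) || any(k_hazard > n) ||
      any(k_hazard != as.integer(k_hazard))) {
    stop_field("k_hazard", "must be whole numbers in [0, n]")
  }
  # half-up rounding of 100k/n to 1 decimal: floor(1000k/n + 1/2) / 10,
  # done exactly as (2000k + n) %/% (2n) / 10
  ((2000 * as.numeric(k_hazard) + n) %/% (2 * n)) / 10
}

check_instances <- function(instances) {
  need <- c("category", "bw", "intake", "label")
  missing <- setdiff(need, names(instances))
  if (length(missing)) {
    stop_field("instances", paste("missing columns:",
                                  paste(missing, collapse = ", ")))
  }
  if (!is.logical(instances$label)) {
    stop_field("instances", "label must be logical")
  }
  invisible(instances)
}

# vectorised binary entropy from (k, n) count vectors
ventropy <- function(k, n) {
  len <- max(length(k), length(n))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  p <- ifelse(n > 0, k / n, 0)
  t1 <- ifelse(p > 0, -p * log2(p), 0)
  t2 <- ifelse(p < 1, -(1 - p) * log2(1 - p), 0)
  ifelse(n > 0, t1 + t2, 0)
}

#' Enumerate and score all binary split candidates
#'
#' Continuous attributes (`bw`, `intake`) contribute one threshold at each
#' midpoint between consecutive distinct sorted values ("<=" goes left).
#' The categorical attribute contributes every binary partition of the
#' categories present (exhaustive subset enumeration, at most
#' `2^(c-1) - 1 = 63` candidates for 7 categories); the left branch is the
#' subset containing the alphabetically first category, a canonical form
#' that names each partition once. Candidates that fail to divide the data
#' are never produced, so every retained candidate has positive split
#' information. A pure-label (or single-instance) input yields zero
#' candidates, and the caller makes a leaf.
#'
#' @param instances Tibble with columns `category`, `bw`, `intake`,
#'   `label` (logical), e.g. from [build_instances()].
#' @return A tibble of candidates: `attribute`, `kind`, `threshold`,
#'   `left_subset` (list column), `n_left`, `n_right`, `gain`,
#'   `split_info`, `gain_ratio`.
#' @export
enumerate_candidates <- function(instances) {
  check_instances(instances)
  n <- nrow(instances)
  k <- sum(instances$label)
  if (n < 2L || k == 0L || k == n) {
    return(empty_candidates())
  }
  h_parent <- binary_entropy(k, n)
  out <- list(
    subset_candidates(instances$category, instances$label, h_parent),
    threshold_candidates("bw", instances$bw, instances$label, h_parent),
    threshold_candidates("intake", instances$intake, instances$label, h_parent)
  )
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

empty_candidates <- function() {
  tibble::tibble(
    attribute = character(), kind = character(), threshold = numeric(),
    left_subset = list(), n_left = integer(), n_right = integer(),
    gain = numeric(), split_info = numeric(), gain_ratio = numeric()
  )
}

threshold_candidates <- function(attribute, x, label, h_parent) {
  n <- length(x)
  k <- sum(label)
  ord <- order(x)
  xs <- x[ord]
  cumk <- cumsum(label[ord])
  cut <- which(xs[-n] < xs[-1])   # last index of each distinct value
  if (!length(cut)) return(NULL)
  n_left <- cut
  k_left <- cumk[cut]
  gain <- h_parent - (n_left / n) * ventropy(k_left, n_left) -
    ((n - n_left) / n) * ventropy(k - k_left, n - n_left)
  gain <- pmax(gain, 0)
  si <- ventropy(n_left, n)   # branch-size entropy of a binary split
  tibble::tibble(
    attribute = attribute, kind = "threshold",
    threshold = (xs[cut] + xs[cut + 1]) / 2,
    left_subset = rep(list(NULL), length(cut)),
    n_left = as.integer(n_left), n_right = as.integer(n - n_left),
    gain = gain, split_info = si, gain_ratio = gain / si
  )
}

subset_candidates <- function(category, label, h_parent) {
  cats <- sort(unique(category))
  m <- length(cats)
  if (m < 2L) return(NULL)
  n <- length(category)
  k <- sum(label)
  n_c <- vapply(cats, function(cat) sum(category == cat), numeric(1))
  k_c <- vapply(cats, function(cat) sum(label[category == cat]), numeric(1))
  n_sub <- bitwShiftL(1L, m - 1L) - 1L   # partitions, left side holds cats[1]
  subsets <- vector("list", n_sub)
  n_left <- k_left <- numeric(n_sub)
  for (code in seq_len(n_sub)) {
    rest <- which(bitwAnd(bitwShiftR(code - 1L, seq_len(m - 1L) - 1L), 1L) == 1L)
    left <- c(cats[1], cats[-1][rest])
    subsets[[code]] <- left
    idx <- c(1L, rest + 1L)
    n_left[code] <- sum(n_c[idx])
    k_left[code] <- sum(k_c[idx])
  }
  gain <- h_parent - (n_left / n) * ventropy(k_left, n_left) -
    ((n - n_left) / n) * ventropy(k - k_left, n - n_left)
  gain <- pmax(gain, 0)
  si <- ventropy(n_left, n)
  tibble::tibble(
    attribute = "category", kind = "subset",
    threshold = NA_real_, left_subset = subsets,
    n_left = as.integer(n_left), n_right = as.integer(n - n_left),
    gain = gain, split_info = si, gain_ratio = gain / si
  )
}

# deterministic argmax over candidates: criterion value, then the config's
# attribute order, then smaller threshold, then lexicographically smaller
# subset
select_best <- function(cands, config) {
  value <- if (config$criterion == "gain") cands$gain else cands$gain_ratio
  keep <- which(value >= max(value) - 1e-12)
  tie <- cands[keep, , drop = FALSE]
  subset_key <- vapply(tie$left_subset, function(s) {
    if (is.null(s)) "" else paste(s, collapse = ",")
  }, character(1))
  o <- order(match(tie$attribute, config$attribute_order),
             tie$threshold, subset_key, na.last = TRUE)
  tie[o[1], , drop = FALSE]
}

# `split` is either a candidate row (left_subset is a list column) or a
# tree node (left_subset is a character vector)
goes_left <- function(split, category, bw, intake) {
  if (split$kind == "threshold") {
    x <- if (split$attribute == "bw") bw else intake
    x <= split$threshold
  } else {
    subset <- split$left_subset
    if (is.list(subset)) subset <- subset[[1]]
    category %in% subset
  }
}

#' Grow a hazard decision tree
#'
#' Recursive binary splitting by the configured criterion (gain ratio by
#' default). A node becomes a leaf when its labels are pure, when `depth ==
#' max_depth`, when it holds fewer than `2 * min_leaf` instances, or when no
#' candidate reaches `min_gain_ratio`. Leaves store the construction-stage
#' counts `(n, k_hazard)` and the risk percentage [leaf_risk()].
#'
#' @param instances Labelled instance tibble (see [build_instances()]).
#' @param config A [tree_config()].
#' @param metal Optional metal identifier stored on the tree.
#' @return A `hazard_tree` object (nested node lists; see
#'   [tree_to_json()] for the serialised layout).
#' @examples
#' inst <- tibble::tibble(
#'   category = rep(c("shellfish", "algae"), each = 10),
#'   bw = rep(c(50, 70), 10), intake = 5, label = rep(c(50, 70), 10) <= 55)
#' grow_tree(inst, tree_config(min_leaf = 1))
#' @export
grow_tree <- function(instances, config = tree_config(), metal = NULL) {
  check_instances(instances)
  if (nrow(instances) == 0L) {
    stop_field("instances", "must contain at least one instance")
  }
  if (!inherits(config, "tree_config")) {
    stop_field("config", "must be a tree_config object")
  }
  root <- grow_node(instances, config, depth = 0L)
  structure(root,
            class = "hazard_tree",
            metal = metal,
            categories = sort(unique(instances$category)),
            config = config)
}

grow_node <- function(instances, config, depth) {
  n <- nrow(instances)
  k <- sum(instances$label)
  make_leaf <- function() {
    list(type = "leaf", depth = depth, n = n, k_hazard = k,
         risk_pct = leaf_risk(k, n), majority = k * 2 > n)
  }
  if (k == 0L || k == n || depth >= config$max_depth ||
      n < 2L * config$min_leaf) {
    return(make_leaf())
  }
  cands <- enumerate_candidates(instances)
  if (nrow(cands) == 0L) return(make_leaf())
  best <- select_best(cands, config)
  value <- if (config$criterion == "gain") best$gain else best$gain_ratio
  if (value < config$min_gain_ratio) return(make_leaf())
  left_mask <- goes_left(best, instances$category, instances$bw,
                         instances$intake)
  list(
    type = "internal", depth = depth, n = n,
    attribute = best$attribute, kind = best$kind,
    threshold = best$threshold,
    left_subset = best$left_subset[[1]],
    gain = best$gain, split_info = best$split_info,
    gain_ratio = best$gain_ratio,
    left = grow_node(instances[left_mask, , drop = FALSE], config, depth + 1L),
    right = grow_node(instances[!left_mask, , drop = FALSE], config, depth + 1L)
  )
}

#' Route a feature vector to its leaf
#'
#' Deterministic descent from the root: threshold conditions send values
#' less than or equal to the threshold down the left branch; subset
#' conditions send categories in the left subset down the left branch.
#'
#' @param tree A `hazard_tree`.
#' @param features A list or one-row data frame with `category`, `bw`,
#'   `intake`.
#' @return The leaf node (a list with `n`, `k_hazard`, `risk_pct`, ...).
#' @export
route <- function(tree, features) {
  if (!inherits(tree, "hazard_tree")) {
    stop_field("tree", "must be a hazard_tree")
  }
  for (f in c("category", "bw", "intake")) {
    if (is.null(features[[f]]) || is.na(features[[f]])) {
      stop_field("features", paste("missing feature:", f))
    }
  }
  if (!features$category %in% attr(tree, "categories")) {
    stop_field("features",
               paste("unknown category:", features$category))
  }
  node <- tree
  while (node$type == "internal") {
    node <- if (goes_left(node, features$category, features$bw,
                          features$intake)) node$left else node$right
  }
  node
}

# route all instances at once, returning the leaf id (depth-first numbering)
# each lands in
route_all <- function(node, instances, next_id = 1L) {
  if (node$type == "leaf") {
    return(list(ids = rep(next_id, nrow(instances)),
                rows = list(instances), next_id = next_id + 1L))
  }
  left_mask <- goes_left(node, instances$category, instances$bw,
                         instances$intake)
  l <- route_all(node$left, instances[left_mask, , drop = FALSE], next_id)
  r <- route_all(node$right, instances[!left_mask, , drop = FALSE], l$next_id)
  list(ids = c(l$ids, r$ids), rows = c(l$rows, r$rows), next_id = r$next_id)
}

#' Re-evaluate leaf statistics on a second-stage case set
#'
#' Two-stage protocol: the tree topology is fixed by the construction cases;
#' the evaluation cases are routed through it and every leaf's
#' `(n, k_hazard, risk_pct)` is recomputed from the instances it receives.
#' A leaf that receives no evaluation instances gets `n = 0`, `risk_pct =
#' NA` and is flagged `empty = TRUE`.
#'
#' @param tree A fitted `hazard_tree`.
#' @param eval_instances Non-empty labelled instance tibble.
#' @return A `hazard_tree` with updated leaf statistics.
#' @export
evaluate_leaves <- function(tree, eval_instances) {
  if (!inherits(tree, "hazard_tree")) {
    stop_field("tree", "must be a hazard_tree")
  }
  check_instances(eval_instances)
  if (nrow(eval_instances) == 0L) {
    stop_field("eval_instances", "must be non-empty")
  }
  unknown <- setdiff(unique(eval_instances$category), attr(tree, "categories"))
  if (length(unknown)) {
    stop_field("eval_instances",
               paste("unknown categories:", paste(unknown, collapse = ", ")))
  }
  out <- reeval_node(tree, eval_instances)
  attributes(out) <- attributes(tree)
  out
}

reeval_node <- function(node, instances) {
  if (node$type == "leaf") {
    n <- nrow(instances)
    k <- sum(instances$label)
    node$n <- n
    node$k_hazard <- k
    if (n == 0L) {
      node$risk_pct <- NA_real_
      node$majority <- NA
      node$empty <- TRUE
    } else {
      node$risk_pct <- leaf_risk(k, n)
      node$majority <- k * 2 > n
      node$empty <- NULL
    }
    return(node)
  }
  left_mask <- goes_left(node, instances$category, instances$bw,
                         instances$intake)
  node$n <- nrow(instances)
  node$left <- reeval_node(node$left, instances[left_mask, , drop = FALSE])
  node$right <- reeval_node(node$right, instances[!left_mask, , drop = FALSE])
  node
}
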