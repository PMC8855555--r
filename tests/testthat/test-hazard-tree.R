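# Split metrics, candidate enumeration, tree growth, routing, two-stage
# evaluation, serialisation.

test_that("entropy matches hand-computed values and rejects empty input", {
  expect_equal(entropy(rep(TRUE, 8)), 0)
  expect_equal(entropy(rep(c(TRUE, FALSE), 4)), 1)
  expect_equal(entropy(rep(c(TRUE, FALSE), c(2, 6))), 0.8112781, tolerance = 1e-6)
  expect_error(entropy(logical(0)), "labels")
  expect_error(entropy(c(1, 0)), "labels")
})

test_that("information gain is the entropy drop of a true partition", {
  parent <- rep(c(TRUE, FALSE), c(2, 6))
  # branches {2+,2-} and {0+,4-}: 0.8113 - 0.5*1 - 0.5*0
  expect_equal(
    information_gain(parent, list(rep(c(TRUE, FALSE), c(2, 2)), rep(FALSE, 4))),
    0.3112781, tolerance = 1e-6)
  # same class proportions as the parent => no information
  half <- rep(c(TRUE, FALSE), c(1, 3))
  expect_equal(information_gain(parent, list(half, half)), 0, tolerance = 1e-12)
  # pure branches from a 50/50 parent => gain equals parent entropy 1
  p5050 <- rep(c(TRUE, FALSE), 4)
  expect_equal(information_gain(p5050, list(rep(TRUE, 4), rep(FALSE, 4))), 1)
  expect_error(information_gain(parent, list(rep(TRUE, 3))),
               "partition")
})

test_that("split information is the branch-size entropy", {
  expect_equal(split_information(c(4, 4)), 1)
  expect_equal(split_information(c(8, 0)), 0)
  expect_equal(split_information(c(2, 6)), 0.8112781, tolerance = 1e-6)
  expect_error(split_information(numeric(0)), "branch_sizes")
  expect_error(split_information(c(0, 0)), "branch_sizes")
})

test_that("gain ratio divides gain by split information and excludes degenerate splits", {
  expect_equal(gain_ratio(0.3113, 1.0), 0.3113)
  expect_equal(gain_ratio(0, 0.5), 0)
  expect_equal(gain_ratio(0.4, 0.8), 2 * gain_ratio(0.2, 0.8))
  expect_error(gain_ratio(0.3, 0), class = "aquarisk_degenerate_split")
})

test_that("candidate enumeration uses midpoints and exhaustive category subsets", {
  inst <- tibble::tibble(
    category = c("shellfish", "shellfish", "algae", "algae"),
    bw = c(50, 60, 50, 60),
    intake = c(1, 2, 3, 4),
    label = c(TRUE, FALSE, TRUE, FALSE)
  )
  cands <- enumerate_candidates(inst)
  bw_thr <- cands$threshold[cands$attribute == "bw"]
  expect_true(55 %in% bw_thr)
  # 2 categories => exactly one binary partition
  expect_equal(sum(cands$attribute == "category"), 1L)
  # every retained candidate is scored and divides the data
  expect_true(all(cands$split_info > 0))
  expect_equal(cands$gain_ratio, cands$gain / cands$split_info)

  pure <- inst
  pure$label <- TRUE
  expect_equal(nrow(enumerate_candidates(pure)), 0L)

  onecat <- inst
  onecat$category <- "shellfish"
  expect_equal(sum(enumerate_candidates(onecat)$attribute == "category"), 0L)
})

test_that("the chosen split maximizes gain ratio on random small datasets (exhaustive oracle)", {
  set.seed(31)
  n_checked <- 0
  for (rep in 1:60) {
    df <- random_instances(n = sample(4:12, 1), n_cats = sample(2:3, 1))
    if (length(unique(df$label)) < 2) next
    cands <- enumerate_candidates(df)
    if (nrow(cands) == 0) next
    expect_equal(max(cands$gain_ratio), oracle_best_value(df),
                 tolerance = 1e-10)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 30)
})

test_that("plain information gain is available as an alternative criterion", {
  set.seed(32)
  df <- random_instances(12, 3)
  df$label[1:4] <- TRUE; df$label[5:12] <- FALSE
  cfg <- tree_config(criterion = "gain", min_leaf = 1)
  tree <- grow_tree(df, cfg)
  if (tree$type == "internal") {
    cands <- enumerate_candidates(df)
    expect_equal(tree$gain, max(cands$gain), tolerance = 1e-10)
    expect_equal(tree$gain, oracle_best_value(df, "gain"), tolerance = 1e-10)
  }
})

test_that("degenerate inputs give single leaves and stopping rules hold", {
  pure <- tibble::tibble(category = "shellfish", bw = 60, intake = 5,
                         label = TRUE)[rep(1, 10), ]
  tree <- grow_tree(pure, tree_config())
  expect_equal(tree$type, "leaf")
  expect_equal(tree$risk_pct, 100)

  mixed <- tibble::tibble(
    category = rep(c("shellfish", "algae"), each = 10),
    bw = runif(20, 40, 100), intake = runif(20, 1, 50),
    label = rep(c(TRUE, FALSE), each = 10)
  )
  stump <- grow_tree(mixed, tree_config(max_depth = 0))
  expect_equal(stump$type, "leaf")
  expect_equal(stump$risk_pct, 50)

  # too few instances for 2 * min_leaf
  small <- mixed[1:8, ]
  expect_equal(grow_tree(small, tree_config(min_leaf = 5))$type, "leaf")

  expect_error(grow_tree(mixed[0, ], tree_config()), "instances")
})

test_that("trees recover a planted single-threshold rule exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    df <- tibble::tibble(
      category = sample(category_vocabulary(), n, replace = TRUE),
      bw = runif(n, 35, 120),
      intake = rlnorm(n, log(10), 1),
      label = NA
    )
    df$label <- df$bw <= 55
    tree <- grow_tree(df, tree_config())
    expect_equal(tree$type, "internal")
    expect_equal(tree$attribute, "bw")
    lo <- max(df$bw[df$bw <= 55]); hi <- min(df$bw[df$bw > 55])
    expect_gt(tree$threshold, lo)
    expect_lte(tree$threshold, hi)
    expect_equal(tree$left$type, "leaf")
    expect_equal(tree$left$risk_pct, 100)
    expect_equal(tree$right$risk_pct, 0)
  }
})

test_that("partition conservation: child counts sum to parents, leaf hazards sum to total", {
  set.seed(33)
  df <- random_instances(300, 4)
  df$label <- df$intake > 12 | (df$bw < 50 & runif(300) < 0.8)
  tree <- grow_tree(df, tree_config(max_depth = 4, min_leaf = 3))

  check_node <- function(node) {
    if (node$type == "leaf") {
      return(c(n = node$n, k = node$k_hazard))
    }
    l <- check_node(node$left); r <- check_node(node$right)
    expect_equal(unname(l["n"] + r["n"]), node$n)
    c(n = unname(l["n"] + r["n"]), k = unname(l["k"] + r["k"]))
  }
  tot <- check_node(tree)
  expect_equal(unname(tot["n"]), nrow(df))
  expect_equal(unname(tot["k"]), sum(df$label))
})

test_that("permuting the labels drives the best gain ratio toward zero", {
  set.seed(34)
  n <- 120
  df <- tibble::tibble(
    category = sample(category_vocabulary()[1:4], n, replace = TRUE),
    bw = runif(n, 35, 120), intake = rlnorm(n, log(10), 1)
  )
  df$label <- df$bw <= 60   # strong signal
  signal <- max(enumerate_candidates(df)$gain_ratio)
  null_best <- replicate(25, {
    shuf <- df
    shuf$label <- sample(df$label)
    max(enumerate_candidates(shuf)$gain_ratio)
  })
  expect_lt(mean(null_best), signal / 2)
})

test_that("routing descends deterministically with <= on the left branch", {
  df <- tibble::tibble(
    category = rep(c("shellfish", "cephalopods"), each = 20),
    bw = rep(c(50, 80), 20),
    intake = 5,
    label = rep(c(50, 80), 20) <= 67.68
  )
  tree <- grow_tree(df, tree_config(min_leaf = 1))
  expect_equal(tree$attribute, "bw")
  # exactly at the threshold goes left
  at <- route(tree, list(category = "shellfish", bw = tree$threshold,
                         intake = 5))
  expect_equal(at$risk_pct, 100)
  above <- route(tree, list(category = "shellfish", bw = tree$threshold + 0.01,
                            intake = 5))
  expect_equal(above$risk_pct, 0)

  leaf_only <- grow_tree(df[df$bw == 50, ], tree_config())
  expect_equal(route(leaf_only, list(category = "shellfish", bw = 99,
                                     intake = 1))$n, 20)

  expect_error(route(tree, list(category = "shellfish", bw = 60)), "intake")
  expect_error(route(tree, list(category = "plankton", bw = 60, intake = 5)),
               "unknown category")
})

test_that("second-stage evaluation recomputes leaf statistics and flags empty leaves", {
  set.seed(35)
  df <- random_instances(200, 3)
  df$label <- df$bw <= 70
  tree <- grow_tree(df, tree_config())

  # idempotence: evaluating on the construction set reproduces the stats
  same <- evaluate_leaves(tree, df)
  expect_identical(tree_to_json(same), tree_to_json(tree))

  # a shifted evaluation set changes leaf counts but preserves the topology
  set.seed(99)
  ev <- tibble::tibble(
    category = sample(unique(df$category), 400, replace = TRUE),
    bw = round(runif(400, 35, 120), 1),
    intake = round(rlnorm(400, log(10), 1), 2)
  )
  ev$label <- ev$bw <= 70
  ev2 <- evaluate_leaves(tree, ev)
  expect_equal(ev2$attribute, tree$attribute)
  expect_equal(ev2$n, 400L)

  # leaves reached by no instance are flagged, not silently zero
  if (tree$type == "internal" && tree$attribute == "bw") {
    only_left <- ev[ev$bw <= tree$threshold, ]
    ev3 <- evaluate_leaves(tree, only_left)
    rightmost <- ev3$right
    while (rightmost$type == "internal") rightmost <- rightmost$left
    expect_true(isTRUE(rightmost$empty))
    expect_true(is.na(rightmost$risk_pct))
  }
})

test_that("leaf risk rounds half-up to one decimal using exact integer arithmetic", {
  expect_equal(leaf_risk(1, 16), 6.3)    # 6.25 rounds up
  expect_equal(leaf_risk(1, 3), 33.3)
  expect_equal(leaf_risk(2, 3), 66.7)
  expect_equal(leaf_risk(0, 5), 0)
  expect_equal(leaf_risk(5, 5), 100)
  expect_equal(leaf_risk(c(90, 0), c(212, 301)), c(42.5, 0))
  expect_error(leaf_risk(1, 0), "n")
  expect_error(leaf_risk(5, 3), "k_hazard")
  expect_error(leaf_risk(-1, 3), "k_hazard")
})

test_that("JSON and DOT serialisation round-trip and describe the tree", {
  set.seed(36)
  df <- random_instances(150, 3)
  df$label <- df$intake > 10
  tree <- grow_tree(df, tree_config(), metal = "Cd")
  js <- tree_to_json(tree)
  back <- tree_from_json(js)
  expect_identical(tree_to_json(back), js)
  expect_equal(attr(back, "metal"), "Cd")
  # routing through the deserialised tree agrees with the original
  probe <- list(category = df$category[1], bw = df$bw[1], intake = df$intake[1])
  expect_equal(route(back, probe)$n, route(tree, probe)$n)

  path <- tempfile(fileext = ".json")
  tree_to_json(tree, path)
  expect_identical(tree_to_json(tree_from_json(path)), js)

  dot <- tree_to_dot(tree)
  expect_match(dot, "^digraph hazard_tree")
  expect_match(dot, "risk=")
  expect_match(dot, "yes")
})
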