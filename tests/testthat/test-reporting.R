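# Rule extraction, endpoint mapping, rendering, highest-risk selection.

make_eval_tree <- function(seed = 40, metal = "Cd") {
  set.seed(seed)
  n <- 300
  df <- tibble::tibble(
    category = sample(category_vocabulary(), n, replace = TRUE),
    bw = runif(n, 35, 120),
    intake = rlnorm(n, log(10), 1)
  )
  df$label <- (df$category %in% c("shellfish", "algae", "cephalopods") &
                 df$intake > 8) | df$bw <= 45
  tree <- grow_tree(df, tree_config(max_depth = 3, min_leaf = 5),
                    metal = metal)
  list(tree = evaluate_leaves(tree, df), instances = df)
}

test_that("the endpoint map carries the seven modeled pairings and is extensible", {
  sm <- symptom_map()
  expect_setequal(names(sm), modeled_metals())
  expect_equal(sm[["iAs"]], "hyperpigmentation and keratosis follicularis")
  expect_equal(sm[["Cd"]], "kidney diseases")
  expect_equal(sm[["Co"]], "goiter")
  expect_equal(sm[["Fe"]], "gastrointestinal disorders")
  expect_equal(sm[["Sr"]], "adult rickets")
  expect_equal(sm[["Tl"]], "perifollicular atrophy")
  expect_equal(sm[["Zn"]],
               "reduce superoxide dismutase activity in red blood cells")
  extended <- symptom_map(extra = c(Pb = "intellectual disability"))
  expect_equal(extended[["Pb"]], "intellectual disability")
  expect_error(symptom_map(extra = "unnamed"), "named")
})

test_that("one rule per populated leaf, conditions root-first, endpoint attached", {
  fx <- make_eval_tree()
  rules <- extract_rules(fx$tree)
  n_leaves <- sum(unlist(gregexpr("\"type\": \"leaf\"",
                                  tree_to_json(fx$tree))) > 0)
  expect_equal(nrow(rules), n_leaves)
  expect_true(all(rules$symptom == "kidney diseases"))
  expect_true(all(rules$risk_pct == leaf_risk(rules$k_hazard, rules$n)))
  # sum of rule n equals the evaluation-set size
  expect_equal(sum(rules$n), nrow(fx$instances))
  expect_error(extract_rules(fx$tree, metal = "Cr"), "symptom map")
})

test_that("a single-leaf tree yields one rule with an empty condition list", {
  df <- tibble::tibble(category = "shellfish", bw = 60, intake = 5,
                       label = TRUE)[rep(1, 12), ]
  tree <- grow_tree(df, tree_config(), metal = "iAs")
  rules <- extract_rules(tree)
  expect_equal(nrow(rules), 1L)
  expect_equal(nrow(rules$conditions[[1]]), 0L)
  expect_match(rules$statement, "100%")
  expect_match(rules$statement, "hyperpigmentation and keratosis follicularis")
})

test_that("every instance satisfying a rule's conditions lands in that rule's leaf", {
  fx <- make_eval_tree()
  rules <- extract_rules(fx$tree)
  df <- fx$instances
  # each instance must satisfy exactly one rule, and that rule's counts must
  # match the leaf it routes to
  for (i in sample(nrow(df), 40)) {
    hits <- which(vapply(rules$conditions, satisfies_rule,
                         logical(1), df$category[i], df$bw[i], df$intake[i]))
    expect_length(hits, 1L)
    leaf <- route(fx$tree, list(category = df$category[i], bw = df$bw[i],
                                intake = df$intake[i]))
    expect_equal(rules$n[hits], leaf$n)
    expect_equal(rules$k_hazard[hits], leaf$k_hazard)
  }
})

test_that("reports render deterministically in all three formats and round-trip via JSON", {
  fx <- make_eval_tree()
  rules <- extract_rules(fx$tree)

  txt <- render_report(rules, "text")
  expect_equal(length(strsplit(txt, "\n")[[1]]), nrow(rules))
  expect_match(txt, "^For an adult")

  js <- render_report(rules, "json")
  back <- parse_rules_json(js)
  expect_equal(nrow(back), nrow(rules))
  expect_equal(back$risk_pct, rules$risk_pct)
  expect_equal(back$statement, rules$statement)
  for (i in seq_len(nrow(rules))) {
    expect_equal(as.data.frame(back$conditions[[i]]),
                 as.data.frame(rules$conditions[[i]]))
  }

  one <- rules[1, ]
  single <- jsonlite::parse_json(render_report(one, "json"))
  expect_length(single, 1L)
  expect_named(single[[1]],
               c("metal", "conditions", "n", "k_hazard", "risk_pct",
                 "symptom", "statement"))

  csv <- render_report(rules, "csv")
  parsed <- read.csv(text = csv, stringsAsFactors = FALSE)
  expect_equal(nrow(parsed), nrow(rules))
  expect_true(all(c("metal", "conditions", "risk_pct") %in% names(parsed)))

  expect_error(render_report(rules[0, ], "text"), "rules")
  expect_error(render_report(rules, "xml"), "arg")
})

test_that("intake conditions are reported in g/week (x7) in the sentence text", {
  df <- tibble::tibble(
    category = rep("shellfish", 40),
    bw = 60,
    intake = rep(c(1, 3), 20),
    label = rep(c(TRUE, FALSE), 20)
  )
  tree <- grow_tree(df, tree_config(min_leaf = 1), metal = "Fe")
  rules <- extract_rules(tree)
  # threshold 2 g/day -> printed as 14 g/week
  expect_match(rules$statement[1], "14 \\(g/week\\)")
})

test_that("highest risk picks the max per metal with ties broken by n then path order", {
  fx <- make_eval_tree(metal = "Cd")
  rules <- extract_rules(fx$tree)
  top <- highest_risk(rules)
  expect_equal(nrow(top), 1L)
  expect_equal(top$risk_pct, max(rules$risk_pct))

  tie <- rules[c(1, 1), ]
  tie$risk_pct <- 40
  tie$n <- c(10L, 100L)
  expect_equal(highest_risk(tie)$n, 100L)

  single <- rules[2, ]
  expect_equal(highest_risk(single)$statement, single$statement)

  # several metals: one row each, vocabulary order
  other <- extract_rules(make_eval_tree(seed = 41, metal = "iAs")$tree)
  combined <- rbind(rules, other)
  top2 <- highest_risk(combined)
  expect_equal(top2$metal, c("iAs", "Cd"))
})
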