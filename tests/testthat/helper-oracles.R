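# Independent oracles, kept deliberately separate from the implementation:
# plain-R entropy, an exhaustive search over every binary split, and a
# numeric-integration mean for the truncated normal.

oracle_entropy <- function(labels) {
  p <- as.vector(table(factor(labels, levels = c(FALSE, TRUE)))) /
    length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_split_value <- function(labels, left_mask, criterion = "gain_ratio") {
  n <- length(labels)
  nl <- sum(left_mask)
  if (nl == 0 || nl == n) return(NA_real_)
  gain <- oracle_entropy(labels) -
    nl / n * oracle_entropy(labels[left_mask]) -
    (n - nl) / n * oracle_entropy(labels[!left_mask])
  if (criterion == "gain") return(gain)
  si <- -(nl / n) * log2(nl / n) - ((n - nl) / n) * log2((n - nl) / n)
  gain / si
}

# Exhaustive maximum over all midpoint thresholds on bw and intake and all
# binary category partitions (every non-empty proper subset; duplicated
# complements do not change the maximum).
oracle_best_value <- function(df, criterion = "gain_ratio") {
  best <- -Inf
  for (attr in c("bw", "intake")) {
    v <- sort(unique(df[[attr]]))
    if (length(v) >= 2) {
      for (i in seq_len(length(v) - 1)) {
        thr <- (v[i] + v[i + 1]) / 2
        val <- oracle_split_value(df$label, df[[attr]] <= thr, criterion)
        if (!is.na(val) && val > best) best <- val
      }
    }
  }
  cats <- sort(unique(df$category))
  if (length(cats) >= 2) {
    for (sz in seq_len(length(cats) - 1)) {
      combos <- utils::combn(cats, sz, simplify = FALSE)
      for (sub in combos) {
        val <- oracle_split_value(df$label, df$category %in% sub, criterion)
        if (!is.na(val) && val > best) best <- val
      }
    }
  }
  best
}

oracle_truncnorm_mean <- function(mean, sd, lower, upper) {
  z <- stats::integrate(function(x) stats::dnorm(x, mean, sd),
                        lower, upper)$value
  stats::integrate(function(x) x * stats::dnorm(x, mean, sd),
                   lower, upper)$value / z
}

# small random labelled-instance tables for property tests
random_instances <- function(n, n_cats = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cats <- sample(category_vocabulary(), n_cats)
  tibble::tibble(
    category = sample(cats, n, replace = TRUE),
    bw = round(runif(n, 35, 120), 1),
    intake = round(rlnorm(n, log(10), 1), 2),
    label = runif(n) < 0.5
  )
}

# evaluate a rule's condition list against one feature row
satisfies_rule <- function(conds, category, bw, intake) {
  if (!nrow(conds)) return(TRUE)
  for (j in seq_len(nrow(conds))) {
    ok <- switch(
      paste(conds$attribute[j], conds$relation[j]),
      "category in" = category %in% conds$subset[[j]],
      "category not_in" = !category %in% conds$subset[[j]],
      "bw le" = bw <= conds$value[j],
      "bw gt" = bw > conds$value[j],
      "intake le" = intake <= conds$value[j],
      "intake gt" = intake > conds$value[j],
      stop("unknown condition")
    )
    if (!ok) return(FALSE)
  }
  TRUE
}
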