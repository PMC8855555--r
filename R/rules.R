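# Rule extraction, health-endpoint mapping, and report rendering.

#' Metal-to-health-endpoint mapping
#'
#' The seven modeled metals and the chronic endpoint associated with their
#' long-term excess intake. Extensible: supply extra pairings via `extra`
#' for metals beyond the seven shipped ones.
#'
#' @param extra Optional named character vector of additional
#'   `metal = endpoint` pairings.
#' @return Named character vector, metal -> endpoint phrase.
#' @examples
#' symptom_map()[["iAs"]]
#' @export
symptom_map <- function(extra = NULL) {
  base <- c(
    iAs = "hyperpigmentation and keratosis follicularis",
    Cd  = "kidney diseases",
    Co  = "goiter",
    Fe  = "gastrointestinal disorders",
    Sr  = "adult rickets",
    Tl  = "perifollicular atrophy",
    Zn  = "reduce superoxide dismutase activity in red blood cells"
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop_field("extra", "must be a named character vector")
    }
    base[names(extra)] <- extra
  }
  base
}

#' Extract leaf-level hazard rules from an evaluated tree
#'
#' Walks the tree and emits one rule per populated leaf (`n >= 1`): the
#' root-first list of split conditions on the path, the leaf's evaluation
#' counts and risk percentage, and the metal's health endpoint.
#'
#' @param tree A fitted (and typically [evaluate_leaves()]-updated)
#'   `hazard_tree`.
#' @param metal Metal identifier; must be present in `symptoms`.
#' @param symptoms Named endpoint vector from [symptom_map()].
#' @return A tibble of rules: `metal`, `conditions` (list column of
#'   tibbles with `attribute`, `relation`, `value`, `subset`), `n`,
#'   `k_hazard`, `risk_pct`, `symptom`, `statement`.
#' @export
extract_rules <- function(tree, metal = attr(tree, "metal"),
                          symptoms = symptom_map()) {
  if (!inherits(tree, "hazard_tree")) {
    stop_field("tree", "must be a hazard_tree")
  }
  if (is.null(metal) || !metal %in% names(symptoms)) {
    stop_field("metal", "must be present in the symptom map")
  }
  acc <- list()
  walk <- function(node, conds) {
    if (node$type == "leaf") {
      if (node$n >= 1L) {
        acc[[length(acc) + 1L]] <<- list(conds = conds, n = node$n,
                                         k = node$k_hazard,
                                         risk = node$risk_pct)
      }
      return(invisible())
    }
    this <- if (node$kind == "threshold") {
      list(attribute = node$attribute, threshold = node$threshold)
    } else {
      list(attribute = "category", subset = node$left_subset)
    }
    walk(node$left, append(conds, list(c(this, relation = "left"))))
    walk(node$right, append(conds, list(c(this, relation = "right"))))
  }
  walk(tree, list())
  if (!length(acc)) {
    stop_field("tree", "no populated leaves to extract rules from")
  }
  rows <- lapply(acc, function(a) {
    conds <- condition_tibble(a$conds)
    tibble::tibble(
      metal = metal,
      conditions = list(conds),
      n = as.integer(a$n), k_hazard = as.integer(a$k),
      risk_pct = a$risk,
      symptom = unname(symptoms[[metal]])
    )
  })
  rules <- do.call(rbind, rows)
  rules$statement <- vapply(seq_len(nrow(rules)), function(i) {
    rule_statement(rules$conditions[[i]], metal, rules$symptom[i],
                   rules$risk_pct[i])
  }, character(1))
  rules
}

condition_tibble <- function(conds) {
  if (!length(conds)) {
    return(tibble::tibble(attribute = character(), relation = character(),
                          value = numeric(), subset = list()))
  }
  do.call(rbind, lapply(conds, function(cn) {
    if (cn$attribute == "category") {
      full <- cn$subset
      tibble::tibble(
        attribute = "category",
        relation = if (cn$relation == "left") "in" else "not_in",
        value = NA_real_,
        subset = list(full)
      )
    } else {
      tibble::tibble(
        attribute = cn$attribute,
        relation = if (cn$relation == "left") "le" else "gt",
        value = cn$threshold,
        subset = list(NULL)
      )
    }
  }))
}

pretty_cats <- function(cats) {
  labels <- c(pelagic_fish = "pelagic fishes", inshore_fish = "inshore fishes",
              other_fish = "other fishes", crustaceans = "crustaceans",
              shellfish = "shellfish", cephalopods = "cephalopods",
              algae = "algae")
  out <- ifelse(cats %in% names(labels), labels[cats], cats)
  if (length(out) == 1L) return(out)
  paste(paste(out[-length(out)], collapse = ", "), "and", out[length(out)])
}

# Sentence template mirroring the report style:
# "For an adult whose ..., the risk of causing <endpoint> was <pct>%."
rule_statement <- function(conds, metal, symptom, risk_pct,
                           intake_unit = "g_week") {
  clauses <- character(0)
  cats_clause <- "aquatic products"
  if (nrow(conds)) {
    for (i in seq_len(nrow(conds))) {
      attr_i <- conds$attribute[i]
      if (attr_i == "category") {
        cats_clause <- if (conds$relation[i] == "in") {
          pretty_cats(conds$subset[[i]])
        } else {
          paste("aquatic products other than", pretty_cats(conds$subset[[i]]))
        }
      } else if (attr_i == "bw") {
        rel <- if (conds$relation[i] == "le") "less than or equal to"
               else "greater than"
        clauses <- c(clauses, sprintf("body weight is %s %.4g (kg)",
                                      rel, conds$value[i]))
      } else {
        rel <- if (conds$relation[i] == "le") "less than or equal to"
               else "greater than"
        if (intake_unit == "g_week") {
          clauses <- c(clauses, sprintf("food intake is %s %.4g (g/week)",
                                        rel, conds$value[i] * 7))
        } else {
          clauses <- c(clauses, sprintf("food intake is %s %.4g (g/day)",
                                        rel, conds$value[i]))
        }
      }
    }
  }
  who <- if (length(clauses)) {
    sprintf("For an adult whose %s who ingests %s with %s",
            paste(clauses, collapse = " and "), cats_clause, metal)
  } else {
    sprintf("For an adult who ingests %s with %s", cats_clause, metal)
  }
  verb <- if (grepl("^reduce", symptom)) "of" else "of causing"
  sprintf("%s, the risk %s %s was %s%%.", who, verb, symptom,
          formatC(risk_pct, format = "fg"))
}

#' Render a rule collection as text, JSON or CSV
#'
#' Rules are ordered deterministically (metal, then root-to-leaf path
#' order). The text format is one risk sentence per rule; JSON is an array
#' of objects carrying every field including the structured conditions
#' (round-trippable via [parse_rules_json()]); CSV flattens the conditions
#' into a readable `conditions` column.
#'
#' @param rules Tibble from [extract_rules()] (rules for several metals may
#'   be row-bound).
#' @param format `"text"`, `"json"` or `"csv"`.
#' @param path Optional file path; when `NULL` the document is returned as
#'   a character string.
#' @return The rendered document as a single string (invisibly when written
#'   to `path`).
#' @export
render_report <- function(rules, format = c("text", "json", "csv"),
                          path = NULL) {
  format <- match.arg(format)
  check_rules(rules)
  rules <- rules[order(match(rules$metal, metal_vocabulary())), , drop = FALSE]
  txt <- switch(format,
    text = paste(rules$statement, collapse = "\n"),
    json = rules_to_json(rules),
    csv = rules_to_csv(rules)
  )
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

check_rules <- function(rules) {
  if (!is.data.frame(rules) || nrow(rules) == 0L) {
    stop_field("rules", "must be a non-empty rule tibble")
  }
  need <- c("metal", "conditions", "n", "k_hazard", "risk_pct", "symptom",
            "statement")
  missing <- setdiff(need, names(rules))
  if (length(missing)) {
    stop_field("rules", paste("missing columns:",
                              paste(missing, collapse = ", ")))
  }
  invisible(rules)
}

rules_to_json <- function(rules) {
  items <- lapply(seq_len(nrow(rules)), function(i) {
    conds <- rules$conditions[[i]]
    cond_list <- lapply(seq_len(nrow(conds)), function(j) {
      if (conds$attribute[j] == "category") {
        list(attribute = "category", relation = conds$relation[j],
             subset = as.list(conds$subset[[j]]))
      } else {
        list(attribute = conds$attribute[j], relation = conds$relation[j],
             value = conds$value[j])
      }
    })
    list(metal = rules$metal[i], conditions = cond_list,
         n = rules$n[i], k_hazard = rules$k_hazard[i],
         risk_pct = rules$risk_pct[i], symptom = rules$symptom[i],
         statement = rules$statement[i])
  })
  as.character(jsonlite::toJSON(items, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

rules_to_csv <- function(rules) {
  flat <- data.frame(
    metal = rules$metal,
    conditions = vapply(rules$conditions, function(conds) {
      if (!nrow(conds)) return("(none)")
      paste(vapply(seq_len(nrow(conds)), function(j) {
        if (conds$attribute[j] == "category") {
          sprintf("category %s {%s}",
                  if (conds$relation[j] == "in") "in" else "not in",
                  paste(conds$subset[[j]], collapse = "|"))
        } else {
          sprintf("%s %s %.6g", conds$attribute[j],
                  if (conds$relation[j] == "le") "<=" else ">",
                  conds$value[j])
        }
      }, character(1)), collapse = "; ")
    }, character(1)),
    n = rules$n, k_hazard = rules$k_hazard, risk_pct = rules$risk_pct,
    symptom = rules$symptom,
    stringsAsFactors = FALSE
  )
  con <- textConnection("out_csv", "w", local = TRUE)
  utils::write.csv(flat, con, row.names = FALSE)
  close(con)
  paste(out_csv, collapse = "\n")
}

#' Parse a JSON rule report back into a rule tibble
#'
#' Inverse of `render_report(rules, "json")`.
#'
#' @param txt JSON string or file path.
#' @return A rule tibble equal (up to attribute bookkeeping) to the one
#'   rendered.
#' @export
parse_rules_json <- function(txt) {
  raw <- if (file.exists(txt)) {
    jsonlite::read_json(txt, simplifyVector = FALSE)
  } else {
    jsonlite::parse_json(txt, simplifyVector = FALSE)
  }
  rows <- lapply(raw, function(item) {
    conds <- if (length(item$conditions)) {
      do.call(rbind, lapply(item$conditions, function(cn) {
        if (cn$attribute == "category") {
          tibble::tibble(attribute = "category", relation = cn$relation,
                         value = NA_real_,
                         subset = list(as.character(unlist(cn$subset))))
        } else {
          tibble::tibble(attribute = cn$attribute, relation = cn$relation,
                         value = as.numeric(cn$value), subset = list(NULL))
        }
      }))
    } else {
      tibble::tibble(attribute = character(), relation = character(),
                     value = numeric(), subset = list())
    }
    tibble::tibble(
      metal = item$metal, conditions = list(conds),
      n = as.integer(item$n), k_hazard = as.integer(item$k_hazard),
      risk_pct = as.numeric(item$risk_pct), symptom = item$symptom,
      statement = item$statement
    )
  })
  do.call(rbind, rows)
}

#' Highest-risk rule per metal
#'
#' For each metal, the rule with the maximal risk percentage; ties are
#' broken by larger evaluation count `n`, then by path order (earlier rule
#' wins).
#'
#' @param rules Rule tibble (one or several metals).
#' @return A rule tibble with one row per metal, ordered by the metal
#'   vocabulary.
#' @export
highest_risk <- function(rules) {
  check_rules(rules)
  picked <- lapply(split(seq_len(nrow(rules)), rules$metal), function(idx) {
    sub <- rules[idx, , drop = FALSE]
    o <- order(-sub$risk_pct, -sub$n, seq_len(nrow(sub)))
    sub[o[1], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  out[order(match(out$metal, metal_vocabulary())), , drop = FALSE]
}
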