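# End-to-end two-stage study: simulate, assess, grow, evaluate, report.

# Subjects needed so the expected number of consumption cases (subject x
# category pairs with positive intake) is about n_cases.
subjects_for_cases <- function(n_cases, zero_intake_prob) {
  expected_per_subject <- sum(1 - zero_intake_prob)
  ceiling(n_cases / expected_per_subject * 1.15) + 5L
}

# Long consumption table (subject, category, bw, intake > 0), truncated to
# exactly n_cases rows in subject order.
consumption_cases <- function(subjects, n_cases) {
  cats <- category_vocabulary()
  long <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    intakes <- vapply(cats, function(cat) {
      subjects[[paste0(cat, "_g_per_day")]][i]
    }, numeric(1))
    keep <- intakes > 0
    if (!any(keep)) return(NULL)
    data.frame(subject_id = subjects$subject_id[i],
               category = cats[keep],
               bw = subjects$body_weight_kg[i],
               intake = intakes[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) < n_cases) {
    stop_field("n_cases", "population too small for the requested case count")
  }
  tibble::as_tibble(long[seq_len(n_cases), , drop = FALSE])
}

# Label a consumption-case table for one metal, optionally sampling
# per-case concentrations.
label_cases <- function(cases, metal, conc_table, rfd_table,
                        concentration = "mean", seed = 1L) {
  prof <- conc_table[conc_table$metal == metal, , drop = FALSE]
  conc <- stats::setNames(prof$mean, prof$category)[cases$category]
  conc <- unname(conc)
  if (concentration == "sample") {
    for (cat in unique(cases$category)) {
      rows <- which(cases$category == cat)
      p <- prof[prof$category == cat, , drop = FALSE]
      sub_seed <- (as.integer(seed) + 104729L * match(metal, metal_vocabulary()) +
                     match(cat, category_vocabulary())) %% .Machine$integer.max
      conc[rows] <- sample_concentrations(p, length(rows), seed = sub_seed)
    }
  }
  rfd <- rfd_for(rfd_table, metal)
  hq <- compute_hq(compute_edi(conc, cases$intake, cases$bw), rfd)
  tibble::tibble(
    subject_id = cases$subject_id, metal = metal,
    category = cases$category, bw = cases$bw, intake = cases$intake,
    concentration = conc, hq = hq, label = classify_hazard(hq)
  )
}

#' Run the full two-stage hazard-tree study
#'
#' Simulates a construction-stage and an evaluation-stage consumption
#' survey at the study scale (422 and 2,107 consumption cases by default),
#' assesses exposure for the modeled metals, grows one gain-ratio hazard
#' tree per metal on the construction cases, recomputes every leaf's risk
#' statistics from the evaluation cases, and extracts the leaf rules and
#' each metal's highest-risk rule.
#'
#' @param seed Integer master seed; construction and evaluation populations
#'   use derived seeds.
#' @param n_construction_cases,n_evaluation_cases Consumption-case counts
#'   for the two stages.
#' @param metals Metals to model (default [modeled_metals()]).
#' @param conc_table,rfd_table Concentration and reference-dose tables.
#' @param config Tree configuration.
#' @param concentration `"sample"` (default: per-case lognormal draws, the
#'   Monte Carlo mode) or `"mean"` (category means; labels are then constant
#'   within a category at fixed bw/intake ratio).
#' @param population Optional [population_spec()] overriding the default
#'   population model (its `n_subjects`/`seed` are replaced per stage).
#' @return A list with `construction`, `evaluation` (labelled case tibbles,
#'   all metals), `trees` (named list of evaluated `hazard_tree`s), `rules`
#'   (rule tibble across metals) and `highest` (one rule per metal).
#' @examples
#' \donttest{
#' study <- run_study(seed = 1, n_construction_cases = 100,
#'                    n_evaluation_cases = 400, metals = c("Cd", "Zn"))
#' study$highest$statement
#' }
#' @export
run_study <- function(seed = 1L,
                      n_construction_cases = 422L,
                      n_evaluation_cases = 2107L,
                      metals = modeled_metals(),
                      conc_table = metal_concentration_table(),
                      rfd_table = reference_dose_table(),
                      config = tree_config(),
                      concentration = c("sample", "mean"),
                      population = NULL) {
  concentration <- match.arg(concentration)
  check_scalar_number(seed, "seed")
  seed <- as.integer(seed)
  zp <- if (is.null(population)) default_zero_intake_prob()
        else population$zero_intake_prob
  make_spec <- function(n_cases, stage_seed) {
    n_subj <- subjects_for_cases(n_cases, zp)
    if (is.null(population)) {
      population_spec(n_subjects = n_subj, seed = stage_seed)
    } else {
      population_spec(
        n_subjects = n_subj, bw_mean = population$bw_mean,
        bw_sd = population$bw_sd, bw_bounds = population$bw_bounds,
        intake_params = population$intake_params,
        zero_intake_prob = population$zero_intake_prob, seed = stage_seed
      )
    }
  }
  seed_c <- (seed * 2L + 1L) %% .Machine$integer.max
  seed_e <- (seed * 2L + 2L) %% .Machine$integer.max
  cases_c <- consumption_cases(generate_population(make_spec(
    n_construction_cases, seed_c)), n_construction_cases)
  cases_e <- consumption_cases(generate_population(make_spec(
    n_evaluation_cases, seed_e)), n_evaluation_cases)

  symptoms <- symptom_map()
  trees <- list()
  construction <- evaluation <- list()
  rules <- list()
  for (metal in metals) {
    inst_c <- label_cases(cases_c, metal, conc_table, rfd_table,
                          concentration, seed = seed_c)
    inst_e <- label_cases(cases_e, metal, conc_table, rfd_table,
                          concentration, seed = seed_e)
    tree <- grow_tree(inst_c, config, metal = metal)
    tree <- evaluate_leaves(tree, inst_e)
    trees[[metal]] <- tree
    construction[[metal]] <- inst_c
    evaluation[[metal]] <- inst_e
    if (metal %in% names(symptoms)) {
      rules[[metal]] <- extract_rules(tree, metal, symptoms)
    }
  }
  rules <- do.call(rbind, rules)
  list(
    construction = do.call(rbind, construction),
    evaluation = do.call(rbind, evaluation),
    trees = trees,
    rules = rules,
    highest = if (!is.null(rules)) highest_risk(rules) else NULL
  )
}
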