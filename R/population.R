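# Synthetic consumption-survey population: spec, generator, CSV/YAML I/O.

#' Specify a synthetic consumption-survey population
#'
#' Describes the adult (19-64) population whose aquatic-product consumption
#' the generator emulates: a truncated-normal body-weight distribution and,
#' per category, a zero-inflated lognormal daily intake (consumption surveys
#' contain many non-consumers of any given category, hence the point mass at
#' zero).
#'
#' Defaults: body weight ~ Normal(64, 11) kg truncated to \[35, 120\] kg;
#' per-category intakes with medians of order grams to tens of grams per day
#' and category-specific non-consumption probabilities. See the package
#' vignette for the rationale behind each value.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param bw_mean,bw_sd Body-weight mean and SD, kg.
#' @param bw_bounds Length-2 numeric, truncation bounds in kg (lower >= 1).
#' @param intake_params Named list, one entry per category, each
#'   `c(meanlog, sdlog)` of the positive intake distribution (g/day scale).
#' @param zero_intake_prob Named numeric, per-category probability of zero
#'   intake, each in \[0, 1\].
#' @param seed Integer seed driving all randomness in
#'   [generate_population()].
#' @return An object of class `population_spec`.
#' @examples
#' spec <- population_spec(n_subjects = 10, seed = 1)
#' generate_population(spec)
#' @export
population_spec <- function(n_subjects,
                            bw_mean = 64,
                            bw_sd = 11,
                            bw_bounds = c(35, 120),
                            intake_params = default_intake_params(),
                            zero_intake_prob = default_zero_intake_prob(),
                            seed = 1L) {
  check_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  if (n_subjects != as.integer(n_subjects)) {
    stop_field("n_subjects", "must be a whole number >= 1")
  }
  check_scalar_number(bw_mean, "bw_mean", positive = TRUE)
  check_scalar_number(bw_sd, "bw_sd", nonneg = TRUE)
  if (!is.numeric(bw_bounds) || length(bw_bounds) != 2L ||
      bw_bounds[1] < 1 || bw_bounds[1] >= bw_bounds[2]) {
    stop_field("bw_bounds", "must be (lower, upper) with 1 <= lower < upper")
  }
  cats <- category_vocabulary()
  if (!is.list(intake_params) || !all(cats %in% names(intake_params))) {
    stop_field("intake_params", "must name every category")
  }
  for (cat in cats) {
    p <- intake_params[[cat]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)) || p[2] < 0) {
      stop_field(paste0("intake_params$", cat),
                 "must be c(meanlog, sdlog) with sdlog >= 0")
    }
  }
  if (!is.numeric(zero_intake_prob) || !all(cats %in% names(zero_intake_prob)) ||
      any(zero_intake_prob < 0 | zero_intake_prob > 1)) {
    stop_field("zero_intake_prob",
               "must name every category with probabilities in [0, 1]")
  }
  check_scalar_number(seed, "seed")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      bw_mean = bw_mean, bw_sd = bw_sd, bw_bounds = as.numeric(bw_bounds),
      intake_params = intake_params[cats],
      zero_intake_prob = zero_intake_prob[cats],
      age_band = "adults_19_64",
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' @rdname population_spec
#' @export
default_intake_params <- function() {
  # medians exp(meanlog) g/day: fish categories ~ 8-12 g/day, invertebrate
  # and algae categories ~ 2-5 g/day, each with a heavy right tail
  list(
    pelagic_fish = c(log(10), 1.0),
    inshore_fish = c(log(12), 1.0),
    other_fish   = c(log(10), 1.0),
    crustaceans  = c(log(5),  1.1),
    shellfish    = c(log(4),  1.2),
    cephalopods  = c(log(5),  1.1),
    algae        = c(log(2),  1.2)
  )
}

#' @rdname population_spec
#' @export
default_zero_intake_prob <- function() {
  c(pelagic_fish = 0.30, inshore_fish = 0.25, other_fish = 0.30,
    crustaceans = 0.55, shellfish = 0.50, cephalopods = 0.50, algae = 0.60)
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Synthetic population spec:", x$n_subjects, "subjects,",
      x$age_band, "\n")
  cat(sprintf("  body weight ~ N(%g, %g) kg truncated to [%g, %g]\n",
              x$bw_mean, x$bw_sd, x$bw_bounds[1], x$bw_bounds[2]))
  cat("  zero-inflated lognormal intakes for",
      length(x$intake_params), "categories; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic consumption-survey population
#'
#' Draws `n_subjects` adult subjects: a body weight from the truncated
#' normal in the spec and, for each of the seven aquatic-product categories,
#' a daily intake that is zero with the category's non-consumption
#' probability and lognormal otherwise. Fully deterministic under the spec's
#' seed (Mersenne-Twister; body weights drawn first, then the per-category
#' zero masks and intakes in the fixed category order).
#'
#' @param spec A [population_spec()].
#' @return A tibble with columns `subject_id`, `body_weight_kg`,
#'   `age_band`, and one `<category>_g_per_day` column per category.
#' @export
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec")) {
    stop_field("spec", "must be a population_spec object")
  }
  n <- spec$n_subjects
  cats <- category_vocabulary()
  withr::with_seed(spec$seed, {
    bw <- rtruncnorm(n, spec$bw_mean, spec$bw_sd,
                     spec$bw_bounds[1], spec$bw_bounds[2])
    intakes <- lapply(cats, function(cat) {
      zero <- stats::rbinom(n, 1L, spec$zero_intake_prob[[cat]]) == 1L
      p <- spec$intake_params[[cat]]
      x <- stats::rlnorm(n, meanlog = p[1], sdlog = p[2])
      x[zero] <- 0
      x
    })
  })
  out <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    body_weight_kg = bw,
    age_band = spec$age_band
  )
  for (i in seq_along(cats)) {
    out[[paste0(cats[i], "_g_per_day")]] <- intakes[[i]]
  }
  out
}

intake_columns <- function() paste0(category_vocabulary(), "_g_per_day")

#' Read and write subject tables
#'
#' Subjects are stored as CSV with header
#' `subject_id,body_weight_kg,age_band,<category>_g_per_day,...`.
#'
#' @param subjects A subject tibble from [generate_population()].
#' @param path File path.
#' @return `write_subjects()` returns `path` invisibly; `read_subjects()`
#'   returns the subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  check_subjects(subjects)
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_subjects(out)
  out
}

check_subjects <- function(subjects) {
  need <- c("subject_id", "body_weight_kg", intake_columns())
  missing <- setdiff(need, names(subjects))
  if (length(missing)) {
    stop_field("subjects", paste("missing columns:",
                                 paste(missing, collapse = ", ")))
  }
  if (any(subjects$body_weight_kg <= 0)) {
    stop_field("subjects", "body weights must be > 0")
  }
  if (any(as.matrix(subjects[intake_columns()]) < 0)) {
    stop_field("subjects", "intakes must be >= 0")
  }
  invisible(subjects)
}

#' Read a population spec from YAML or JSON
#'
#' The file carries the fields of [population_spec()]; `intake_params` as a
#' mapping `category: [meanlog, sdlog]` and `zero_intake_prob` as
#' `category: probability`. Omitted fields take the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `population_spec`.
#' @export
read_population_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list(n_subjects = raw$n_subjects)
  for (f in c("bw_mean", "bw_sd", "bw_bounds", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$intake_params)) {
    args$intake_params <- lapply(raw$intake_params, unlist)
  }
  if (!is.null(raw$zero_intake_prob)) {
    args$zero_intake_prob <- unlist(raw$zero_intake_prob)
  }
  do.call(population_spec, args)
}

#' Write sampled concentrations as CSV
#'
#' Long format `metal,category,sample_id,conc_mg_kg`, one row per draw.
#'
#' @param samples Numeric vector of concentrations (mg/kg).
#' @param metal,category Identifiers for the sampled profile.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_concentration_samples <- function(samples, metal, category, path) {
  check_metal(metal)
  check_category(category)
  df <- data.frame(
    metal = metal, category = category,
    sample_id = seq_along(samples), conc_mg_kg = samples
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
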