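# Built-in concentration table and seeded concentration sampling.

.aquarisk_env <- new.env(parent = emptyenv())

#' Built-in tissue-concentration table
#'
#' Per-(metal, category) summary of heavy-metal concentrations in cooked
#' aquatic products: mean and standard deviation in mg/kg wet weight, plus
#' the number of laboratory samples behind each category. The table covers
#' all 12 metals in all 7 categories (84 profiles) and is shipped as a CSV
#' under `inst/extdata/`.
#'
#' @return A tibble with columns `metal`, `category`, `mean`, `sd`
#'   (mg/kg wet weight) and `n_samples`.
#' @examples
#' tab <- metal_concentration_table()
#' subset(tab, metal == "Cd" & category == "shellfish")
#' @export
metal_concentration_table <- function() {
  if (is.null(.aquarisk_env$conc_table)) {
    path <- system.file("extdata", "metal_concentrations.csv",
                        package = "aquarisk", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(
      nrow(tab) == 84L,
      all(tab$metal %in% metal_vocabulary()),
      all(tab$category %in% category_vocabulary()),
      all(tab$mean > 0), all(tab$sd >= 0)
    )
    .aquarisk_env$conc_table <- tibble::as_tibble(tab)
  }
  .aquarisk_env$conc_table
}

#' Look up one concentration profile
#'
#' @param metal One of the 12 metal identifiers.
#' @param category One of the 7 category identifiers.
#' @return A one-row tibble from [metal_concentration_table()].
#' @examples
#' concentration_profile("Fe", "shellfish")
#' @export
concentration_profile <- function(metal, category) {
  check_metal(metal)
  check_category(category)
  tab <- metal_concentration_table()
  tab[tab$metal == metal & tab$category == category, , drop = FALSE]
}

# Lognormal parameters matched to an arithmetic mean m and SD s:
# sigma^2 = log(1 + s^2/m^2), mu = log(m) - sigma^2/2.
lnorm_params <- function(m, s) {
  sigma2 <- log1p((s / m)^2)
  list(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Sample tissue concentrations from a profile
#'
#' Draws strictly positive concentration values whose population mean and SD
#' match the profile's printed moments. The default distribution is a
#' lognormal with moment-matched parameters (tissue concentrations are
#' right-skewed, and several profiles have SD > mean, which no positive
#' normal can produce); a zero-truncated normal is available for sensitivity
#' checks. A profile with `sd = 0` is degenerate and returns `n` copies of
#' the mean.
#'
#' @param profile A one-row data frame with columns `mean` and `sd`
#'   (mg/kg), e.g. from [concentration_profile()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; the same seed always yields the same draws.
#' @param distribution `"lognormal"` (default) or `"truncated_normal"`.
#' @return Numeric vector of `n` concentrations, mg/kg.
#' @examples
#' x <- sample_concentrations(concentration_profile("Fe", "shellfish"),
#'                            n = 1000, seed = 1)
#' mean(x)
#' @export
sample_concentrations <- function(profile, n, seed,
                                  distribution = c("lognormal",
                                                   "truncated_normal")) {
  distribution <- match.arg(distribution)
  if (!is.data.frame(profile) || nrow(profile) != 1L ||
      !all(c("mean", "sd") %in% names(profile))) {
    stop_field("profile", "must be a one-row data frame with mean and sd")
  }
  check_scalar_number(n, "n", positive = TRUE)
  if (n != as.integer(n)) stop_field("n", "must be a whole number")
  check_scalar_number(seed, "seed")
  m <- profile$mean
  s <- profile$sd
  check_scalar_number(m, "profile$mean", positive = TRUE)
  check_scalar_number(s, "profile$sd", nonneg = TRUE)
  if (s == 0) return(rep(m, n))
  withr::with_seed(as.integer(seed), {
    if (distribution == "lognormal") {
      p <- lnorm_params(m, s)
      stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
    } else {
      rtruncnorm(n, mean = m, sd = s, lower = 0, upper = Inf)
    }
  })
}

# Inverse-CDF sampling of a truncated normal; deterministic under the
# current RNG state. Used for concentrations (lower = 0) and body weights.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), upper)
}
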