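# Exposure algebra: EDI, HQ, hazard label, ADI, and labelled instances.

#' Estimated daily intake of a metal from one food
#'
#' EDI = C x CR x 10^-3 / BW, in mg/kg bw/day, where C is the tissue
#' concentration (mg/kg wet weight), CR the consumption rate (g/day) and BW
#' the body weight (kg); the 10^-3 converts grams of food to kilograms.
#' Vectorised over its arguments.
#'
#' @param concentration Concentration in the cooked product, mg/kg (>= 0).
#' @param intake Consumption rate, g/day (>= 0).
#' @param body_weight Body weight, kg (> 0).
#' @return EDI in mg/kg bw/day.
#' @examples
#' compute_edi(1.25, 20, 60)   # 4.1667e-4
#' @export
compute_edi <- function(concentration, intake, body_weight) {
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop_field("concentration", "must be finite and >= 0")
  }
  if (any(!is.finite(intake)) || any(intake < 0)) {
    stop_field("intake", "must be finite and >= 0")
  }
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    stop_field("body_weight", "must be finite and > 0")
  }
  concentration * intake * 1e-3 / body_weight
}

#' Hazard quotient
#'
#' HQ = EDI / RfD: the ratio of the dose actually ingested to the maximum
#' tolerable chronic dose (RfD, used interchangeably with HBGV).
#' Vectorised.
#'
#' @param edi Estimated daily intake, mg/kg bw/day (>= 0).
#' @param rfd Reference dose, mg/kg bw/day (> 0).
#' @return Dimensionless hazard quotient.
#' @examples
#' compute_hq(4.1667e-4, 1e-3)
#' @export
compute_hq <- function(edi, rfd) {
  if (any(!is.finite(edi)) || any(edi < 0)) {
    stop_field("edi", "must be finite and >= 0")
  }
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop_field("rfd", "must be finite and > 0")
  }
  edi / rfd
}

#' Hazard label from a hazard quotient
#'
#' `TRUE` iff HQ strictly exceeds 1. HQ values less than or equal to 1 are
#' within the acceptable range; the boundary HQ = 1 is acceptable.
#'
#' @param hq Hazard quotient (>= 0). Vectorised.
#' @return Logical vector.
#' @examples
#' classify_hazard(c(0.5, 1, 1.0000001))
#' @export
classify_hazard <- function(hq) {
  if (any(!is.finite(hq)) || any(hq < 0)) {
    stop_field("hq", "must be finite and >= 0")
  }
  hq > 1
}

#' Maximum safe intake (ADI)
#'
#' The acceptable daily intake here is the consumption rate (g/day) at which
#' the hazard quotient reaches exactly 1 for the given concentration and
#' body weight: ADI = RfD x BW / (C x 10^-3). By construction,
#' `compute_hq(compute_edi(c, adi, bw), rfd) == 1`. A concentration of zero
#' admits no finite bound; it is signalled as a classed error condition
#' (`aquarisk_unbounded_intake`) rather than returned as a number.
#'
#' @param rfd Reference dose, mg/kg bw/day (> 0).
#' @param body_weight Body weight, kg (> 0).
#' @param concentration Concentration, mg/kg (> 0).
#' @return ADI in g/day. Vectorised.
#' @examples
#' compute_adi(1e-3, 60, 1.25)   # 48 g/day
#' @export
compute_adi <- function(rfd, body_weight, concentration) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop_field("rfd", "must be finite and > 0")
  }
  if (any(!is.finite(body_weight)) || any(body_weight <= 0)) {
    stop_field("body_weight", "must be finite and > 0")
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop_field("concentration", "must be finite and >= 0")
  }
  if (any(concentration == 0)) {
    stop(structure(
      class = c("aquarisk_unbounded_intake", "error", "condition"),
      list(message = paste(
        "concentration is 0: no finite intake reaches HQ = 1",
        "(unbounded safe intake)"), call = sys.call(-1))
    ))
  }
  rfd * body_weight / (concentration * 1e-3)
}

#' Build labelled instances for one metal's hazard tree
#'
#' One instance per (subject, category) pair with positive intake: the
#' feature vector is (category, body weight, intake); the class label is
#' the hazard flag HQ > 1 computed from the supplied per-category
#' concentration and the metal's reference dose. HQ, EDI and ADI are carried
#' along for reporting but are never used as tree features (the label is a
#' deterministic function of HQ, so using them would leak the label).
#'
#' @param subjects Subject tibble from [generate_population()] or
#'   [read_subjects()].
#' @param concentration_by_category Named numeric, mg/kg, one entry per
#'   category consumed by any subject. Scalars recycle per category; supply
#'   the category means from [metal_concentration_table()] for the
#'   deterministic mode, or per-instance draws for a Monte Carlo assessment
#'   (see [assess_exposure()]).
#' @param rfd Reference dose for the metal, mg/kg bw/day.
#' @param metal Metal identifier (kept on each instance).
#' @return A tibble with columns `subject_id`, `metal`, `category`, `bw`,
#'   `intake`, `concentration`, `edi`, `hq`, `label`.
#' @export
build_instances <- function(subjects, concentration_by_category, rfd, metal) {
  check_subjects(subjects)
  check_metal(metal)
  check_scalar_number(rfd, "rfd", positive = TRUE)
  cats <- category_vocabulary()
  long <- do.call(rbind, lapply(cats, function(cat) {
    intake <- subjects[[paste0(cat, "_g_per_day")]]
    keep <- intake > 0
    if (!any(keep)) return(NULL)
    data.frame(
      subject_id = subjects$subject_id[keep],
      category = cat,
      bw = subjects$body_weight_kg[keep],
      intake = intake[keep],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(long)) {
    return(tibble::tibble(
      subject_id = character(), metal = character(), category = character(),
      bw = numeric(), intake = numeric(), concentration = numeric(),
      edi = numeric(), hq = numeric(), label = logical()
    ))
  }
  consumed <- unique(long$category)
  missing <- setdiff(consumed, names(concentration_by_category))
  if (length(missing)) {
    stop_field("concentration_by_category",
               paste("no concentration for consumed categories:",
                     paste(missing, collapse = ", ")))
  }
  conc <- unname(unlist(concentration_by_category)[long$category])
  edi <- compute_edi(conc, long$intake, long$bw)
  hq <- compute_hq(edi, rfd)
  tibble::tibble(
    subject_id = long$subject_id,
    metal = metal,
    category = long$category,
    bw = long$bw,
    intake = long$intake,
    concentration = conc,
    edi = edi,
    hq = hq,
    label = classify_hazard(hq)
  )
}

#' Full exposure assessment
#'
#' Evaluates every (subject, metal, category) combination with positive
#' intake: concentration, EDI, HQ, the hazard flag, and the maximum safe
#' intake ADI. Concentrations are either the per-category means of
#' `conc_table` (`concentration = "mean"`, the default) or per-instance
#' lognormal draws matched to the table's moments
#' (`concentration = "sample"`, seeded).
#'
#' @param subjects Subject tibble.
#' @param conc_table Concentration table in the layout of
#'   [metal_concentration_table()].
#' @param rfd_table Reference-dose tibble (`metal`, `rfd`), e.g.
#'   [reference_dose_table()].
#' @param metals Metals to assess (default: all in `rfd_table`).
#' @param concentration `"mean"` or `"sample"`.
#' @param seed Seed for the `"sample"` mode.
#' @return A tibble with one row per exposure record: `subject_id`, `metal`,
#'   `category`, `conc_mg_kg`, `edi`, `hq`, `hazardous`, `adi_g_day`, plus
#'   the features `bw` and `intake`.
#' @examples
#' subjects <- generate_population(population_spec(n_subjects = 20, seed = 1))
#' head(assess_exposure(subjects, metals = "Cd"))
#' @export
assess_exposure <- function(subjects,
                            conc_table = metal_concentration_table(),
                            rfd_table = reference_dose_table(),
                            metals = rfd_table$metal,
                            concentration = c("mean", "sample"),
                            seed = 1L) {
  concentration <- match.arg(concentration)
  out <- vector("list", length(metals))
  for (i in seq_along(metals)) {
    metal <- metals[i]
    prof <- conc_table[conc_table$metal == metal, , drop = FALSE]
    if (nrow(prof) == 0L) {
      stop_field("conc_table", paste("no profiles for metal", metal))
    }
    conc_by_cat <- stats::setNames(prof$mean, prof$category)
    inst <- build_instances(subjects, conc_by_cat,
                            rfd_for(rfd_table, metal), metal)
    if (concentration == "sample" && nrow(inst) > 0L) {
      # one seeded draw per instance, streamed per category profile
      for (cat in unique(inst$category)) {
        rows <- which(inst$category == cat)
        p <- prof[prof$category == cat, , drop = FALSE]
        sub_seed <- (as.integer(seed) + 7919L * i +
                       match(cat, category_vocabulary())) %% .Machine$integer.max
        inst$concentration[rows] <-
          sample_concentrations(p, length(rows), seed = sub_seed)
      }
      inst$edi <- compute_edi(inst$concentration, inst$intake, inst$bw)
      inst$hq <- compute_hq(inst$edi, rfd_for(rfd_table, metal))
      inst$label <- classify_hazard(inst$hq)
    }
    inst$adi_g_day <- if (nrow(inst)) {
      compute_adi(rfd_for(rfd_table, metal), inst$bw, inst$concentration)
    } else numeric(0)
    out[[i]] <- inst
  }
  res <- do.call(rbind, out)
  names(res)[names(res) == "concentration"] <- "conc_mg_kg"
  names(res)[names(res) == "label"] <- "hazardous"
  res[c("subject_id", "metal", "category", "conc_mg_kg", "edi", "hq",
        "hazardous", "adi_g_day", "bw", "intake")]
}

#' Write an exposure-record table as CSV
#'
#' Columns `subject_id,metal,category,conc_mg_kg,edi,hq,hazardous,adi_g_day`.
#'
#' @param records Tibble from [assess_exposure()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_exposure <- function(records, path) {
  cols <- c("subject_id", "metal", "category", "conc_mg_kg",
            "edi", "hq", "hazardous", "adi_g_day")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop_field("records", paste("missing columns:",
                                paste(missing, collapse = ", ")))
  }
  utils::write.csv(records[, union(cols, names(records))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
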