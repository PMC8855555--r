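# Reference doses (RfD / health-based guidance values), mg/kg bw/day.

#' Default reference-dose table
#'
#' Chronic oral reference doses (RfD, mg/kg bw/day) for the twelve metals,
#' with a source label per entry. RfD and HBGV (health-based guidance value)
#' are treated as one quantity throughout the package. These defaults are a
#' convenience populated from public regulatory sources (USEPA IRIS where an
#' oral RfD exists, otherwise PPRTV/HEAST provisional values; lead uses the
#' former JECFA PTWI converted to a daily dose, kept only so every metal has
#' a screening value). Any study use should pass an explicit table reviewed
#' for that study, e.g. via [read_rfd()].
#'
#' @return A tibble with columns `metal`, `rfd` (mg/kg bw/day), `source`.
#' @examples
#' reference_dose_table()
#' @export
reference_dose_table <- function() {
  tibble::tibble(
    metal = c("iAs", "Cd", "Co", "Cr", "Cu", "Fe",
              "Mn", "Ni", "Pb", "Sr", "Tl", "Zn"),
    rfd = c(3e-4, 1e-3, 3e-4, 1.5, 4e-2, 7e-1,
            1.4e-1, 2e-2, 3.5e-3, 6e-1, 1e-5, 3e-1),
    source = c(
      "USEPA IRIS, inorganic arsenic oral RfD",
      "USEPA IRIS, cadmium (food) oral RfD",
      "USEPA PPRTV, cobalt provisional oral RfD",
      "USEPA IRIS, chromium(III) oral RfD (dietary Cr assumed trivalent)",
      "USEPA HEAST, copper provisional oral RfD",
      "USEPA PPRTV, iron provisional oral RfD",
      "USEPA IRIS, manganese oral RfD (diet)",
      "USEPA IRIS, nickel soluble salts oral RfD",
      "former JECFA PTWI 25 ug/kg bw/week / 7 (no current RfD for lead)",
      "USEPA IRIS, strontium oral RfD",
      "USEPA PPRTV, thallium soluble salts provisional oral RfD",
      "USEPA IRIS, zinc oral RfD"
    )
  )
}

#' Read a reference-dose table from YAML or JSON
#'
#' Expected layout: `metal: {rfd: <mg/kg bw/day>, source: <text>}` per
#' entry. Every RfD must be positive; a full 12-metal assessment requires
#' all 12 metals to be present.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A tibble with columns `metal`, `rfd`, `source`.
#' @export
read_rfd <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  metals <- names(raw)
  bad <- setdiff(metals, metal_vocabulary())
  if (length(bad)) {
    stop_field("path", paste("unknown metals:", paste(bad, collapse = ", ")))
  }
  rfd <- vapply(raw, function(e) as.numeric(e$rfd), numeric(1))
  if (any(!is.finite(rfd) | rfd <= 0)) {
    stop_field("rfd", "every reference dose must be a positive number")
  }
  src <- vapply(raw, function(e) {
    if (is.null(e$source)) NA_character_ else as.character(e$source)
  }, character(1))
  tibble::tibble(metal = metals, rfd = unname(rfd), source = unname(src))
}

rfd_for <- function(rfd_table, metal) {
  i <- match(metal, rfd_table$metal)
  if (is.na(i)) stop_field("rfd_table", paste("no reference dose for", metal))
  rfd_table$rfd[i]
}
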