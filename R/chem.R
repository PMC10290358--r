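# Reference chemistry of dry-reed samples from Brates Lake (Romania),
# packaged as plain-CSV fixtures: EDX elemental composition (wt%) of control
# vs water-kept stems, pH/conductivity/soluble salts of aqueous reed
# extracts, and the published analyte concentration ranges. Plus the
# conductometric cell-constant formula used to calibrate the conductivity
# measurements.

chem_path <- function(file) {
  p <- system.file("extdata", file, package = "reedcover")
  if (!nzchar(p)) stop("fixture missing from package: ", file)
  p
}

#' Load a packaged reed-chemistry table
#'
#' Tables: `"edx"` — elemental composition in wt% for four sample columns
#' (control/water-kept x epiderm/cross-section); `"extract"` — pH,
#' electrical conductivity (mS/cm) and soluble salts (g/L) of three aqueous
#' reed extracts; `"ranges"` — published concentration ranges per analyte
#' with units. Type invariants are validated on load; for the EDX table each
#' sample column's wt% sum is checked against 100 within 0.5 and the maximum
#' deviation is attached as attribute `max_column_deviation`.
#'
#' @param name One of `"edx"`, `"extract"`, `"ranges"`.
#' @return A data frame of typed records.
#' @export
load_chem_table <- function(name = c("edx", "extract", "ranges")) {
  name <- match.arg(name)
  file <- switch(name, edx = "edx_composition.csv",
                 extract = "extract_chemistry.csv",
                 ranges = "printed_ranges.csv")
  tab <- utils::read.csv(chem_path(file), stringsAsFactors = FALSE)
  if (name == "edx") {
    cols <- c("control_epiderm", "control_cross_section",
              "water_epiderm", "water_cross_section")
    if (!identical(names(tab), c("element", cols)))
      stop("EDX fixture is corrupt: unexpected columns")
    if (any(as.matrix(tab[cols]) < 0))
      stop("EDX fixture is corrupt: negative wt%")
    sums <- colSums(tab[cols])
    dev <- abs(sums - 100)
    if (any(dev > 0.5))
      stop("EDX column sum deviates from 100 wt% by more than 0.5: ",
           paste(cols[dev > 0.5], round(sums[dev > 0.5], 2), collapse = ", "))
    attr(tab, "column_sums") <- sums
    attr(tab, "max_column_deviation") <- max(dev)
  } else if (name == "extract") {
    if (!identical(names(tab), c("sample_id", "pH", "conductivity_mS_cm",
                                 "soluble_salts_g_L")))
      stop("extract fixture is corrupt: unexpected columns")
    if (any(tab$pH <= 0 | tab$pH >= 14) || any(tab$conductivity_mS_cm <= 0) ||
        any(tab$soluble_salts_g_L <= 0))
      stop("extract fixture is corrupt: values out of physical range")
  } else {
    if (any(tab$lo > tab$hi))
      stop("ranges fixture is corrupt: lo > hi after normalisation")
  }
  tab
}

#' Exact min and max of a table field
#'
#' @param records Nonempty data frame of typed records, e.g. from
#'   [load_chem_table()].
#' @param field Column name.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @examples
#' range_summary(load_chem_table("extract"), "pH") # 4.91 .. 4.98
#' @export
range_summary <- function(records, field) {
  if (nrow(records) == 0L) stop("records must be nonempty")
  if (!field %in% names(records)) stop("no such field: ", field)
  x <- records[[field]]
  c(min = min(x), max = max(x))
}

#' Conductometric cell constant from two KCl standards
#'
#' The cell constant of a conductometric cell is calibrated against two
#' potassium chloride standard solutions (0.1 n and 0.01 n): each standard
#' gives a partial constant `k_i = gamma_i / c_i` — its known specific
#' conductivity over the measured conductivity — and the cell constant is
#' their mean, `k = (gamma1/c1 + gamma2/c2) / 2`.
#'
#' @param gamma1,gamma2 Specific conductivities (cm^-1) of the 0.1 n and
#'   0.01 n KCl solutions; strictly positive.
#' @param c1,c2 Measured electrical conductivities of the two solutions (in
#'   the instrument's readout units); strictly positive.
#' @return The cell constant `k`, strictly positive.
#' @examples
#' cell_constant(gamma1 = 2, c1 = 1, gamma2 = 1, c2 = 1) # 1.5
#' @export
cell_constant <- function(gamma1, c1, gamma2, c2) {
  vals <- c(gamma1 = gamma1, c1 = c1, gamma2 = gamma2, c2 = c2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all inputs must be strictly positive: ",
         paste(names(vals)[vals <= 0 | !is.finite(vals)], collapse = ", "))
  (gamma1 / c1 + gamma2 / c2) / 2
}
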