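#' Built-in covariate catalogue for the two acid-grassland surveys
#'
#' Reference metadata for the covariates of the two UK acid-grassland
#' gradient surveys the package emulates: the 1998 Countryside Survey subset
#' ("mea10", 883 scattered plots) and the 68-site stratified deposition-
#' gradient survey ("sea04", 5 plots per site). For each covariate: role,
#' original units and range, the rescaling divisor, and which model sets use
#' it. The rescaled range is always `original range / divisor`; endpoints
#' reported at 2 decimals. (The published lower endpoint of the sea04
#' 1996-2006 precipitation is a typo, 0.42 for 604.9/250 = 2.42; the
#' catalogue stores the self-consistent value.)
#'
#' @param study `"mea10"`, `"sea04"`, or `"all"`
#' @return data frame with columns `name`, `role`, `units`, `divisor`,
#'   `orig_lo`, `orig_hi`, `resc_lo`, `resc_hi`, `study`, `model_set`
#' @export
covariate_catalogue <- function(study = c("all", "mea10", "sea04")) {
  study <- match.arg(study)
  row <- function(name, role, units, div, lo, hi, st, set) {
    data.frame(name = name, role = role, units = units, divisor = div,
               orig_lo = lo, orig_hi = hi,
               resc_lo = round(lo / div, 2), resc_hi = round(hi / div, 2),
               study = st, model_set = set)
  }
  cat <- rbind(
    row("ndep_total",    "pollutant",  "kg ha-1 yr-1",     1,   4.9,    40.0,   "mea10", "m1"),
    row("sdep_change",   "pollutant",  "delta kg S ha-1 yr-1", 1, -5.36, 0.00,  "mea10", "m1"),
    row("altitude",      "terrain",    "m",                100, 0,      975,    "mea10", "m1"),
    row("temp_min_jan",  "climate",    "deg C",            1,   -8.16,  0.08,   "mea10", "m1"),
    row("temp_max_jul",  "climate",    "deg C",            1,   14.11,  26.67,  "mea10", "m1"),
    row("precip",        "climate",    "mm",               250, 554.33, 3305.80,"mea10", "m1"),
    row("sheep_change",  "management", "delta sheep yr-1", 10,  -11.19, 88.47,  "mea10", "m1"),
    row("precip",        "climate",    "mm",               250, 604.9,  1773.3, "sea04", "m1"),
    row("temp_max",      "climate",    "deg C",            1,   11.5,   14.6,   "sea04", "m1"),
    row("temp_min",      "climate",    "deg C",            1,   4.2,    8.1,    "sea04", "m1"),
    row("soil_al",       "soil",       "mg kg-1 dry soil", 200, 11.60,  1318.75,"sea04", "m1"),
    row("sdep_total",    "pollutant",  "kg ha-1 yr-1",     1,   3.20,   13.44,  "sea04", "m1+m2"),
    row("ndep_total",    "pollutant",  "kg ha-1 yr-1",     1,   7.70,   40.86,  "sea04", "m1+m2"),
    row("soil_ph",       "soil",       "pH unit",          0.5, 3.69,   5.37,   "sea04", "m1+m2"),
    row("altitude",      "terrain",    "m",                100, 15,     500,    "sea04", "m1+m2"),
    row("climate_pc1",   "climate",    "",                 1,   -4.90,  3.43,   "sea04", "m2"),
    row("climate_pc2",   "climate",    "",                 1,   -1.47,  1.20,   "sea04", "m2"),
    row("cn_ratio",      "soil",       "topsoil mass ratio", 1, 13.34,  30.58,  "sea04", "m2"),
    row("slope",         "terrain",    "degrees",          10,  0,      60,     "sea04", "m2"),
    row("soil_n",        "soil",       "topsoil %N",       1,   0.12,   1.57,   "sea04", "m2"),
    row("smd",           "climate",    "mm",               10,  1.66,   48.94,  "sea04", "m2")
  )
  if (study != "all") cat <- cat[cat$study == study, , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Covariate specs for a catalogue study
#'
#' @param study `"mea10"` or `"sea04"`
#' @return named list of [covariate_spec()]s
#' @export
catalogue_specs <- function(study) {
  cat <- covariate_catalogue(study)
  sp <- lapply(seq_len(nrow(cat)), function(i) {
    covariate_spec(cat$name[i], divisor = cat$divisor[i], role = cat$role[i],
                   original_units = cat$units[i])
  })
  setNames(sp, cat$name)
}
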