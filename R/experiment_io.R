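# Conversion of raw hydrolysate measurements (HPLC concentrations, g/L)
# into yield-% observations, and the tidy experiment CSV dialect.

MW_ANHYDROXYLOSE <- 132.115   # g/mol per chain unit
MW_WATER <- 18.02             # g/mol, terminal water of hydration
WATER_DENSITY_25C <- 997.047  # kg/m^3

#' Molecular weight of a xylo-oligomer
#'
#' `MW(X_i) = 132.115 i + 18.02` g/mol: `i` anhydroxylose units plus one
#' terminal water.
#'
#' @param i Degree of polymerisation.
#' @return Molecular weight (g/mol).
#' @export
oligomer_mw <- function(i) MW_ANHYDROXYLOSE * i + MW_WATER

#' A bagasse sample loaded into the reaction cell
#'
#' @param dry_mass_g Dry mass of the sample (g).
#' @param xylan_fraction Xylan mass fraction of the dry material.
#' @return An object of class `bagasse_sample`.
#' @examples
#' bagasse_sample(4.68, 0.202)
#' @export
bagasse_sample <- function(dry_mass_g = 4.68, xylan_fraction = 0.202) {
  stopifnot("dry mass must be positive" = dry_mass_g > 0,
            "xylan fraction must be in (0, 1)" =
              xylan_fraction >= 0 && xylan_fraction < 1)
  structure(list(dry_mass_g = dry_mass_g, xylan_fraction = xylan_fraction),
            class = "bagasse_sample")
}

#' Initial xylan mass of a sample
#'
#' @param sample A [bagasse_sample()].
#' @return Initial xylan mass `X0` (g).
#' @examples
#' initial_xylan_mass(bagasse_sample(4.68, 0.202))  # 0.94536 g
#' @export
initial_xylan_mass <- function(sample) {
  sample$xylan_fraction * sample$dry_mass_g
}

#' A timed hydrolysate measurement
#'
#' Concentrations of dissolved species in the drained hydrolysate at one
#' time point, with the hydrolysate mass converted to volume using the
#' density of water at 25 degC (997.047 kg/m^3).
#'
#' @param time_min Sampling time (minutes).
#' @param conc_g_per_L Named numeric vector of concentrations (g/L);
#'   names from `X1`..`X6` and `furfural`.
#' @param hydrolysate_mass_g Mass of drained hydrolysate (g).
#' @return An object of class `hydrolysate_record` with the volume (m^3)
#'   precomputed.
#' @export
hydrolysate_record <- function(time_min, conc_g_per_L, hydrolysate_mass_g) {
  stopifnot("time must be non-negative" = time_min >= 0,
            "concentrations must be non-negative" = all(conc_g_per_L >= 0),
            "hydrolysate mass must be positive" = hydrolysate_mass_g > 0)
  parse_species(names(conc_g_per_L), m = 6L)
  structure(list(time_min = time_min, conc_g_per_L = conc_g_per_L,
                 volume_m3 = hydrolysate_mass_g / 1000 / WATER_DENSITY_25C),
            class = "hydrolysate_record")
}

#' Experimental oligomer yield from a hydrolysate record
#'
#' Converts a concentration to xylan-equivalent mass,
#' `1000 * conc * V * (MW(X_i) - MW(H2O)) / MW(X_i)`, removing the water of
#' hydration added on scission, and divides by the initial xylan mass.
#'
#' @param record A [hydrolysate_record()].
#' @param i Degree of polymerisation (1..6).
#' @param X0 Initial xylan mass (g), from [initial_xylan_mass()].
#' @return Yield in % of initial xylan mass.
#' @export
oligomer_yield <- function(record, i, X0) {
  if (i < 1 || i > 6) stop("oligomer DP must be 1..6", call. = FALSE)
  stopifnot("X0 must be positive" = X0 > 0)
  conc <- record$conc_g_per_L[[paste0("X", i)]]
  if (is.null(conc)) stop("record has no X", i, " concentration",
                          call. = FALSE)
  mw <- oligomer_mw(i)
  mass_g <- 1000 * conc * record$volume_m3 * (mw - MW_WATER) / mw
  100 * mass_g / X0
}

#' Experimental furfural yield from a hydrolysate record
#'
#' Furfural mass is scaled by 132/96 (xylan-equivalent mass per furfural)
#' before dividing by the initial xylan mass.
#'
#' @inheritParams oligomer_yield
#' @return Yield in % of initial xylan mass.
#' @export
furfural_yield <- function(record, X0) {
  stopifnot("X0 must be positive" = X0 > 0)
  conc <- record$conc_g_per_L[["furfural"]]
  if (is.null(conc)) stop("record has no furfural concentration",
                          call. = FALSE)
  100 * 1000 * conc * record$volume_m3 * (132 / 96) / X0
}

#' Read and write experiment observation CSV
#'
#' The dialect is tidy: columns `time_min`, `species`, `value`,
#' `value_kind`, with `value_kind` either `yield_pct` (value is a yield in
#' %) or `conc_g_per_L` (value is an HPLC concentration; such rows also
#' require a `volume_ml` column and a `sample` argument, and are converted
#' to yields on read).
#'
#' @param path CSV file path.
#' @param sample A [bagasse_sample()], required when concentration rows are
#'   present.
#' @return `read_experiment`: data.frame `species`, `time_min`,
#'   `yield_pct`. `write_experiment` returns `path` invisibly.
#' @export
read_experiment <- function(path, sample = NULL) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  need <- c("time_min", "species", "value", "value_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("experiment CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- df$species == "furfural" | grepl("^X[1-6]$", df$species)
  if (any(!ok))
    stop("unknown species label(s) at data line(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(df$species[!ok]), collapse = ", "), call. = FALSE)
  bad_kind <- !(df$value_kind %in% c("yield_pct", "conc_g_per_L"))
  if (any(bad_kind))
    stop("unknown value_kind at data line(s) ",
         paste(which(bad_kind), collapse = ", "), call. = FALSE)
  yield <- df$value
  conc <- df$value_kind == "conc_g_per_L"
  if (any(conc)) {
    if (!("volume_ml" %in% names(df)))
      stop("concentration rows require a volume_ml column", call. = FALSE)
    if (is.null(sample))
      stop("concentration rows require a bagasse_sample for conversion",
           call. = FALSE)
    X0 <- initial_xylan_mass(sample)
    for (r in which(conc)) {
      rec <- hydrolysate_record(
        df$time_min[r],
        stats::setNames(df$value[r], df$species[r]),
        hydrolysate_mass_g = df$volume_ml[r] * WATER_DENSITY_25C / 1000)
      yield[r] <- if (df$species[r] == "furfural")
        furfural_yield(rec, X0)
      else oligomer_yield(rec, as.integer(sub("^X", "", df$species[r])), X0)
    }
  }
  data.frame(species = df$species, time_min = df$time_min,
             yield_pct = yield)
}

#' @rdname read_experiment
#' @param series Data.frame `species`, `time_min`, `yield_pct` (as
#'   returned by `read_experiment` or built from [yields()] output).
#' @export
write_experiment <- function(series, path) {
  stopifnot(all(c("species", "time_min", "yield_pct") %in% names(series)))
  out <- data.frame(time_min = series$time_min, species = series$species,
                    value = series$yield_pct, value_kind = "yield_pct")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
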