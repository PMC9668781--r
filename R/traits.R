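#' Gravimetric root dry matter content
#'
#' Dry matter content (%) of fresh cassava roots from the specific-gravity
#' method: a root sample is weighed in air and then submerged in water, and
#' the empirical Kawano regression converts the weight ratio to percent dry
#' matter:
#' \deqn{DMC = 158.3 \frac{W_{air}}{W_{air} - W_{water}} - 142}
#'
#' Because the regression is empirical it can return values outside
#' \[0, 100\] for unusual weight ratios; such values are returned unmodified
#' with a warning rather than clamped, since silent clamping would hide
#' assay errors.
#'
#' @param weight_air sample weight in air (kg), > 0.
#' @param weight_water sample weight submerged in water (kg), >= 0 and
#'   strictly less than `weight_air`.
#' @return numeric vector of dry matter content in percent.
#' @examples
#' dmc_gravimetric(5, 0.528) # about 35 %
#' @export
dmc_gravimetric <- function(weight_air, weight_water) {
  bad <- !is.na(weight_air) & !is.na(weight_water) &
    (weight_air <= weight_water | weight_air <= 0 | weight_water < 0)
  if (any(bad)) {
    stop("dmc_gravimetric: weight_air must exceed weight_water (both >= 0); ",
         sum(bad), " offending value(s)")
  }
  dmc <- 158.3 * weight_air / (weight_air - weight_water) - 142
  out_of_range <- !is.na(dmc) & (dmc < 0 | dmc > 100)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " gravimetric DMC value(s) outside [0, 100]; returned unclamped")
  }
  dmc
}

#' Oven-dry root dry matter content
#'
#' Dry matter content (%) from oven drying at 90 degrees C to constant
#' weight: `100 - humidity`.
#'
#' @param humidity measured moisture content in percent, in \[0, 100\].
#' @return numeric vector, percent dry matter.
#' @export
dmc_oven_dry <- function(humidity) {
  bad <- !is.na(humidity) & (humidity < 0 | humidity > 100)
  if (any(bad)) stop("dmc_oven_dry: humidity must lie in [0, 100]")
  100 - humidity
}

#' Harvest index
#'
#' Root fresh yield as a percentage of total biomass yield:
#' \deqn{HI = 100 \cdot FRY / (FRY + ShY)}
#'
#' @param fry fresh root yield (t/ha), >= 0.
#' @param shy shoot yield (t/ha), >= 0. `fry + shy` must be positive.
#' @return percent in \[0, 100\].
#' @export
harvest_index <- function(fry, shy) {
  bad <- !is.na(fry) & !is.na(shy) & (fry < 0 | shy < 0 | fry + shy <= 0)
  if (any(bad)) {
    stop("harvest_index: fry and shy must be >= 0 with a positive sum")
  }
  100 * fry / (fry + shy)
}

#' Dry root yield
#'
#' Product of fresh root yield and the dry matter fraction,
#' `fry * dmc_grav / 100`, in t/ha.
#'
#' @param fry fresh root yield (t/ha), >= 0.
#' @param dmc_grav gravimetric dry matter content in percent, \[0, 100\].
#' @return dry root yield (t/ha).
#' @export
dry_root_yield <- function(fry, dmc_grav) {
  bad <- (!is.na(fry) & fry < 0) |
    (!is.na(dmc_grav) & (dmc_grav < 0 | dmc_grav > 100))
  if (any(bad)) stop("dry_root_yield: need fry >= 0 and dmc_grav in [0, 100]")
  fry * dmc_grav / 100
}

#' Spectrophotometric total carotenoid content
#'
#' Total carotenoid content of root tissue (micrograms per gram fresh
#' weight) from absorbance at 450 nm of a petroleum-ether extract:
#' \deqn{TCC = \frac{A \cdot V \cdot 10^4}{A^{1\%}_{1cm} \cdot P}}
#' where A is the absorbance, V the total extract volume (mL), P the sample
#' mass (g) and \eqn{A^{1\%}_{1cm}} the extinction coefficient of
#' beta-carotene in petroleum ether, 2592.
#'
#' @param absorbance absorbance units, >= 0.
#' @param extract_volume total extract volume (mL), > 0.
#' @param sample_mass sample fresh mass (g), > 0.
#' @param extinction_coefficient specific absorption coefficient; default
#'   2592 (beta-carotene in petroleum ether).
#' @return carotenoid content in micrograms per gram.
#' @examples
#' tcc_spectro(0.5, 50, 10) # 9.645 ug/g
#' @export
tcc_spectro <- function(absorbance, extract_volume, sample_mass,
                        extinction_coefficient = 2592) {
  bad <- (!is.na(absorbance) & absorbance < 0) |
    (!is.na(extract_volume) & extract_volume <= 0) |
    (!is.na(sample_mass) & sample_mass <= 0)
  if (any(bad)) {
    stop("tcc_spectro: need absorbance >= 0, extract_volume > 0, ",
         "sample_mass > 0")
  }
  if (any(extinction_coefficient <= 0)) {
    stop("tcc_spectro: extinction_coefficient must be > 0")
  }
  absorbance * extract_volume * 1e4 / (extinction_coefficient * sample_mass)
}

#' Plot weight to per-hectare yield
#'
#' Converts a plot-level fresh weight (kg) to t/ha given the plot area in
#' square metres: `weight / 1000 * 10000 / area`.
#'
#' @param plot_weight_kg total plot weight in kg, >= 0.
#' @param plot_area_m2 harvested plot area in square metres, > 0. The
#'   default corresponds to a 20-plant plot at 0.90 m x 0.80 m spacing.
#' @return yield in t/ha.
#' @export
yield_t_ha <- function(plot_weight_kg, plot_area_m2 = 14.4) {
  if (any(!is.na(plot_area_m2) & plot_area_m2 <= 0)) {
    stop("yield_t_ha: plot_area_m2 must be > 0")
  }
  if (any(!is.na(plot_weight_kg) & plot_weight_kg < 0)) {
    stop("yield_t_ha: plot_weight_kg must be >= 0")
  }
  plot_weight_kg / 1000 * 10000 / plot_area_m2
}

#' Average number of roots per plant
#'
#' Total root count in the plot divided by the number of plants actually
#' harvested. Zero harvested plants yields `NA` (not zero): the plot carries
#' no information about root number.
#'
#' @param n_roots total roots counted in the plot, >= 0.
#' @param n_plants_harvested plants harvested in the plot, >= 0.
#' @return roots per plant, `NA` where no plants were harvested.
#' @export
roots_per_plant <- function(n_roots, n_plants_harvested) {
  bad <- (!is.na(n_roots) & n_roots < 0) |
    (!is.na(n_plants_harvested) & n_plants_harvested < 0)
  if (any(bad)) stop("roots_per_plant: counts must be >= 0")
  out <- n_roots / n_plants_harvested
  out[!is.na(n_plants_harvested) & n_plants_harvested == 0] <- NA_real_
  out
}

#' Sweet/bitter cassava classification
#'
#' Classifies cassava by root cyanogenic-compound concentration: sweet
#' cassava has at most 100 mg of cyanogenic compounds per kg, bitter
#' cassava more. Applies to concentrations in mg/kg only, not to the 1-9
#' picrate score used for modelling.
#'
#' @param hcn_mg_per_kg cyanogenic compound concentration, mg/kg, >= 0.
#' @return character vector, `"sweet"` or `"bitter"`.
#' @export
classify_cyanogenic <- function(hcn_mg_per_kg) {
  if (any(!is.na(hcn_mg_per_kg) & hcn_mg_per_kg < 0)) {
    stop("classify_cyanogenic: concentration must be >= 0")
  }
  ifelse(hcn_mg_per_kg <= 100, "sweet", "bitter")
}

#' Derive all traits from raw plot measurements
#'
#' Adds/overwrites the derived trait columns of a plot table from its raw
#' measurement columns. Raw columns used (all optional; a trait is derived
#' only where its inputs are present): `weight_air`, `weight_water`
#' (gravimetric DMC), `humidity` (oven-dry DMC), `plot_root_weight`,
#' `plot_shoot_weight`, `plot_area` (yields; `plot_area` falls back to
#' `default_plot_area`), `n_roots`, `n_plants_harvested` (NRP),
#' `absorbance`, `extract_volume`, `sample_mass` (TCC), and the directly
#' scored `starch_content`, `pulp_color`, `hcn_score`, which pass through
#' as `StC`, `PulpColor` and `HCN`.
#'
#' Derived columns: `DMC.Grav`, `DMC.OD`, `FRY`, `ShY`, `HI`, `DRY`,
#' `NRP`, `TCC`, `StC`, `PulpColor`, `HCN`.
#'
#' @param plots data frame of plot records.
#' @param default_plot_area plot area in m2 used where no `plot_area`
#'   column is present (default 14.4 = 20 plants x 0.90 m x 0.80 m).
#' @return `plots` with derived trait columns appended.
#' @export
derive_traits <- function(plots, default_plot_area = 14.4) {
  stopifnot(is.data.frame(plots))
  has <- function(...) all(c(...) %in% names(plots))
  area <- if (has("plot_area")) {
    ifelse(is.na(plots$plot_area), default_plot_area, plots$plot_area)
  } else {
    rep(default_plot_area, nrow(plots))
  }
  if (has("weight_air", "weight_water")) {
    ok <- !is.na(plots$weight_air) & !is.na(plots$weight_water)
    plots$DMC.Grav <- NA_real_
    if (any(ok)) {
      plots$DMC.Grav[ok] <-
        dmc_gravimetric(plots$weight_air[ok], plots$weight_water[ok])
    }
  }
  if (has("humidity")) plots$DMC.OD <- dmc_oven_dry(plots$humidity)
  if (has("plot_root_weight")) {
    plots$FRY <- yield_t_ha(plots$plot_root_weight, area)
  }
  if (has("plot_shoot_weight")) {
    plots$ShY <- yield_t_ha(plots$plot_shoot_weight, area)
  }
  if (has("FRY", "ShY")) {
    ok <- !is.na(plots$FRY) & !is.na(plots$ShY) & (plots$FRY + plots$ShY > 0)
    plots$HI <- NA_real_
    plots$HI[ok] <- harvest_index(plots$FRY[ok], plots$ShY[ok])
  }
  if (has("FRY", "DMC.Grav")) {
    plots$DRY <- dry_root_yield(plots$FRY, plots$DMC.Grav)
  }
  if (has("n_roots", "n_plants_harvested")) {
    plots$NRP <- roots_per_plant(plots$n_roots, plots$n_plants_harvested)
  }
  if (has("absorbance", "extract_volume", "sample_mass")) {
    plots$TCC <- tcc_spectro(plots$absorbance, plots$extract_volume,
                             plots$sample_mass)
  }
  if (has("starch_content")) plots$StC <- plots$starch_content
  if (has("pulp_color")) plots$PulpColor <- plots$pulp_color
  if (has("hcn_score")) plots$HCN <- plots$hcn_score
  plots
}
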