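#' @title Food composition tables with wheat/rice recipe attribution
#'
#' @description A composition table maps each food code to its energy and
#' iron densities plus the recipe-level wheat and rice content: what
#' fraction of the item's mass is wheat (or rice), what share of that
#' wheat (rice) component is wholegrain (brown), and the iron densities of
#' the refined/wholegrain wheat and white/brown rice components. This is
#' what lets a diary entry be decomposed into wheat-derived, rice-derived,
#' and other mass, energy, and iron.
#'
#' @name composition
NULL

composition_columns <- function() {
  c("food_code", "category", "energy_density", "iron_density",
    "wheat_fraction", "rice_fraction", "wholegrain_share", "brown_share",
    "iron_density_wheat_refined", "iron_density_wheat_whole",
    "iron_density_rice_white", "iron_density_rice_brown")
}

#' Validate a food composition table
#'
#' Checks the structural contract: required columns present, unique food
#' codes, densities non-negative, mass fractions and shares in [0, 1] with
#' wheat + rice fractions summing to at most 1, wholegrain iron density at
#' least the refined one (brown at least white), and the component-implied
#' iron never exceeding the item's total iron density. Violations raise an
#' error naming the offending row and field.
#'
#' @param tab A data frame with the columns of `composition_columns()`.
#' @return The table, invisibly classed `composition_table`.
#' @export
as_composition_table <- function(tab) {
  missing_cols <- setdiff(composition_columns(), names(tab))
  if (length(missing_cols))
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- duplicated(tab$food_code)
  if (any(dup))
    stop("duplicate food_code in row ", which(dup)[1L], ": '",
         tab$food_code[which(dup)[1L]], "'", call. = FALSE)
  num_cols <- setdiff(composition_columns(), c("food_code", "category"))
  for (cl in num_cols) {
    v <- tab[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("column '", cl, "' must be finite numeric", call. = FALSE)
    if (any(v < 0))
      stop("row ", which(v < 0)[1L], ", field '", cl,
           "': negative value", call. = FALSE)
  }
  for (cl in c("wheat_fraction", "rice_fraction",
               "wholegrain_share", "brown_share")) {
    bad <- tab[[cl]] > 1
    if (any(bad))
      stop("row ", which(bad)[1L], ", field '", cl,
           "': value above 1", call. = FALSE)
  }
  bad <- tab$wheat_fraction + tab$rice_fraction > 1 + 1e-12
  if (any(bad))
    stop("row ", which(bad)[1L],
         ": wheat_fraction + rice_fraction exceeds 1", call. = FALSE)
  bad <- tab$iron_density_wheat_whole < tab$iron_density_wheat_refined
  if (any(bad))
    stop("row ", which(bad)[1L],
         ", field 'iron_density_wheat_whole': wholegrain iron density ",
         "below the refined one", call. = FALSE)
  bad <- tab$iron_density_rice_brown < tab$iron_density_rice_white
  if (any(bad))
    stop("row ", which(bad)[1L],
         ", field 'iron_density_rice_brown': brown iron density below ",
         "the white one", call. = FALSE)
  implied <- tab$wheat_fraction * blend_density(tab$wholegrain_share,
                                                tab$iron_density_wheat_whole,
                                                tab$iron_density_wheat_refined) +
    tab$rice_fraction * blend_density(tab$brown_share,
                                      tab$iron_density_rice_brown,
                                      tab$iron_density_rice_white)
  bad <- implied > tab$iron_density + 1e-9
  if (any(bad))
    stop("row ", which(bad)[1L],
         ": component-implied iron exceeds the item iron_density",
         call. = FALSE)
  if (!inherits(tab, "composition_table"))
    class(tab) <- c("composition_table", class(tab))
  invisible(tab)
}

# share-weighted component iron density: s*rho_high + (1-s)*rho_low
blend_density <- function(share, rho_high, rho_low) {
  share * rho_high + (1 - share) * rho_low
}

#' Read a composition table from CSV
#'
#' @param path Path to a CSV file with the documented schema
#'   (`composition_columns()`), UTF-8, header row, '.' decimal separator.
#' @return A validated `composition_table`.
#' @export
load_composition_table <- function(path) {
  if (!file.exists(path))
    stop("composition file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_composition_table(tab)
}

#' Write a composition table to CSV
#'
#' @param tab A `composition_table`.
#' @param path Output path.
#' @export
write_composition_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Decompose a consumed item into wheat, rice, and other components
#'
#' For `grams` of one food: the wheat-derived mass is
#' `grams * wheat_fraction`; its iron is that mass times the
#' share-weighted component density
#' `wholegrain_share * rho_whole + (1 - wholegrain_share) * rho_refined`
#' (rice analogously with brown/white); component energy is the component
#' mass times the item energy density (mass-proportional attribution);
#' "other" takes the remainder so that mass, energy, and iron are each
#' conserved. A residual "other iron" more negative than rounding noise
#' (1e-9) is clamped to zero with a warning.
#'
#' @param record One row of a `composition_table` (data frame or list).
#' @param grams Mass consumed, g (>= 0; vectorised).
#' @return A data frame with columns `wheat_g`, `rice_g`, `other_g`,
#'   `wheat_kcal`, `rice_kcal`, `other_kcal`, `wheat_iron_mg`,
#'   `rice_iron_mg`, `other_iron_mg`, one row per element of `grams`.
#' @export
#' @examples
#' rec <- list(food_code = "bread", category = "cereal",
#'   energy_density = 2.7, iron_density = 0.009,
#'   wheat_fraction = 0.7, rice_fraction = 0, wholegrain_share = 0,
#'   brown_share = 0, iron_density_wheat_refined = 0.01,
#'   iron_density_wheat_whole = 0.02, iron_density_rice_white = 0.004,
#'   iron_density_rice_brown = 0.012)
#' decompose_item(rec, 100)
decompose_item <- function(record, grams) {
  if (any(grams < 0))
    stop("grams must be >= 0", call. = FALSE)
  wheat_g <- grams * record$wheat_fraction
  rice_g <- grams * record$rice_fraction
  other_g <- grams - wheat_g - rice_g
  wheat_iron <- wheat_g * blend_density(record$wholegrain_share,
                                        record$iron_density_wheat_whole,
                                        record$iron_density_wheat_refined)
  rice_iron <- rice_g * blend_density(record$brown_share,
                                      record$iron_density_rice_brown,
                                      record$iron_density_rice_white)
  other_iron <- grams * record$iron_density - wheat_iron - rice_iron
  if (any(other_iron < -1e-9))
    warning("component iron exceeds item iron for food '",
            record$food_code, "'; residual clamped to 0", call. = FALSE)
  other_iron <- pmax(other_iron, 0)
  data.frame(
    wheat_g = wheat_g, rice_g = rice_g, other_g = other_g,
    wheat_kcal = wheat_g * record$energy_density,
    rice_kcal = rice_g * record$energy_density,
    other_kcal = other_g * record$energy_density,
    wheat_iron_mg = wheat_iron, rice_iron_mg = rice_iron,
    other_iron_mg = other_iron
  )
}
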