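# Diisocyanate species: molecular constants and NCO mass conversion.

# Monoisotopic-independent standard atomic masses give the NCO group
# (N + C + O) a mass of 42.017 g/mol; molecular weights in the packaged
# species table are computed from the molecular formulas with the same
# standard masses (MDI 250.25, TDI 174.16, HDI 168.20, IPDI 222.28 g/mol).
NCO_GROUP_MASS <- 42.017

#' Table of supported diisocyanate species
#'
#' Returns the packaged species table: molecular formula and weight, number
#' of isocyanate (NCO) groups (two for every diisocyanate), and the urinary
#' diamine metabolite each species hydrolyses to (MDI -> MDA, TDI -> TDA,
#' HDI -> HDA, IPDI -> IPDA).
#'
#' @return data.frame with columns `name`, `formula`, `molecular_weight`
#'   (g/mol), `n_nco_groups`, `metabolite`, `nco_fraction`.
#' @export
#' @examples
#' species_table()
species_table <- function() {
  tab <- utils::read.csv(pkg_extdata("di_species.csv"),
                         stringsAsFactors = FALSE)
  tab$nco_fraction <- tab$n_nco_groups * NCO_GROUP_MASS / tab$molecular_weight
  tab
}

#' Look up one diisocyanate species
#'
#' @param name species identifier, one of `"MDI"`, `"TDI"`, `"HDI"`,
#'   `"IPDI"` (case-insensitive).
#' @return a `di_species` list with fields `name`, `molecular_weight`,
#'   `n_nco_groups`, `metabolite`, `nco_fraction`.
#' @export
#' @examples
#' di_species("HDI")$nco_fraction
di_species <- function(name) {
  tab <- species_table()
  i <- match(toupper(name), tab$name)
  if (is.na(i)) {
    stop("unknown diisocyanate species: '", name,
         "' (supported: ", paste(tab$name, collapse = ", "), ")")
  }
  sp <- as.list(tab[i, ])
  stopifnot(sp$molecular_weight > 0, sp$n_nco_groups >= 1,
            sp$nco_fraction > 0, sp$nco_fraction < 1)
  class(sp) <- "di_species"
  sp
}

#' @export
print.di_species <- function(x, ...) {
  cat(sprintf("<di_species> %s (%s, %.2f g/mol, %d NCO groups, %.1f%% NCO, metabolite %s)\n",
              x$name, x$formula, x$molecular_weight, x$n_nco_groups,
              100 * x$nco_fraction, x$metabolite))
  invisible(x)
}

#' Convert a diisocyanate air concentration to NCO mass
#'
#' Air levels of different diisocyanates are made comparable by expressing
#' the concentration as the mass of reactive isocyanate (NCO) groups:
#' ug NCO/m3 = ug DI/m3 x (mass of NCO groups / molecular weight).
#'
#' @param conc numeric vector, ug DI/m3 (>= 0).
#' @param species a `di_species` object or species name.
#' @return numeric vector, ug NCO/m3.
#' @export
#' @examples
#' convert_di_to_nco(100, "MDI")   # ~33.6
#' convert_di_to_nco(97.7, "HDI")  # ~48.8
convert_di_to_nco <- function(conc, species) {
  if (!inherits(species, "di_species")) species <- di_species(species)
  if (any(conc < 0, na.rm = TRUE)) stop("air concentration must be >= 0")
  conc * species$nco_fraction
}

#' Convert an NCO-mass air concentration back to the parent diisocyanate
#'
#' @param conc numeric vector, ug NCO/m3 (>= 0).
#' @inheritParams convert_di_to_nco
#' @return numeric vector, ug DI/m3.
#' @export
convert_nco_to_di <- function(conc, species) {
  if (!inherits(species, "di_species")) species <- di_species(species)
  if (any(conc < 0, na.rm = TRUE)) stop("air concentration must be >= 0")
  conc / species$nco_fraction
}

#' Occupational exposure limits for diisocyanates, as NCO
#'
#' The Finnish short-term (15-min) OEL is 35 ug NCO/m3; the proposed EU
#' binding OEL is 10 ug NCO/m3, tightening to 6 ug NCO/m3 from 2029.
#'
#' @return named list (`short_term_fi`, `proposed_boel`,
#'   `proposed_boel_2029`), all in ug NCO/m3.
#' @export
oel_thresholds <- function() {
  defaults <- yaml::read_yaml(pkg_extdata("defaults.yaml"))
  oel <- defaults$oel_ug_nco_m3
  stopifnot(all(unlist(oel) > 0))
  oel
}
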