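#' Cell model for stoichiometric budgeting
#'
#' Holds the two cell-level constants the per-cell budget needs: the dry
#' weight of a single cell (femtograms) and the growth-associated ATP
#' maintenance cost (GAM, mmol ATP per gram dry weight for one duplication).
#' Defaults are 280 fg/cell (copiotrophic bacterium growing exponentially on
#' glucose) and 85 mmol ATP/gDW (from a genome-scale metabolic model).
#'
#' @param dry_weight_fg Dry weight per cell, fg (> 0).
#' @param gam_mmol_per_gdw Growth-associated ATP maintenance, mmol/gDW (> 0).
#' @return A `cell_model` list.
#' @export
cell_model <- function(dry_weight_fg = 280, gam_mmol_per_gdw = 85) {
  if (dry_weight_fg <= 0 || gam_mmol_per_gdw <= 0) {
    stop("dry weight and GAM must both be positive")
  }
  structure(list(dry_weight_fg = dry_weight_fg,
                 gam_mmol_per_gdw = gam_mmol_per_gdw),
            class = "cell_model")
}

#' Convert a per-dry-weight amount to a per-cell amount
#'
#' Dimensional identity: 1 mmol/g times 1 fg equals exactly 1 amol
#' (10^-3 mol/g x 10^-15 g = 10^-18 mol), so the per-cell amount in
#' attomoles is simply `amount_mmol_per_g * dry_weight_fg`.
#'
#' @param amount_mmol_per_g Amount per gram dry weight, mmol/g (>= 0).
#' @param cell A [cell_model()].
#' @return Amount per cell, amol.
#' @export
per_cell_amount <- function(amount_mmol_per_g, cell = cell_model()) {
  if (any(amount_mmol_per_g < 0)) stop("amount must be non-negative")
  amount_mmol_per_g * cell$dry_weight_fg
}

#' Dissimilatory ATP requirement per cell duplication
#'
#' The GAM of the cell model converted to a per-cell amount:
#' with the defaults (85 mmol/gDW, 280 fg) this is 23,800 amol ATP per cell.
#'
#' @param cell A [cell_model()].
#' @return ATP requirement, amol/cell.
#' @export
atp_requirement <- function(cell = cell_model()) {
  per_cell_amount(cell$gam_mmol_per_gdw, cell)
}

#' Build a table of one-carbon sinks
#'
#' A C1 sink is a biosynthetic end point that consumes one-carbon groups:
#' the canonical seven in a heterotrophic bacterium are ATP, GTP, dATP,
#' dGTP, dTTP, histidine and methionine. Each row records the per-cell
#' amount of the sink metabolite and the net number of C1 groups
#' incorporated per molecule.
#'
#' @param name Sink labels.
#' @param amount_per_cell_amol Per-cell amount of each sink, amol (>= 0).
#' @param c1_per_molecule Net C1 groups per molecule (integer >= 1).
#' @return A data frame of class `c1_sinks`.
#' @export
c1_sinks <- function(name, amount_per_cell_amol, c1_per_molecule) {
  if (length(name) == 0L) stop("sink table must not be empty")
  if (any(amount_per_cell_amol < 0)) stop("sink amounts must be non-negative")
  if (any(c1_per_molecule < 1)) stop("each sink must consume at least 1 C1 group")
  out <- data.frame(name = name,
                    amount_per_cell_amol = amount_per_cell_amol,
                    c1_per_molecule = as.integer(c1_per_molecule),
                    stringsAsFactors = FALSE)
  class(out) <- c("c1_sinks", "data.frame")
  out
}

#' Read a C1-sink table from CSV
#'
#' Accepts either per-cell amounts (`amount_per_cell_amol`) or per-dry-weight
#' amounts (`amount_mmol_per_gdw`, converted via the cell model).
#'
#' @param path CSV with columns `name`, `c1_per_molecule` and one of the two
#'   amount columns.
#' @param cell A [cell_model()], used only for the per-dry-weight dialect.
#' @return A `c1_sinks` table.
#' @export
read_c1_sinks <- function(path, cell = cell_model()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  amount <- if ("amount_per_cell_amol" %in% names(df)) {
    df$amount_per_cell_amol
  } else if ("amount_mmol_per_gdw" %in% names(df)) {
    per_cell_amount(df$amount_mmol_per_gdw, cell)
  } else {
    stop("sink CSV needs amount_per_cell_amol or amount_mmol_per_gdw")
  }
  c1_sinks(df$name, amount, df$c1_per_molecule)
}

#' Total assimilatory C1 requirement from a sink table
#'
#' Sum over sinks of (per-cell amount x net C1 groups per molecule).
#'
#' @param sinks A [c1_sinks()] table.
#' @return Total C1 requirement, amol/cell.
#' @export
total_c1_requirement <- function(sinks) {
  if (!inherits(sinks, "c1_sinks")) stop("expected a c1_sinks table")
  if (nrow(sinks) == 0L) stop("sink table must not be empty")
  sum(sinks$amount_per_cell_amol * sinks$c1_per_molecule)
}

#' Per-cell C1/ATP budget
#'
#' Assembles the assimilatory C1 and dissimilatory ATP demand for one cell
#' duplication. The assimilatory side can be computed from a sink table; in
#' the default fallback mode (no sink table available) the published total
#' of 190.1 amol C1 per cell is used directly. The dissimilatory side is the
#' GAM-derived ATP requirement.
#'
#' @param sinks Optional [c1_sinks()] table; overrides `assimilatory_c1`.
#' @param cell A [cell_model()].
#' @param assimilatory_c1 Fallback assimilatory total, amol C1/cell
#'   (default 190.1).
#' @return A `c1_budget` with `assimilatory_c1` and `dissimilatory_atp`
#'   (both amol/cell).
#' @export
c1_budget <- function(sinks = NULL, cell = cell_model(),
                      assimilatory_c1 = 190.1) {
  assim <- if (!is.null(sinks)) total_c1_requirement(sinks) else assimilatory_c1
  if (assim <= 0) stop("assimilatory budget must be positive")
  structure(list(assimilatory_c1 = assim,
                 dissimilatory_atp = atp_requirement(cell)),
            class = "c1_budget")
}

#' @export
print.c1_budget <- function(x, ...) {
  cat(sprintf("<c1_budget> per cell duplication: %.1f amol C1 (assimilatory), %s amol ATP (dissimilatory)\n",
              x$assimilatory_c1,
              format(x$dissimilatory_atp, big.mark = ",")))
  invisible(x)
}

#' External methyl-group supply scenario
#'
#' Describes a culture supplemented with a methylated compound: compound
#' name, medium concentration, number of transferable methyl groups per
#' molecule (two for DMSP) and the cell density over which the supply is
#' shared. CFU are equated with cells.
#'
#' @param compound Compound label.
#' @param concentration_mol_per_l Concentration in the medium, mol/L (>= 0).
#' @param methyl_groups_per_molecule Methyl groups per molecule (>= 0).
#' @param cell_density_cfu_per_ml Cell density, CFU/ml (> 0).
#' @return A `supply_scenario`.
#' @export
supply_scenario <- function(compound, concentration_mol_per_l,
                            methyl_groups_per_molecule,
                            cell_density_cfu_per_ml) {
  if (concentration_mol_per_l < 0) stop("concentration must be non-negative")
  if (methyl_groups_per_molecule < 0) stop("methyl group count must be non-negative")
  if (cell_density_cfu_per_ml <= 0) stop("cell density must be positive")
  structure(list(compound = compound,
                 concentration_mol_per_l = concentration_mol_per_l,
                 methyl_groups_per_molecule = methyl_groups_per_molecule,
                 cell_density_cfu_per_ml = cell_density_cfu_per_ml),
            class = "supply_scenario")
}

#' Methyl-group supply available per cell
#'
#' Total methyl groups in the medium divided by the cells sharing them:
#' `concentration * methyls / density`, with the density converted from
#' CFU/ml to CFU/L and the result expressed in amol/cell
#' (1 mol = 10^18 amol).
#'
#' @param scenario A [supply_scenario()].
#' @return Supply, amol C1 per cell.
#' @export
methyl_supply_per_cell <- function(scenario) {
  stopifnot(inherits(scenario, "supply_scenario"))
  amol_per_l <- scenario$concentration_mol_per_l * 1e18 *
    scenario$methyl_groups_per_molecule
  cells_per_l <- scenario$cell_density_cfu_per_ml * 1000
  amol_per_l / cells_per_l
}

#' Percent coverage of the per-cell budget by an external supply
#'
#' How far the methyl groups supplied per cell go towards the assimilatory
#' C1 demand and the dissimilatory ATP demand, assuming one ATP is generated
#' per dissimilated methyl group (formate-THF ligase route); the yield is
#' configurable. Coverages are kept at full precision; rounding to the
#' conventional display (integer percent assimilatory, one decimal
#' dissimilatory) happens only in the print method.
#'
#' @param scenario A [supply_scenario()].
#' @param budget A [c1_budget()].
#' @param atp_per_methyl ATP generated per dissimilated methyl group
#'   (default 1).
#' @return A `coverage_result` with `supply_per_cell` (amol),
#'   `assimilatory_coverage` and `dissimilatory_coverage` (percent;
#'   may exceed 100).
#' @export
coverage <- function(scenario, budget, atp_per_methyl = 1) {
  stopifnot(inherits(budget, "c1_budget"))
  supply <- methyl_supply_per_cell(scenario)
  structure(
    list(compound = scenario$compound,
         supply_per_cell = supply,
         assimilatory_coverage = 100 * supply / budget$assimilatory_c1,
         dissimilatory_coverage = 100 * supply * atp_per_methyl /
           budget$dissimilatory_atp),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %s supplies %.4g amol C1 per cell\n",
              x$compound, x$supply_per_cell))
  cat(sprintf("  covers %d%% of assimilatory C1 needs, %.1f%% of dissimilatory ATP needs\n",
              round(x$assimilatory_coverage), x$dissimilatory_coverage))
  invisible(x)
}
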