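#' Colony counts from a 6-thioguanine resistance assay
#'
#' In the HPRT/6-TG assay, cells plated under 6-TG selection survive only if
#' they carry inactivating HPRT1 mutations, so the frequency of resistant
#' colonies — corrected by the plating efficiency of an unselected control
#' plate — estimates the relative mutation frequency of the line. Default
#' plated-cell numbers are the assay's standard setup (1e6 cells under
#' selection, 1500 unselected controls).
#'
#' @param resistant_colonies Colonies surviving 6-TG selection (>= 0).
#' @param control_colonies Colonies on the unselected control plate (> 0 for
#'   the frequency to be defined).
#' @param cells_plated_selected Cells plated under selection.
#' @param cells_plated_control Cells plated without selection.
#' @param label Sample name.
#' @return A `colony_assay` list.
#' @export
colony_assay <- function(resistant_colonies, control_colonies,
                         cells_plated_selected = 1e6,
                         cells_plated_control = 1500,
                         label = NA_character_) {
  if (resistant_colonies < 0 || control_colonies < 0)
    stop("colony counts must be >= 0")
  if (cells_plated_selected <= 0 || cells_plated_control <= 0)
    stop("plated cell counts must be > 0")
  structure(list(resistant_colonies = resistant_colonies,
                 control_colonies = control_colonies,
                 cells_plated_selected = cells_plated_selected,
                 cells_plated_control = cells_plated_control,
                 label = label),
            class = "colony_assay")
}

#' Induced mutant frequency of a 6-TG assay
#'
#' The resistant-colony frequency divided by the control plating efficiency:
#' `(resistant / plated_selected) / (control / plated_control)`.
#'
#' @param assay A [colony_assay()].
#' @return The induced mutant frequency (dimensionless).
#' @examples
#' mutant_frequency(colony_assay(1000, 1500))  # 1e-3
#' @export
mutant_frequency <- function(assay) {
  stopifnot(inherits(assay, "colony_assay"))
  if (assay$control_colonies <= 0)
    stop("plating efficiency undefined: control_colonies must be > 0")
  (assay$resistant_colonies / assay$cells_plated_selected) /
    (assay$control_colonies / assay$cells_plated_control)
}

#' Fold change of mutant frequency between two assays
#'
#' @param test,reference [colony_assay()] objects; the reference frequency
#'   must be positive.
#' @return `mutant_frequency(test) / mutant_frequency(reference)`.
#' @export
frequency_fold <- function(test, reference) {
  f_ref <- mutant_frequency(reference)
  if (f_ref <= 0)
    stop("reference mutant frequency must be > 0")
  fold_change(mutant_frequency(test), f_ref)
}

#' Mutant frequencies and folds for a table of assays
#'
#' @param table data.frame with columns `label`, `resistant`,
#'   `control_colonies` and optionally `plated_selected`, `plated_control`.
#' @param reference Label of the reference line for fold changes (default:
#'   first row).
#' @return The input with `frequency` and `fold_vs_reference` columns added.
#' @export
mutant_frequency_table <- function(table, reference = table$label[1]) {
  if (!all(c("label", "resistant", "control_colonies") %in% names(table)))
    stop("table needs columns label, resistant, control_colonies")
  if (is.null(table$plated_selected)) table$plated_selected <- 1e6
  if (is.null(table$plated_control)) table$plated_control <- 1500
  assays <- lapply(seq_len(nrow(table)), function(i) {
    colony_assay(table$resistant[i], table$control_colonies[i],
                 table$plated_selected[i], table$plated_control[i],
                 table$label[i])
  })
  table$frequency <- vapply(assays, mutant_frequency, numeric(1))
  ref <- which(table$label == reference)[1]
  if (is.na(ref)) stop("reference label not found: ", reference)
  if (table$frequency[ref] <= 0)
    stop("reference mutant frequency must be > 0")
  table$fold_vs_reference <- table$frequency / table$frequency[ref]
  table
}
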