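#' Per-drug configuration for episode construction and cohort assignment
#'
#' A `DrugSpec` table carries, for each study medication: the dispensing
#' (ATC) codes identifying it in claims, its class (the three oral
#' bisphosphonates share one class, so their new-user washout is evaluated
#' at class level), the days of coverage conferred by one dispensed unit,
#' the hierarchy rank used for cohort assignment (1 = highest priority =
#' most recently marketed), and the carry-over used by the virtual-exposure
#' sensitivity analysis (365 days for bisphosphonates including zoledronic
#' acid, 30 days otherwise).
#'
#' @param drug_name label for the medication (or medication group).
#' @param drug_codes character vector of dispensing codes.
#' @param drug_class class label; the washout is applied per class.
#' @param coverage_days_per_unit days covered by one dispensed unit (>= 1).
#' @param hierarchy_rank integer priority for cohort assignment; must be
#'   unique across specs (1 = assigned first).
#' @param virtual_extension_days carry-over days appended after the end of
#'   exposure in the virtual-exposure analysis (>= 0).
#' @return a one-row tibble (class retained through `bind_rows()`).
#' @seealso [default_drug_specs()]
#' @export
drug_spec <- function(drug_name, drug_codes, drug_class = drug_name,
                      coverage_days_per_unit, hierarchy_rank,
                      virtual_extension_days) {
  stopifnot(
    is.character(drug_name), length(drug_name) == 1L,
    is.character(drug_codes), length(drug_codes) >= 1L,
    coverage_days_per_unit >= 1,
    virtual_extension_days >= 0
  )
  tibble(
    drug_name = drug_name,
    drug_codes = list(drug_codes),
    drug_class = drug_class,
    coverage_days_per_unit = as.integer(coverage_days_per_unit),
    hierarchy_rank = as.integer(hierarchy_rank),
    virtual_extension_days = as.integer(virtual_extension_days)
  )
}

#' Default specifications for the five study medications
#'
#' Hierarchy follows market-entry recency: denosumab, zoledronic acid,
#' teriparatide, oral bisphosphonates, raloxifene. Coverage per unit is
#' configuration, not a claim about any national database: oral
#' bisphosphonates and raloxifene 30 d per monthly pack, denosumab 182 d
#' (semiannual injection), zoledronic acid 365 d (annual infusion),
#' teriparatide 28 d.
#'
#' @return a tibble of drug specifications.
#' @export
default_drug_specs <- function() {
  specs <- bind_rows(
    drug_spec("denosumab", "M05BX04",
      coverage_days_per_unit = 182, hierarchy_rank = 1,
      virtual_extension_days = 30
    ),
    drug_spec("zoledronic_acid", "M05BA08",
      coverage_days_per_unit = 365, hierarchy_rank = 2,
      virtual_extension_days = 365
    ),
    drug_spec("teriparatide", "H05AA02",
      coverage_days_per_unit = 28, hierarchy_rank = 3,
      virtual_extension_days = 30
    ),
    drug_spec("oral_bp", c("M05BA04", "M05BA07", "M05BA06"),
      drug_class = "oral_bp",
      coverage_days_per_unit = 30, hierarchy_rank = 4,
      virtual_extension_days = 365
    ),
    drug_spec("raloxifene", "G03XC01",
      coverage_days_per_unit = 30, hierarchy_rank = 5,
      virtual_extension_days = 30
    )
  )
  validate_drug_specs(specs)
  specs
}

validate_drug_specs <- function(specs) {
  stopifnot(
    !anyDuplicated(specs$hierarchy_rank),
    !anyDuplicated(specs$drug_name),
    all(specs$coverage_days_per_unit >= 1L),
    all(specs$virtual_extension_days >= 0L)
  )
  codes <- unlist(specs$drug_codes)
  if (anyDuplicated(codes)) stop("a dispensing code appears in two drug specs")
  invisible(specs)
}

# long (drug_code -> drug_name/class/...) lookup used by joins
specs_code_table <- function(specs) {
  specs %>%
    mutate(drug_code = .data$drug_codes) %>%
    select(-"drug_codes") %>%
    unnest("drug_code")
}
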