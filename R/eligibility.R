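# Screening eligibility gate.

#' Washout windows (days) for excluded prior therapies
#'
#' @return named numeric vector: minimum days since last use required at
#'   enrollment for each therapy class.
#' @export
eligibility_washout_windows <- function() {
  c(
    narcotic_analgesic = 1,
    tocilizumab = 21, dapsone = 21, mycophenolate = 21,
    etanercept = 28, leflunomide = 28, thalidomide = 28, cyclosporine = 28,
    glucocorticoid = 28,
    ivig = 56, adalimumab = 56, methotrexate = 56,
    infliximab = 84, mercaptopurine = 84, azathioprine = 84,
    cyclophosphamide = 84, chlorambucil = 84,
    rituximab = 182,
    live_vaccine = 30
  )
}

elig_fields_required <- c(
  "genotype_confirmed", "age_years", "stable_concomitant_meds",
  "cshq_total", "sbrs_ge_minus2sd", "cns_impairment", "nccpc_total",
  "seizure_disorder", "movement_disorder",
  "prior_trial_participation", "prior_trial_exclusion", "vineland_ratio",
  "anc", "ast_uln_ratio", "alt_uln_ratio", "bilirubin_uln_ratio",
  "creatinine_clearance", "active_infection", "tb_evidence",
  "malignancy_history", "pregnant", "other_trial", "prior_il1_inhibitor",
  "hypersensitivity_ecoli"
)

#' Evaluate trial eligibility from a screening record
#'
#' Inclusion requires: genetically confirmed MPS III, age >= 4 years and
#' stable concomitant medication, together with EITHER at least two of six
#' disease-severity criteria (CSHQ total >= 41; an SBRS cluster or domain at
#' or beyond -2 SD of the age-group mean; significant MPS III-related CNS
#' impairment or behavioral disturbance; NCCPC-R total >= 7; an MPS
#' III-related seizure disorder on regular medication; a movement disorder)
#' OR at least one alternate criterion (previous participation in, or
#' exclusion from, a gene/cell/enzyme trial; Vineland functional age at most
#' half of chronological age). Exclusions: enrollment in another trial, prior
#' IL-1 inhibitor, unexpired medication washout, liver-test thresholds
#' (AST/ALT > 5x ULN, or > 3x ULN with bilirubin > 2x ULN), creatinine
#' clearance < 30, ANC < 1,200 cells/uL, active infection or TB evidence,
#' malignancy history, E. coli-protein hypersensitivity, pregnancy.
#'
#' @param screening named list. Severity fields: `cshq_total`,
#'   `sbrs_ge_minus2sd` (logical; the SBRS reference table is site
#'   configuration so the criterion arrives pre-evaluated), `cns_impairment`,
#'   `nccpc_total`, `seizure_disorder`, `movement_disorder`. Alternate:
#'   `prior_trial_participation`, `prior_trial_exclusion`, `vineland_ratio`.
#'   Base: `genotype_confirmed`, `age_years`, `stable_concomitant_meds`.
#'   Labs/flags: `anc`, `ast_uln_ratio`, `alt_uln_ratio`,
#'   `bilirubin_uln_ratio`, `creatinine_clearance`, `active_infection`,
#'   `tb_evidence`, `malignancy_history`, `pregnant`, `other_trial`,
#'   `prior_il1_inhibitor`, `hypersensitivity_ecoli`, and optional
#'   `days_since_medication` (named vector checked against
#'   [eligibility_washout_windows()]).
#' @param vineland_strict use strict `< 0.5` for the Vineland ratio criterion.
#' @return list with `status` (`"eligible"`, `"ineligible"` or
#'   `"indeterminate"`), `eligible` (logical, `NA` when indeterminate),
#'   `satisfied`, `violated` and `missing_fields`.
#' @export
check_eligibility <- function(screening, vineland_strict = FALSE) {
  missing_fields <- setdiff(elig_fields_required, names(screening))
  if (length(missing_fields)) {
    return(list(
      status = "indeterminate", eligible = NA,
      satisfied = character(), violated = character(),
      missing_fields = missing_fields
    ))
  }
  s <- screening

  severity <- c(
    cshq_ge_41 = s$cshq_total >= 41,
    sbrs_ge_minus2sd = isTRUE(s$sbrs_ge_minus2sd),
    cns_impairment = isTRUE(s$cns_impairment),
    nccpc_ge_7 = s$nccpc_total >= 7,
    seizure_disorder = isTRUE(s$seizure_disorder),
    movement_disorder = isTRUE(s$movement_disorder)
  )
  alternate <- c(
    prior_trial_participation = isTRUE(s$prior_trial_participation),
    prior_trial_exclusion = isTRUE(s$prior_trial_exclusion),
    vineland_le_half = if (vineland_strict) {
      s$vineland_ratio < 0.5
    } else {
      s$vineland_ratio <= 0.5
    }
  )
  base <- c(
    genotype_confirmed = isTRUE(s$genotype_confirmed),
    age_ge_4 = s$age_years >= 4,
    stable_concomitant_meds = isTRUE(s$stable_concomitant_meds)
  )

  washout_violated <- character()
  if (!is.null(s$days_since_medication) && length(s$days_since_medication)) {
    w <- eligibility_washout_windows()
    meds <- intersect(names(s$days_since_medication), names(w))
    bad <- meds[s$days_since_medication[meds] < w[meds]]
    washout_violated <- if (length(bad)) paste0("washout_", bad) else character()
  }

  exclusions <- c(
    other_trial = isTRUE(s$other_trial),
    prior_il1_inhibitor = isTRUE(s$prior_il1_inhibitor),
    liver = s$ast_uln_ratio > 5 || s$alt_uln_ratio > 5 ||
      ((s$ast_uln_ratio > 3 || s$alt_uln_ratio > 3) && s$bilirubin_uln_ratio > 2),
    renal = s$creatinine_clearance < 30,
    neutropenia = s$anc < 1200,
    active_infection = isTRUE(s$active_infection),
    tb_evidence = isTRUE(s$tb_evidence),
    malignancy_history = isTRUE(s$malignancy_history),
    hypersensitivity_ecoli = isTRUE(s$hypersensitivity_ecoli),
    pregnant = isTRUE(s$pregnant)
  )
  violated <- c(names(exclusions)[exclusions], washout_violated)

  inclusion_met <- all(base) && (sum(severity) >= 2 || sum(alternate) >= 1)
  eligible <- inclusion_met && length(violated) == 0

  list(
    status = if (eligible) "eligible" else "ineligible",
    eligible = eligible,
    satisfied = c(
      names(base)[base], names(severity)[severity],
      names(alternate)[alternate]
    ),
    violated = c(names(base)[!base], violated),
    missing_fields = character()
  )
}
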